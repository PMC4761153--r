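#' @include synthetic-exome.R
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom jsonlite write_json read_json
NULL

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
}

.readTsv <- function(path) {
  read.delim(path, sep = "\t", na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a gene table from its TSV file pair
#'
#' Reads the per-gene summary TSV (`gene_id, dn, ds, dn_ds, div_n, div_s,
#' syn_sites, nonsyn_sites`) and the SNV TSV (`gene_id, pos, class` followed
#' by one dosage column per sample) and applies the divergence quality
#' filter at load: genes with dN > `maxDiv` or dS > `maxDiv` (default 0.8,
#' guarding against multiple-hit overcorrection in likelihood divergence
#' estimates) are excluded together with their SNVs. The retained gene
#' count is reported.
#'
#' @param genePath path to the gene summary TSV.
#' @param snvPath path to the SNV/dosage TSV.
#' @param maxDiv divergence exclusion threshold applied to dN and dS.
#' @return A [GeneTable-class].
#' @seealso [writeGeneTable()]
#' @export
readGeneTable <- function(genePath, snvPath, maxDiv = 0.8) {
  genes <- .readTsv(genePath)
  need <- c("gene_id", "dn", "ds", "dn_ds", "div_n", "div_s", "syn_sites",
            "nonsyn_sites")
  if (!nrow(genes) || !all(need %in% names(genes)))
    stop("schema error: gene summary must be non-empty with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  snvs <- .readTsv(snvPath)
  sneed <- c("gene_id", "pos", "class")
  if (!all(sneed %in% names(snvs)))
    stop("schema error: SNV table must have columns: ",
         paste(sneed, collapse = ", "), call. = FALSE)

  keep <- genes$dn <= maxDiv & genes$ds <= maxDiv
  message(sprintf("retained %d of %d genes (dN or dS > %g excluded)",
                  sum(keep), nrow(genes), maxDiv))
  genes <- genes[keep, , drop = FALSE]
  snvs <- snvs[snvs$gene_id %in% genes$gene_id, , drop = FALSE]
  sampleCols <- setdiff(names(snvs), sneed)
  dos <- as.matrix(snvs[, sampleCols, drop = FALSE])
  rownames(genes) <- rownames(snvs) <- NULL
  GeneTable(genes = genes, snvs = snvs[, sneed], dosages = dos,
            sampleIds = sampleCols, ploidy = 2L)
}

#' Write a gene table as its TSV file pair
#'
#' Inverse of [readGeneTable()]: writes `genes.tsv` and `snvs.tsv` (dosage
#' columns named by sample id) into `dir`, plus a JSON run manifest with
#' file checksums.
#'
#' @param geneTable a [GeneTable-class].
#' @param dir output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @return Invisibly, the manifest list.
#' @export
writeGeneTable <- function(geneTable, dir, seed = NULL) {
  stopifnot(is(geneTable, "GeneTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(geneTable@genes, file.path(dir, "genes.tsv"))
  dos <- as.data.frame(geneTable@dosages)
  names(dos) <- geneTable@sampleIds
  .writeTsv(cbind(geneTable@snvs, dos), file.path(dir, "snvs.tsv"))
  man <- runManifest(c(file.path(dir, "genes.tsv"),
                       file.path(dir, "snvs.tsv")), seed = seed)
  writeManifest(man, file.path(dir, "manifest.json"))
  invisible(man)
}

#' Read bi-allelic SNVs from a VCF
#'
#' Reads a VCF with GT fields, keeping only bi-allelic single-nucleotide
#' records; multi-allelic and non-SNV records are dropped and counted.
#' Genotypes become allele dosages 0/1/2; sites with any missing call are
#' dropped listwise. Positions are reported 0-based half-open.
#'
#' @param path VCF path (plain text or gzip).
#' @param sampleSubset optional character vector of sample names to keep.
#' @return List with `dosages` (sites x samples integer matrix), `sites`
#'   (data.frame `chrom`, `pos0`, `ref`, `alt`) and `dropped` (named counts
#'   of discarded records).
#' @export
readVcfBiallelic <- function(path, sampleSubset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(list(dosages = matrix(integer(), 0, 0),
                sites = data.frame(chrom = character(), pos0 = integer(),
                                   ref = character(), alt = character()),
                dropped = c(non_snv_or_multiallelic = 0L, missing_gt = 0L)))
  snv <- !is.na(fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(sampleSubset)) {
    miss <- setdiff(sampleSubset, colnames(gt))
    if (length(miss))
      stop("samples not in VCF: ", paste(miss, collapse = ", "),
           call. = FALSE)
    gt <- gt[, sampleSubset, drop = FALSE]
  }
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(p) {
      if (any(is.na(p)) || any(p == ".")) NA_integer_
      else sum(as.integer(p))
    }, integer(1))
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) dos[, j] <- alleles(gt[, j])
  complete <- !apply(dos, 1L, anyNA)
  keep <- snv & complete
  message(sprintf(
    "VCF: kept %d of %d records (%d non-SNV/multi-allelic, %d with missing GT)",
    sum(keep), nrow(fix), sum(!snv), sum(snv & !complete)))
  list(dosages = dos[keep, , drop = FALSE],
       sites = data.frame(chrom = fix$CHROM[keep],
                          pos0 = as.integer(fix$POS[keep]) - 1L,
                          ref = fix$REF[keep], alt = fix$ALT[keep]),
       dropped = c(non_snv_or_multiallelic = sum(!snv),
                   missing_gt = sum(snv & !complete)),
       samples = colnames(gt))
}

#' Write a gene table as a minimal VCF plus class-annotation BED
#'
#' Emits a GT-only VCF 4.2 dialect file (CHROM = gene id, POS = 1-based
#' SNV position, placeholder REF/ALT alleles) and a BED file (0-based
#' half-open) carrying the synonymous/nonsynonymous class of every SNV, for
#' exercising the VCF reading path against known dosages.
#'
#' @param geneTable a [GeneTable-class].
#' @param vcfPath,bedPath output paths.
#' @return Invisibly, `vcfPath`.
#' @export
writeVcfBiallelic <- function(geneTable, vcfPath, bedPath = NULL) {
  stopifnot(is(geneTable, "GeneTable"), geneTable@ploidy == 2L)
  snvs <- geneTable@snvs
  dos <- geneTable@dosages
  gtCodes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snvs)), function(i) {
    paste(c(snvs$gene_id[i], snvs$pos[i] + 1L, ".", "A", "G", ".", "PASS",
            ".", "GT", gtCodes[dos[i, ] + 1L]), collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geneTable@sampleIds), collapse = "\t"))
  writeLines(c(hdr, body), vcfPath)
  if (!is.null(bedPath))
    writeLines(sprintf("%s\t%d\t%d\t%s", snvs$gene_id, snvs$pos,
                       snvs$pos + 1L, snvs$class), bedPath)
  invisible(vcfPath)
}

#' Read a site-class annotation BED
#'
#' Reads a BED file whose name column labels each site
#' `synonymous`/`nonsynonymous` and returns 0-based positions.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `pos0`, `class`.
#' @export
readClassBed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  data.frame(chrom = as.character(gr$seqnames),
             pos0 = gr$start - 1L,   # GRanges is 1-based
             class = gr$name)
}

#' Assemble a gene table from a VCF and class annotation
#'
#' Real-data entry path: combines a gene summary TSV (read and filtered as
#' in [readGeneTable()]), a bi-allelic SNV VCF and a class-annotation BED
#' into a [GeneTable-class]. VCF CHROM is taken as the gene id and sites
#' are matched to their class by (gene, position).
#'
#' @param genePath gene summary TSV path.
#' @param vcfPath VCF path.
#' @param bedPath class-annotation BED path.
#' @param maxDiv divergence exclusion threshold.
#' @return A [GeneTable-class].
#' @export
geneTableFromVcf <- function(genePath, vcfPath, bedPath, maxDiv = 0.8) {
  genes <- .readTsv(genePath)
  keep <- genes$dn <= maxDiv & genes$ds <= maxDiv
  message(sprintf("retained %d of %d genes (dN or dS > %g excluded)",
                  sum(keep), nrow(genes), maxDiv))
  genes <- genes[keep, , drop = FALSE]
  vc <- readVcfBiallelic(vcfPath)
  ann <- readClassBed(bedPath)
  key <- paste(vc$sites$chrom, vc$sites$pos0)
  cls <- ann$class[match(key, paste(ann$chrom, ann$pos0))]
  sel <- !is.na(cls) & vc$sites$chrom %in% genes$gene_id
  snvs <- data.frame(gene_id = vc$sites$chrom[sel],
                     pos = vc$sites$pos0[sel], class = cls[sel])
  rownames(genes) <- NULL
  GeneTable(genes = genes, snvs = snvs,
            dosages = vc$dosages[sel, , drop = FALSE],
            sampleIds = vc$samples, ploidy = 2L)
}

#' Run manifest
#'
#' A small provenance record for an output directory: input/output file MD5
#' checksums, the seed, package version and timestamp. Re-running a
#' deterministic stage with the same manifest inputs reproduces its outputs
#' byte-identically.
#'
#' @param files character vector of file paths to checksum.
#' @param seed optional RNG seed to record.
#' @param extra optional named list of additional fields.
#' @return A list (class `"runManifest"`).
#' @export
runManifest <- function(files = character(), seed = NULL, extra = list()) {
  sums <- if (length(files)) as.list(tools::md5sum(files)) else list()
  c(list(package = "thetaSweep",
         version = as.character(packageVersion("thetaSweep")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, checksums = sums), extra)
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path JSON output path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write sweep results as tidy TSV files
#'
#' Writes `sweep_stats.tsv` (one row per redraw x bin x sample size x site
#' class) and `sweep_summary.tsv` (one row per series) with `.` for
#' undefined statistics, plus a JSON manifest.
#'
#' @param sweep a [SweepResult-class].
#' @param dir output directory.
#' @return Invisibly, the manifest list.
#' @export
writeSweepResult <- function(sweep, dir) {
  stopifnot(is(sweep, "SweepResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(sweep@stats, file.path(dir, "sweep_stats.tsv"))
  .writeTsv(sweep@summaries, file.path(dir, "sweep_summary.tsv"))
  man <- runManifest(file.path(dir, c("sweep_stats.tsv",
                                      "sweep_summary.tsv")),
                     seed = sweep@meta$seed,
                     extra = list(sizes = sweep@meta$sizes,
                                  nRedraws = sweep@meta$nRedraws))
  writeManifest(man, file.path(dir, "manifest.json"))
  invisible(man)
}

#' Write simulation replicates as a tidy TSV with a manifest sidecar
#'
#' One row per replicate x sample size x site class, with columns
#' `replicate, sample_size, site_class, S, singletons, theta_w, pi,
#' n_sites`, plus a JSON manifest recording the seed, rescaling factor and
#' file checksum.
#'
#' @param reps a `"wfReplicates"` object from [runSimulation()].
#' @param dir output directory.
#' @return Invisibly, the manifest list.
#' @export
writeSimulationResult <- function(reps, dir) {
  stopifnot(inherits(reps, "wfReplicates"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(summariseReplicates(reps), file.path(dir, "replicates.tsv"))
  cfg <- attr(reps, "config")
  man <- runManifest(file.path(dir, "replicates.tsv"), seed = cfg@seed,
                     extra = list(lambda = cfg@lambda, mu = cfg@mu,
                                  seqLength = cfg@seqLength,
                                  nReplicates = cfg@nReplicates,
                                  diagnostics = attr(reps, "diagnostics")))
  writeManifest(man, file.path(dir, "manifest.json"))
  invisible(man)
}
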