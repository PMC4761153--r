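#' @include sweep-pipeline.R
#' @importFrom stats rbeta rbinom rgamma rpois
#' @importFrom utils head
NULL

# folded-spectrum sampling weights for minor-allele count m = 1 .. n/2 in a
# panel of n sequences: neutral law phi(m) ~ 1/m + 1/(n - m) (halved at
# m = n/2), optionally tilted by moving probability mass tau onto the
# singleton bin
.sfsWeights <- function(nSeqPanel, tilt = 0) {
  m <- seq_len(nSeqPanel %/% 2L)
  w <- 1 / m + 1 / (nSeqPanel - m)
  if (2L * m[length(m)] == nSeqPanel) w[length(w)] <- w[length(w)] / 2
  w <- w / sum(w)
  if (tilt > 0) {
    w <- (1 - tilt) * w
    w[1L] <- w[1L] + tilt
  }
  w
}

# place m allele copies on a panel of nInd diploid individuals and return
# the dosage vector; random placement draws haplotypes without replacement,
# deterministic placement fills individuals left to right (used by the
# planted construction)
.placeCopies <- function(m, nInd, random = TRUE) {
  hap <- if (random) sample.int(2L * nInd, m) else seq_len(m)
  tabulate((hap + 1L) %/% 2L, nbins = nInd)
}

#' Generate a synthetic exome-SNV gene table
#'
#' Builds a [GeneTable-class] with the statistical shape of a large human
#' exome polymorphism panel: per-gene dN/dS drawn from a constraint
#' distribution concentrated at low values, human-chimp-scale divergence
#' rates with Poisson fixed-difference counts, and bi-allelic SNVs whose
#' panel minor-allele counts follow a folded neutral spectrum optionally
#' tilted toward singletons -- uniformly (`"growth"`, emulating the
#' rare-variant excess of an expanded population) and, for nonsynonymous
#' SNVs, in proportion to `1 - dN/dS` (`"selection"`, emulating purifying
#' selection holding deleterious variants at low frequency). The tilt is a
#' one-parameter modelling convenience for exercising the pipeline, not a
#' mechanistic map from selection to the spectrum.
#'
#' Allele copies are placed uniformly on the panel's haplotypes, so the
#' realized panel spectrum reproduces the drawn counts exactly; genotypes
#' are the induced diploid dosages (no inbreeding, no structure). Generated
#' dN and dS stay below the 0.8 load filter by construction.
#'
#' @param config a [SynthConfig-class].
#' @return A [GeneTable-class] over `config@nIndividuals` samples.
#' @seealso [plantedGeneTable()] for an exact-recovery fixture,
#'   [runSweep()] for the analysis it feeds.
#' @export
syntheticGeneTable <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config@seed)

  nInd <- config@nIndividuals
  n2 <- 2L * nInd
  nG <- config@nGenes
  ids <- sprintf("gene%05d", seq_len(nG))

  dnds <- rbeta(nG, 1.2, 3.3)                   # constraint proxy in [0, 1]
  ds <- rgamma(nG, shape = 6, scale = 0.013 / 6)  # human-chimp-scale dS
  ds <- pmin(ds, 0.79)
  dn <- pmin(dnds * ds, 0.79)
  genes <- data.frame(gene_id = ids, dn = dn, ds = ds, dn_ds = dnds,
                      div_n = rpois(nG, dn * config@nonsynSites),
                      div_s = rpois(nG, ds * config@synSites),
                      syn_sites = config@synSites,
                      nonsyn_sites = config@nonsynSites)

  growth <- if (config@sfsModel == "neutral") 0 else config@growthTilt
  wSyn <- .sfsWeights(n2, growth)
  mm <- seq_len(n2 %/% 2L)

  snvList <- vector("list", nG)
  dosList <- vector("list", nG)
  for (g in seq_len(nG)) {
    nSyn <- rbinom(1L, config@synSites, config@synDensity)
    # constrained genes carry proportionally fewer nonsynonymous SNVs
    nNon <- rbinom(1L, config@nonsynSites,
                   config@nonsynDensity * (0.25 + 0.75 * dnds[g]))
    if (nSyn + nNon == 0L) next
    tiltN <- if (config@sfsModel == "selection")
      min(1, growth + config@constraintTilt * (1 - dnds[g])) else growth
    wNon <- .sfsWeights(n2, tiltN)
    cls <- c(rep("synonymous", nSyn), rep("nonsynonymous", nNon))
    pos <- c(if (nSyn) sample.int(config@synSites, nSyn) - 1L,
             if (nNon) config@synSites +
               sample.int(config@nonsynSites, nNon) - 1L)
    m <- c(if (nSyn) sample(mm, nSyn, replace = TRUE, prob = wSyn),
           if (nNon) sample(mm, nNon, replace = TRUE, prob = wNon))
    snvList[[g]] <- data.frame(gene_id = ids[g], pos = pos, class = cls)
    dosList[[g]] <- t(vapply(m, .placeCopies, integer(nInd), nInd = nInd))
  }
  keep <- !vapply(snvList, is.null, logical(1))
  snvs <- if (any(keep)) do.call(rbind, snvList[keep]) else
    data.frame(gene_id = character(), pos = integer(), class = character())
  dos <- if (any(keep)) do.call(rbind, dosList[keep]) else
    matrix(integer(), 0L, nInd)
  rownames(snvs) <- NULL
  GeneTable(genes = genes, snvs = snvs, dosages = dos,
            sampleIds = sprintf("ind%04d", seq_len(nInd)), ploidy = 2L)
}

#' Gene table realizing a planted site frequency spectrum exactly
#'
#' Constructs a deterministic [GeneTable-class] whose pooled per-class panel
#' spectrum equals the given spectra exactly: for every class and
#' minor-allele count m with c planted sites, c SNVs are created carrying
#' exactly m allele copies (individuals filled left to right). Used as the
#' construct-then-recover fixture for the sweep pipeline.
#'
#' @param sfsByClass named list with elements `synonymous` and/or
#'   `nonsynonymous`, each a [SiteFrequencySpectrum-class] whose `nSeq` is
#'   twice the panel size.
#' @param nIndividuals diploid panel size; defaults to `nSeq/2` of the first
#'   spectrum.
#' @return A [GeneTable-class] with a single gene whose per-class site
#'   totals equal the spectra's `nSites`.
#' @export
plantedGeneTable <- function(sfsByClass, nIndividuals = NULL) {
  stopifnot(is.list(sfsByClass), length(sfsByClass) >= 1L,
            all(names(sfsByClass) %in% c("synonymous", "nonsynonymous")))
  n2 <- nSeq(sfsByClass[[1L]])
  if (is.null(nIndividuals)) nIndividuals <- n2 %/% 2L
  if (n2 != 2L * nIndividuals)
    stop("planted spectra must have nSeq = 2 * nIndividuals", call. = FALSE)
  siteCap <- c(synonymous = 0, nonsynonymous = 0)
  rows <- list()
  dos <- list()
  for (cl in names(sfsByClass)) {
    sfs <- sfsByClass[[cl]]
    if (nSeq(sfs) != n2)
      stop("all planted spectra must share one nSeq", call. = FALSE)
    if (segSites(sfs) > nSites(sfs))
      stop("infeasible spectrum: more segregating sites than sites",
           call. = FALSE)
    siteCap[[cl]] <- nSites(sfs)
    counts <- sfsCounts(sfs)
    p <- 0L
    for (m in seq_along(counts)) {
      cm <- counts[m]
      if (cm <= 0) next
      for (j in seq_len(cm)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = "planted", pos = NA_integer_, class = cl,
                     m = m)
        p <- p + 1L
      }
    }
  }
  snvs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), pos = integer(), class = character(),
               m = integer())
  # deterministic positions: class-contiguous layout
  offs <- c(synonymous = 0, nonsynonymous = siteCap[["synonymous"]])
  for (cl in unique(snvs$class)) {
    sel <- snvs$class == cl
    snvs$pos[sel] <- offs[[cl]] + seq_len(sum(sel)) - 1L
  }
  dosM <- if (nrow(snvs))
    t(vapply(snvs$m, .placeCopies, integer(nIndividuals),
             nInd = nIndividuals, random = FALSE))
  else matrix(integer(), 0L, nIndividuals)
  snvs$m <- NULL
  genes <- data.frame(gene_id = "planted", dn = 0.1, ds = 0.2, dn_ds = 0.5,
                      div_n = 0L, div_s = 0L,
                      syn_sites = max(siteCap[["synonymous"]], 1),
                      nonsyn_sites = max(siteCap[["nonsynonymous"]], 1))
  GeneTable(genes = genes, snvs = snvs, dosages = dosM,
            sampleIds = sprintf("ind%04d", seq_len(nIndividuals)),
            ploidy = 2L)
}

#' Pooled panel spectrum of a gene table
#'
#' Folds the full-panel dosages of one site class (over an optional gene
#' subset) into a [SiteFrequencySpectrum-class], with `nSites` taken from
#' the genes' per-class site totals.
#'
#' @param geneTable a [GeneTable-class].
#' @param siteClass `"synonymous"` or `"nonsynonymous"`.
#' @param geneIds optional gene subset.
#' @return A [SiteFrequencySpectrum-class].
#' @export
pooledSFS <- function(geneTable, siteClass = c("synonymous",
                                               "nonsynonymous"),
                      geneIds = NULL) {
  siteClass <- match.arg(siteClass)
  stopifnot(is(geneTable, "GeneTable"))
  genes <- geneTable@genes
  sel <- geneTable@snvs$class == siteClass
  if (!is.null(geneIds)) {
    sel <- sel & geneTable@snvs$gene_id %in% geneIds
    genes <- genes[genes$gene_id %in% geneIds, , drop = FALSE]
  }
  nsites <- sum(if (siteClass == "synonymous") genes$syn_sites
                else genes$nonsyn_sites)
  sfsFromGenotypes(geneTable@dosages[sel, , drop = FALSE],
                   ploidy = geneTable@ploidy, nSites = nsites,
                   siteClass = siteClass)
}
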