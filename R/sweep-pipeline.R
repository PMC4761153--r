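#' @include mk-stats.R
#' @importFrom stats lm coef cor.test sd setNames
NULL

#' Partition a sample panel into disjoint size groups
#'
#' Draws, for each redraw, a uniformly random partition of the sample ids
#' into non-overlapping groups of the requested sizes (the remainder of the
#' panel is left unused). Redraws use distinct, seed-derived substreams, so
#' a partition is reproducible from `seed` alone.
#'
#' @param sampleIds character vector of available sample ids.
#' @param sizes integer vector of group sizes; their sum must not exceed
#'   `length(sampleIds)`.
#' @param nRedraws number of independent partitions.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A list of length `nRedraws`; each element is a named list of
#'   disjoint id vectors (names are the sizes).
#' @examples
#' p <- partitionSamples(sprintf("s%04d", 1:1008),
#'                       c(16, 32, 64, 128, 256, 512), nRedraws = 2, seed = 1)
#' lengths(p[[1]])
#' @export
partitionSamples <- function(sampleIds, sizes, nRedraws = 1, seed = NULL) {
  sizes <- as.integer(sizes)
  if (sum(sizes) > length(sampleIds))
    stop(sprintf(
      "partition error: group sizes sum to %d but only %d samples are available",
      sum(sizes), length(sampleIds)), call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  redrawSeeds <- sample.int(.Machine$integer.max - 1L, nRedraws)
  lapply(seq_len(nRedraws), function(r) {
    set.seed(redrawSeeds[r])
    pool <- sample(sampleIds, sum(sizes))
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    setNames(lapply(seq_along(sizes),
                    function(i) pool[starts[i]:ends[i]]),
             as.character(sizes))
  })
}

#' Bin genes by dN/dS
#'
#' Assigns genes to half-open bins `[lo, hi)` of their dN/dS ratio; genes at
#' or above the last edge are placed in the top bin (so with the default
#' edges a gene with dN/dS = 0.95 lands in the `"0.9-1"` bin).
#'
#' @param geneTable a [GeneTable-class] (already dN/dS-filtered at load).
#' @param edges increasing numeric bin boundaries, default
#'   `seq(0, 1, by = 0.1)`.
#' @return Named list of gene-id character vectors, one per bin (possibly
#'   empty); names are `"lo-hi"` labels, attribute `"midpoints"` the bin
#'   centres.
#' @export
binGenesByDnDs <- function(geneTable, edges = seq(0, 1, by = 0.1)) {
  stopifnot(is(geneTable, "GeneTable"), length(edges) >= 2L,
            !is.unsorted(edges, strictly = TRUE))
  g <- geneTable@genes
  idx <- findInterval(g$dn_ds, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  idx[idx > nb] <- nb   # >= last edge goes to the top bin
  idx[idx < 1L] <- 1L
  labels <- paste0(edges[-length(edges)], "-", edges[-1L])
  out <- setNames(lapply(seq_len(nb), function(b) g$gene_id[idx == b]),
                  labels)
  attr(out, "midpoints") <- (edges[-length(edges)] + edges[-1L]) / 2
  out
}

# statistics for one sample group and one gene set
.groupStats <- function(geneTable, groupIds, geneIds = NULL) {
  gt <- geneTable
  genes <- gt@genes
  snvs <- gt@snvs
  keepSnv <- rep(TRUE, nrow(snvs))
  if (!is.null(geneIds)) {
    genes <- genes[genes$gene_id %in% geneIds, , drop = FALSE]
    keepSnv <- snvs$gene_id %in% geneIds
  }
  cols <- match(groupIds, gt@sampleIds)
  if (anyNA(cols))
    stop("unknown sample ids in group", call. = FALSE)
  nSeqG <- gt@ploidy * length(cols)
  ac <- as.integer(round(rowSums(gt@dosages[, cols, drop = FALSE])))

  classSites <- c(synonymous = sum(genes$syn_sites),
                  nonsynonymous = sum(genes$nonsyn_sites))
  perClass <- lapply(c("synonymous", "nonsynonymous"), function(cl) {
    rows <- keepSnv & snvs$class == cl
    acc <- ac[rows]
    minor <- pmin(acc, nSeqG - acc)
    minor <- minor[acc > 0L & acc < nSeqG]
    sfs <- SiteFrequencySpectrum(tabulate(minor, nbins = nSeqG %/% 2L),
                                 nSeq = nSeqG,
                                 nSites = max(classSites[[cl]], 1),
                                 siteClass = cl)
    S <- segSites(sfs)
    list(sfs = sfs, S = S, singletons = unname(singletons(sfs)),
         theta = if (classSites[[cl]] > 0) wattersonTheta(sfs) else NA_real_,
         pi = if (classSites[[cl]] > 0) nucleotideDiversity(sfs)
              else NA_real_,
         # undefined statistics (S = 0, n_seq < 3, degenerate variance)
         # propagate as NA without per-group warnings
         DT = if (S > 0 && nSeqG >= 3L) suppressWarnings(tajimaD(sfs))
              else NA_real_,
         DFL = if (S > 0 && nSeqG >= 3L) suppressWarnings(fuLiDStar(sfs))
               else NA_real_)
  })
  names(perClass) <- c("synonymous", "nonsynonymous")

  nS <- perClass$nonsynonymous$S
  sS <- perClass$synonymous$S
  p <- if (nS + sS > 0) nS / (nS + sS) else NA_real_
  pse <- if (nS + sS > 0) sqrt(p * (1 - p) / (nS + sS)) else NA_real_
  mk <- MKCounts(Pn = nS, Ps = sS, Dn = sum(genes$div_n),
                 Ds = sum(genes$div_s))
  ni <- if (mk@Ps > 0 && mk@Dn > 0) neutralityIndex(mk) else NA_real_
  al <- if (mk@Ps > 0 && mk@Dn > 0) alphaAdaptive(mk) else NA_real_

  do.call(rbind, lapply(names(perClass), function(cl) {
    x <- perClass[[cl]]
    data.frame(sample_size = length(cols), n_seq = nSeqG, site_class = cl,
               S = x$S, singletons = x$singletons, theta_w = x$theta,
               pi = x$pi, tajima_d = x$DT, fu_li_d_star = x$DFL,
               n_sites = unname(classSites[[cl]]), nsnv_fraction = p,
               nsnv_fraction_se = pse, Pn = mk@Pn, Ps = mk@Ps, Dn = mk@Dn,
               Ds = mk@Ds, ni = ni, alpha = al)
  }))
}

#' Statistics per sample-size group
#'
#' For each group of individuals, pools the SNVs of the selected genes into
#' one folded spectrum per site class and computes every statistic of the
#' sweep: per-site Watterson's theta and nucleotide diversity, Tajima's D,
#' Fu-Li D*, segregating-site and singleton counts, the nonsynonymous SNV
#' fraction with its binomial standard error, and the pooled
#' McDonald-Kreitman table with Neutrality Index and alpha. Polymorphism is
#' assessed within the group: a site segregating only outside the group does
#' not count, which is precisely the sample-size mechanism under study.
#'
#' @param geneTable a [GeneTable-class].
#' @param groups named list of sample-id vectors (one per sample size), as
#'   produced by [partitionSamples()].
#' @param geneIds optional subset of genes (e.g. one dN/dS bin).
#' @return data.frame, two rows (site classes) per group.
#' @export
statsBySize <- function(geneTable, groups, geneIds = NULL) {
  stopifnot(is(geneTable, "GeneTable"))
  out <- do.call(rbind, lapply(groups, .groupStats, geneTable = geneTable,
                               geneIds = geneIds))
  rownames(out) <- NULL
  out
}

#' Log2-log2 regression slope of a statistic on sample size
#'
#' Ordinary least squares of `log2(statistic)` on `log2(sample size)`: the
#' power-law exponent of the statistic's growth with sample size (0 for a
#' flat, sample-size-free statistic). Non-positive values cannot be
#' log-transformed and are dropped with a warning.
#'
#' @param sizes sample sizes.
#' @param values statistic values, same length.
#' @return Named numeric vector `c(slope, stderr)`; both `NA` when fewer
#'   than 3 positive points remain.
#' @examples
#' loglogSlope(c(16, 32, 64, 128), 2e-4 * c(16, 32, 64, 128)^0.2)
#' @export
loglogSlope <- function(sizes, values) {
  stopifnot(length(sizes) == length(values))
  ok <- is.finite(values) & values > 0 & is.finite(sizes) & sizes > 0
  if (any(!ok & is.finite(values)))
    warning("dropping non-positive values from log-log regression",
            call. = FALSE)
  if (sum(ok) < 3L) return(c(slope = NA_real_, stderr = NA_real_))
  fit <- lm(log2(values[ok]) ~ log2(sizes[ok]))
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  c(slope = unname(coef(fit)[2L]), stderr = unname(sm[2L, 2L]))
}

#' Large-versus-small sample-size difference and ratio
#'
#' `delta = value(nHi) - value(nLo)` and `ratio = value(nHi) / value(nLo)`
#' for one statistic series: the ratio is oriented large/small, so a
#' statistic inflated by sample size gives ratio > 1 (and delta > 0 for
#' positive series).
#'
#' @param sizes sample sizes of the series.
#' @param values statistic values.
#' @param nLo,nHi the two sizes to compare (default 16 and 512); both must
#'   be present in `sizes`.
#' @return Named numeric vector `c(delta, ratio)`; `ratio` is `NA` for a
#'   zero denominator.
#' @export
deltaAndRatio <- function(sizes, values, nLo = 16, nHi = 512) {
  iLo <- match(nLo, sizes)
  iHi <- match(nHi, sizes)
  if (is.na(iLo) || is.na(iHi))
    stop(sprintf("sizes %s and %s must both be present in the series",
                 nLo, nHi), call. = FALSE)
  vLo <- values[iLo]
  vHi <- values[iHi]
  c(delta = vHi - vLo,
    ratio = if (is.finite(vLo) && vLo != 0) vHi / vLo else NA_real_)
}

#' Correlation tests of a statistic against sample size
#'
#' Pearson correlation on log2-transformed pairs (raw pairs when the series
#' is not strictly positive) and the non-parametric Kendall rank correlation
#' on raw pairs, with two-sided p-values.
#'
#' @param sizes sample sizes.
#' @param values statistic values.
#' @return Named numeric vector
#'   `c(pearson_r, pearson_p, kendall_tau, kendall_p)`; all `NA` with a
#'   warning for constant or too-short series.
#' @export
correlationTests <- function(sizes, values) {
  ok <- is.finite(sizes) & is.finite(values)
  x <- sizes[ok]; y <- values[ok]
  nas <- c(pearson_r = NA_real_, pearson_p = NA_real_,
           kendall_tau = NA_real_, kendall_p = NA_real_)
  if (length(y) < 3L || sd(y) == 0 || sd(x) == 0) {
    warning("correlation undefined for constant or too-short series",
            call. = FALSE)
    return(nas)
  }
  yl <- if (all(y > 0)) log2(y) else y
  pe <- cor.test(log2(x), yl, method = "pearson")
  ke <- suppressWarnings(cor.test(x, y, method = "kendall"))
  c(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    kendall_tau = unname(ke$estimate), kendall_p = ke$p.value)
}

.seriesSummary <- function(bin, cls, statistic, sizes, valueMatrix,
                           nLo, nHi) {
  # valueMatrix: redraws x sizes
  meanv <- colMeans(valueMatrix)
  sl <- suppressWarnings(loglogSlope(sizes, meanv))
  perRedraw <- apply(valueMatrix, 1L, function(v)
    suppressWarnings(loglogSlope(sizes, v))[["slope"]])
  dr <- if (nLo %in% sizes && nHi %in% sizes)
    deltaAndRatio(sizes, meanv, nLo, nHi)
  else c(delta = NA_real_, ratio = NA_real_)
  ct <- suppressWarnings(correlationTests(sizes, meanv))
  data.frame(bin = bin, site_class = cls, statistic = statistic,
             slope = sl[["slope"]], slope_se = sl[["stderr"]],
             slope_sd_redraws = if (sum(is.finite(perRedraw)) > 1L)
               sd(perRedraw, na.rm = TRUE) else NA_real_,
             delta = dr[["delta"]], ratio = dr[["ratio"]],
             pearson_r = ct[["pearson_r"]], pearson_p = ct[["pearson_p"]],
             kendall_tau = ct[["kendall_tau"]],
             kendall_p = ct[["kendall_p"]])
}

#' Run the full sample-size sweep
#'
#' The complete subsampling analysis: the panel is partitioned into disjoint
#' groups of the requested sizes (`nRedraws` independent partitions), every
#' statistic of [statsBySize()] is computed per group for the pooled gene
#' set and, optionally, per dN/dS bin, and each (bin, class, statistic)
#' series is summarised by its log2-log2 regression slope, its
#' large-vs-small delta and ratio, and correlation tests. Series summaries
#' are computed on the redraw-mean series; the spread of per-redraw slopes
#' is reported as `slope_sd_redraws`.
#'
#' @param geneTable a [GeneTable-class].
#' @param sizes sample sizes in individuals (diploid samples; statistics are
#'   computed on `2 * size` sequences).
#' @param nRedraws number of independent panel partitions.
#' @param seed RNG seed for the partitions.
#' @param binEdges optional dN/dS bin boundaries (e.g. `seq(0, 1, 0.1)`);
#'   the pooled "all" bin is always included.
#' @param nLo,nHi sizes compared by the delta/ratio summaries.
#' @return A [SweepResult-class].
#' @examples
#' gt <- syntheticGeneTable(SynthConfig(nIndividuals = 60, nGenes = 40,
#'                                      seed = 2))
#' sw <- runSweep(gt, sizes = c(8, 16, 32), nRedraws = 2, seed = 9)
#' head(sweepSummary(sw))
#' @export
runSweep <- function(geneTable, sizes = c(16, 32, 64, 128, 256, 512),
                     nRedraws = 10, seed = 1, binEdges = NULL,
                     nLo = min(sizes), nHi = max(sizes)) {
  stopifnot(is(geneTable, "GeneTable"))
  sizes <- sort(as.integer(sizes))
  parts <- partitionSamples(geneTable@sampleIds, sizes, nRedraws, seed)
  bins <- list(all = geneTable@genes$gene_id)
  if (!is.null(binEdges))
    bins <- c(bins, binGenesByDnDs(geneTable, binEdges))

  stats <- do.call(rbind, lapply(seq_len(nRedraws), function(r) {
    do.call(rbind, lapply(names(bins), function(b) {
      if (!length(bins[[b]])) return(NULL)
      st <- statsBySize(geneTable, parts[[r]], geneIds = bins[[b]])
      cbind(redraw = r, bin = b, st)
    }))
  }))
  rownames(stats) <- NULL

  groupStats <- c("theta_w", "pi", "tajima_d", "fu_li_d_star", "S",
                  "singletons")
  binStats <- c("nsnv_fraction", "ni", "alpha")
  summaries <- do.call(rbind, lapply(unique(stats$bin), function(b) {
    sb <- stats[stats$bin == b, , drop = FALSE]
    rows <- list()
    for (cl in c("synonymous", "nonsynonymous")) {
      sc <- sb[sb$site_class == cl, , drop = FALSE]
      for (st in groupStats) {
        vm <- matrix(NA_real_, nRedraws, length(sizes))
        for (r in seq_len(nRedraws)) {
          sr <- sc[sc$redraw == r, , drop = FALSE]
          vm[r, ] <- sr[[st]][match(sizes, sr$sample_size)]
        }
        rows[[length(rows) + 1L]] <-
          .seriesSummary(b, cl, st, sizes, vm, nLo, nHi)
      }
    }
    scl <- sb[sb$site_class == "synonymous", , drop = FALSE]  # bin-level
    for (st in binStats) {
      vm <- matrix(NA_real_, nRedraws, length(sizes))
      for (r in seq_len(nRedraws)) {
        sr <- scl[scl$redraw == r, , drop = FALSE]
        vm[r, ] <- sr[[st]][match(sizes, sr$sample_size)]
      }
      rows[[length(rows) + 1L]] <-
        .seriesSummary(b, NA_character_, st, sizes, vm, nLo, nHi)
    }
    do.call(rbind, rows)
  }))
  rownames(summaries) <- NULL

  new("SweepResult", stats = stats, summaries = summaries,
      meta = list(sizes = sizes, nRedraws = nRedraws, seed = seed,
                  sampleUnit = "individuals (diploid); n_seq = 2 * size",
                  binEdges = binEdges, nLo = nLo, nHi = nHi))
}

#' Nonsynonymous-to-synonymous theta ratio by sample size
#'
#' Redraw-mean ratio of per-site Watterson's theta at nonsynonymous versus
#' synonymous sites, per sample size, from a sweep result. A ratio rising
#' with sample size indicates that larger panels surface proportionally
#' more (rare, constrained) nonsynonymous variation.
#'
#' @param sweep a [SweepResult-class].
#' @param bin which gene bin to use (default the pooled `"all"` bin).
#' @return data.frame with columns `sample_size` and `theta_ratio`.
#' @export
thetaRatioBySize <- function(sweep, bin = "all") {
  stopifnot(is(sweep, "SweepResult"))
  st <- sweep@stats[sweep@stats$bin == bin, , drop = FALSE]
  if (!nrow(st)) stop("bin not present in sweep: ", bin, call. = FALSE)
  out <- do.call(rbind, lapply(split(st, st$sample_size), function(d) {
    ratios <- vapply(split(d, d$redraw), function(dd) {
      thN <- dd$theta_w[dd$site_class == "nonsynonymous"]
      thS <- dd$theta_w[dd$site_class == "synonymous"]
      if (length(thN) && length(thS) && is.finite(thS) && thS > 0)
        thN / thS else NA_real_
    }, numeric(1))
    data.frame(sample_size = d$sample_size[1L],
               theta_ratio = mean(ratios, na.rm = TRUE))
  }))
  out <- out[order(out$sample_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}
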