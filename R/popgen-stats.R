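#' @include accessors.R
NULL

#' Harmonic numbers used by spectrum statistics
#'
#' Returns `a1 = sum(1/i)` and `a2 = sum(1/i^2)` for `i = 1 .. n - 1`, the
#' harmonic sums that normalize the segregating-site count in Watterson's
#' estimator and enter every variance constant below.
#'
#' @param nSeq number of sequences, an integer >= 2.
#' @return Named numeric vector with elements `a1` and `a2`.
#' @examples
#' harmonicNumbers(2)   # c(a1 = 1, a2 = 1)
#' harmonicNumbers(16)
#' @export
harmonicNumbers <- function(nSeq) {
  nSeq <- .checkNSeq(nSeq, min = 2L)
  i <- seq_len(nSeq - 1L)
  c(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

.checkNSeq <- function(nSeq, min = 2L) {
  if (length(nSeq) != 1L || is.na(nSeq) || nSeq != as.integer(nSeq) ||
      nSeq < min)
    stop("invalid sample size: nSeq must be a single integer >= ", min,
         call. = FALSE)
  as.integer(nSeq)
}

#' Variance constants of Tajima's D
#'
#' The constants b1, b2, c1, c2, e1, e2 of Tajima's (1989) test statistic,
#' computed from the harmonic numbers for a sample of `nSeq` sequences.
#'
#' @param nSeq number of sequences, >= 3 (the variance is undefined below
#'   that).
#' @return Named numeric vector `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @seealso [tajimaD()]
#' @export
tajimaConstants <- function(nSeq) {
  n <- as.numeric(.checkNSeq(nSeq, min = 3L))
  h <- harmonicNumbers(nSeq)
  a1 <- h[["a1"]]; a2 <- h[["a2"]]
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
    e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Variance constants of Fu and Li's D* (no outgroup)
#'
#' The constants u_D* and v_D* of the D* statistic, using the corrected
#' expressions (Simonsen, Churchill & Aquadro 1995 erratum to Fu & Li 1993,
#' p. 701):
#' \deqn{c_n = 2 (n a_n - 2(n-1)) / ((n-1)(n-2))}
#' \deqn{d_n = c_n + (n-2)/(n-1)^2 + (2/(n-1)) (3/2 - (2 a_{n+1} - 3)/(n-2) - 1/n)}
#' \deqn{v_{D^*} = [ (n/(n-1))^2 b_n + a_n^2 d_n - 2 n a_n (a_n+1)/(n-1)^2 ] / (a_n^2 + b_n)}
#' \deqn{u_{D^*} = (n/(n-1)) (a_n - n/(n-1)) - v_{D^*}}
#' where `a_n`, `b_n` are the harmonic numbers and `a_{n+1} = a_n + 1/n`.
#'
#' @param nSeq number of sequences, >= 3.
#' @return Named numeric vector `an, uD, vD`.
#' @seealso [fuLiDStar()]
#' @export
fuLiConstants <- function(nSeq) {
  n <- as.numeric(.checkNSeq(nSeq, min = 3L))
  h <- harmonicNumbers(nSeq)
  an <- h[["a1"]]; bn <- h[["a2"]]
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  ud <- (n / (n - 1)) * (an - n / (n - 1)) - vd
  c(an = an, uD = ud, vD = vd)
}

.checkSfs <- function(sfs) {
  if (!is(sfs, "SiteFrequencySpectrum"))
    stop("expected a SiteFrequencySpectrum", call. = FALSE)
  validObject(sfs)
  invisible(sfs)
}

#' Watterson's estimator of the scaled mutation rate
#'
#' Per-site Watterson's theta, `(S / a1) / nSites`, where S is the number of
#' segregating sites and `a1` the harmonic number of the sample size. Under
#' neutrality and constant population size its expectation is `4 Ne mu`
#' independent of sample size; an excess of rare variants (population growth,
#' purifying selection) makes it rise with sample size because larger samples
#' reveal more rare segregating sites.
#'
#' @param x a [SiteFrequencySpectrum-class] with `nSites > 0`.
#' @param ... unused.
#' @return Per-site theta (numeric scalar).
#' @examples
#' wattersonTheta(SiteFrequencySpectrum(20, nSeq = 2, nSites = 1000)) # 0.02
#' @export
setMethod("wattersonTheta", "SiteFrequencySpectrum", function(x, ...) {
  .checkSfs(x)
  if (x@nSites <= 0)
    stop("empty region: nSites must be > 0", call. = FALSE)
  S <- sum(x@counts)
  if (S == 0) return(0)
  a1 <- harmonicNumbers(x@nSeq)[["a1"]]
  (S / a1) / x@nSites
})

#' Nucleotide diversity from a folded spectrum
#'
#' Per-site mean number of pairwise nucleotide differences,
#' `sum_m counts[m] * m * (n - m) / choose(n, 2) / nSites`. Each segregating
#' site with minor-allele count m contributes `m (n - m)` differing pairs out
#' of `choose(n, 2)`, so this folded-spectrum form equals the mean pairwise
#' Hamming distance per site over the sampled sequences. Its expectation is
#' invariant to subsampling, which is why diversity-based estimates are flat
#' in sample size where Watterson's theta is not.
#'
#' @param x a [SiteFrequencySpectrum-class] with `nSites > 0`.
#' @param ... unused.
#' @return Per-site pi (numeric scalar).
#' @export
setMethod("nucleotideDiversity", "SiteFrequencySpectrum", function(x, ...) {
  .checkSfs(x)
  if (x@nSites <= 0)
    stop("empty region: nSites must be > 0", call. = FALSE)
  n <- as.numeric(x@nSeq)
  m <- seq_along(x@counts)
  sum(x@counts * m * (n - m)) / choose(n, 2) / x@nSites
})

#' Tajima's D
#'
#' The normalized difference between the diversity-based and the
#' segregating-site-based estimators of the scaled mutation rate:
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with k the per-locus mean
#' pairwise difference and the variance constants of [tajimaConstants()].
#' Under neutrality the two estimators have equal expectation and D is near
#' zero; an excess of rare variants drives D negative.
#'
#' For `S = 0` the statistic is undefined and `NA_real_` is returned (with a
#' warning), never 0: per-gene spectra at small sample sizes frequently have
#' no segregating sites and an undefined value must stay distinguishable from
#' a vanishing numerator.
#'
#' @param x a [SiteFrequencySpectrum-class]; `nSeq` must be >= 3.
#' @param ... unused.
#' @return Tajima's D (numeric scalar), or `NA_real_` if undefined.
#' @export
setMethod("tajimaD", "SiteFrequencySpectrum", function(x, ...) {
  .checkSfs(x)
  n <- .checkNSeq(x@nSeq, min = 3L)
  S <- sum(x@counts)
  if (S == 0) {
    warning("Tajima's D is undefined for S = 0; returning NA", call. = FALSE)
    return(NA_real_)
  }
  cst <- tajimaConstants(n)
  k <- nucleotideDiversity(x) * x@nSites
  (k - S / cst[["a1"]]) /
    sqrt(cst[["e1"]] * S + cst[["e2"]] * S * (S - 1))
})

#' Fu and Li's D* (no outgroup)
#'
#' The singleton-based neutrality test that needs no ancestral-state call:
#' `D* = ((n/(n-1)) eta - a_n eta_s) / sqrt(uD eta + vD eta^2)`, where eta is
#' the total number of segregating sites, eta_s the number of minor-allele
#' singletons, and uD, vD the corrected constants of [fuLiConstants()].
#' Segregating-site and singleton-site counts stand in for the total and
#' singleton mutation counts of the underlying genealogy.
#'
#' Undefined for `eta = 0`; returns `NA_real_` with a warning (see
#' [tajimaD()] for the rationale).
#'
#' @param x a [SiteFrequencySpectrum-class]; `nSeq` must be >= 3.
#' @param ... unused.
#' @return D* (numeric scalar), or `NA_real_` if undefined.
#' @export
setMethod("fuLiDStar", "SiteFrequencySpectrum", function(x, ...) {
  .checkSfs(x)
  n <- as.numeric(.checkNSeq(x@nSeq, min = 3L))
  eta <- sum(x@counts)
  if (eta == 0) {
    warning("Fu-Li D* is undefined for eta = 0; returning NA", call. = FALSE)
    return(NA_real_)
  }
  etaS <- x@counts[1L]
  cst <- fuLiConstants(x@nSeq)
  denom <- cst[["uD"]] * eta + cst[["vD"]] * eta^2
  if (denom <= 0) {
    # n = 3 folded: every segregating site is a singleton and both variance
    # constants vanish identically -- the statistic is degenerate
    warning("Fu-Li D* is degenerate for this sample size; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  ((n / (n - 1)) * eta - cst[["an"]] * etaS) / sqrt(denom)
})

#' Fold a genotype dosage matrix into a site frequency spectrum
#'
#' Tallies, per site, the minor-allele count over `ploidy * nSamples`
#' sequences. Monomorphic sites contribute to `nSites` but not to the
#' spectrum. Dosages must be complete (no NA) and bi-allelic
#' (`0 .. ploidy`); sites with missing calls should be dropped upstream
#' (listwise per site) before calling this.
#'
#' @param dosages integer matrix, sites x samples, entries in `0 .. ploidy`.
#' @param ploidy number of haploid genomes per sample (2 for diploid).
#' @param nSites total surveyed sites for per-site scaling; defaults to
#'   `nrow(dosages)`, i.e. a spectrum over exactly the assayed sites (per
#'   class, when `siteClass` is a per-site mask).
#' @param siteClass either a single class label for the resulting spectrum,
#'   or a per-site label vector (length `nrow(dosages)`), in which case one
#'   spectrum per class is returned.
#' @return A [SiteFrequencySpectrum-class], or a named list of them for a
#'   per-site `siteClass` mask.
#' @examples
#' g <- matrix(c(0, 1, 0, 0), nrow = 2)  # 2 sites x 2 samples
#' sfsFromGenotypes(g, ploidy = 2, nSites = 10)
#' @export
sfsFromGenotypes <- function(dosages, ploidy = 2L, nSites = nrow(dosages),
                             siteClass = "unlabeled") {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  ploidy <- as.integer(ploidy)
  if (length(siteClass) > 1L) {
    if (length(siteClass) != nrow(dosages))
      stop("invalid input: per-site siteClass must match nrow(dosages)",
           call. = FALSE)
    cls <- unique(siteClass)
    return(setNames(lapply(cls, function(cl)
      sfsFromGenotypes(dosages[siteClass == cl, , drop = FALSE],
                       ploidy = ploidy, nSites = sum(siteClass == cl),
                       siteClass = cl)), cls))
  }
  if (anyNA(dosages))
    stop("invalid input: missing dosages; drop incomplete sites first",
         call. = FALSE)
  if (length(dosages) && (min(dosages) < 0 || max(dosages) > ploidy))
    stop("invalid input: dosages must lie in 0..ploidy (bi-allelic)",
         call. = FALSE)
  n <- ploidy * ncol(dosages)
  ac <- as.integer(round(rowSums(dosages)))
  minor <- pmin(ac, n - ac)
  minor <- minor[minor > 0L]
  counts <- tabulate(minor, nbins = n %/% 2L)
  SiteFrequencySpectrum(counts, nSeq = n, nSites = nSites,
                        siteClass = siteClass)
}
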