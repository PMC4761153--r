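# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# mean pairwise Hamming distance per site over the columns of a haplotype
# matrix (sites x haplotypes, entries 0/1)
bruteForcePi <- function(hap, nSites = nrow(hap)) {
  n <- ncol(hap)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + sum(hap[, i] != hap[, j])
  tot / choose(n, 2) / nSites
}

# folded spectrum of a haplotype matrix by direct per-site tally
bruteForceFoldedCounts <- function(hap) {
  n <- ncol(hap)
  ac <- rowSums(hap)
  minor <- pmin(ac, n - ac)
  tabulate(minor[minor > 0], nbins = n %/% 2L)
}

# Kendall tau by O(n^2) concordant/discordant pair counting (no ties in x)
bruteForceKendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  (conc - disc) / choose(n, 2)
}

# Monte Carlo coalescent expectation of per-locus Watterson theta under a
# piecewise constant/exponential diploid size schedule (independent of the
# package's ODE-based integrator). Epoch waiting times are drawn in
# coalescent time and mapped to generations through the schedule's
# closed-form time change.
mcCoalescentTheta <- function(nSeq, demography, mu, L, nRep = 4000,
                              seed = 1) {
  ph <- demography@phases
  ph <- ph[rev(seq_len(nrow(ph))), , drop = FALSE]  # most recent first
  r <- ifelse(ph$mode == "exponential",
              log(ph$endSize / ph$startSize) / ph$duration, 0)
  Nrec <- ph$endSize
  dtau <- ifelse(r != 0, (exp(r * ph$duration) - 1) / (2 * Nrec * r),
                 ph$duration / (2 * Nrec))
  cumtau <- c(0, cumsum(dtau))
  # generations elapsed between coalescent times 0..tau
  gensAt <- function(tau) {
    g <- 0
    for (i in seq_along(dtau)) {
      d <- min(tau - cumtau[i], dtau[i])
      if (i == length(dtau)) d <- tau - cumtau[i]  # oldest phase extended
      if (d <= 0) break
      g <- g + if (r[i] != 0)
        log(1 + 2 * Nrec[i] * r[i] * d) / r[i]
      else 2 * Nrec[i] * d
    }
    g
  }
  set.seed(seed)
  a1 <- sum(1 / seq_len(nSeq - 1))
  tot <- numeric(nRep)
  for (rep in seq_len(nRep)) {
    ks <- nSeq:2
    waits <- stats::rexp(length(ks), rate = ks * (ks - 1) / 2)
    bounds <- cumsum(c(0, waits))
    tgen <- vapply(bounds, gensAt, numeric(1))
    tot[rep] <- sum(ks * diff(tgen))
  }
  list(theta = mu * L * mean(tot) / a1,
       se = mu * L * stats::sd(tot) / sqrt(nRep) / a1)
}

# a random feasible folded spectrum for a panel of nSeq sequences
randomFeasibleSFS <- function(nSeq, nSites, maxS = 50, siteClass = "synonymous") {
  nb <- nSeq %/% 2L
  counts <- stats::rmultinom(1, sample.int(min(maxS, nSites), 1),
                             prob = 1 / seq_len(nb))[, 1]
  SiteFrequencySpectrum(counts, nSeq = nSeq, nSites = nSites,
                        siteClass = siteClass)
}

# Poisson Random Field expectation of segregating sites at mutation-drift-
# selection equilibrium (constant N, genic selection h = 1/2): a deleterious
# allele with scaled coefficient g = 2Ns contributes the standing density
#   f(x) = theta/(x(1-x)) * exp(-g x)(1 - exp(-g(1-x))) / (1 - exp(-g)),
# and E[S_n] = theta * L * int f(x) (1 - x^n - (1-x)^n) dx with
# theta = 4 N mu per site. gammaMean = 0 gives the neutral 1/x density.
prfExpectedS <- function(n, gammaMean, shape = 0.206, thetaSite, L,
                         nx = 20001) {
  x <- seq(1e-7, 1 - 1e-7, length.out = nx)
  seg <- 1 - x^n - (1 - x)^n
  one <- function(g) {
    dens <- if (g < 1e-8) 1 / x
    else exp(-g * x) * (1 - exp(-pmin(g * (1 - x), 700))) /
      ((1 - exp(-min(g, 700))) * x * (1 - x))
    sum(dens * seg) * (x[2] - x[1])
  }
  val <- if (gammaMean == 0) one(0) else {
    gs <- exp(seq(log(1e-4), log(1e6), length.out = 300))
    w <- stats::dgamma(gs, shape = shape, scale = gammaMean / shape)
    vals <- vapply(gs, one, numeric(1))
    # trapezoid over the gamma mixture, normalized
    tz <- function(y) sum(diff(gs) * (y[-1] + y[-length(y)]) / 2)
    tz(w * vals) / tz(w)
  }
  thetaSite * L * val
}

prfExpectedTheta <- function(n, gammaMean, shape = 0.206, thetaSite, L) {
  prfExpectedS(n, gammaMean, shape, thetaSite, L) /
    sum(1 / seq_len(n - 1)) / L
}
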