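#' @include wf-simulator.R
#' @importFrom deSolve ode
NULL

# Backward-time view of a schedule: one row per phase, most recent first,
# with the diploid size at the recent edge (Nrecent), the backward rate r
# (forward exponential rate; N(u) = Nrecent * exp(-r * u) at backward time u
# within the phase), the phase duration, and the coalescent-time capacity
# dtau of the phase. The oldest phase is extended to infinity at its
# ancestral size.
.backwardPhases <- function(demography) {
  ph <- demography@phases
  ph <- ph[rev(seq_len(nrow(ph))), , drop = FALSE]
  r <- ifelse(ph$mode == "exponential",
              log(ph$endSize / ph$startSize) / ph$duration, 0)
  dtau <- ifelse(r != 0,
                 (exp(r * ph$duration) - 1) / (2 * ph$endSize * r),
                 ph$duration / (2 * ph$endSize))
  data.frame(duration = ph$duration, Nrecent = ph$endSize,
             Nold = ph$startSize, r = r, dtau = dtau)
}

# diploid size at cumulative coalescent time tau before the present
.sizeAtTau <- function(tau, bwd) {
  N <- numeric(length(tau))
  lo <- 0
  done <- rep(FALSE, length(tau))
  for (i in seq_len(nrow(bwd))) {
    hi <- lo + bwd$dtau[i]
    last <- i == nrow(bwd)
    sel <- !done & (tau <= hi | last)
    if (any(sel)) {
      dt <- tau[sel] - lo
      if (last) dt <- pmin(dt, bwd$dtau[i])  # oldest phase: constant beyond
      if (bwd$r[i] != 0) {
        u <- log(pmax(1 + 2 * bwd$Nrecent[i] * bwd$r[i] * dt, 1e-300)) /
          bwd$r[i]
        N[sel] <- bwd$Nrecent[i] * exp(-bwd$r[i] * pmin(u, bwd$duration[i]))
      } else {
        N[sel] <- bwd$Nrecent[i]
      }
      done[sel] <- TRUE
    }
    lo <- hi
  }
  N[!done] <- bwd$Nold[nrow(bwd)]
  N
}

#' Expected neutral Watterson's theta under a demographic schedule
#'
#' Deterministic coalescent expectation of the per-locus Watterson estimator
#' for a neutral sample of `nSeq` haplotypes drawn at the end of the
#' schedule: `E[theta_W] = mu * L * E[T_total] / a_n`, with the expected
#' total tree length obtained by numerical integration of the
#' ancestral-lineage pure-death process. In coalescent time tau (generations
#' rescaled by 1/(2N(t))) the number of ancestral lineages is a Markov death
#' chain with rates `choose(k, 2)`; its state distribution is integrated
#' with a stiff ODE solver and the expected lineage count mapped back to
#' generations through the analytic time change of the piecewise
#' constant/exponential schedule.
#'
#' For a constant-size schedule this reduces to `4 Ne mu L` for every
#' sample size (the `a_n` factors cancel), the classic sample-size-free
#' neutral expectation. The value is invariant under [rescaleConfig()]'s
#' theta-preserving rescaling.
#'
#' @param nSeq number of haplotypes sampled (>= 2).
#' @param demography a [DemographySchedule-class].
#' @param mu mutation rate per site per generation (on the same scale as the
#'   schedule, i.e. rescaled if the schedule is).
#' @param L locus length in sites.
#' @param tauMax integration horizon in coalescent time units (the lineage
#'   process is extinct to machine precision well before the default).
#' @return Expected per-locus Watterson theta (numeric scalar); divide by
#'   `L` for the per-site value.
#' @examples
#' d <- DemographySchedule(duration = 1000, startSize = 500)
#' expectedThetaNeutral(16, d, mu = 1e-6, L = 5000)  # ~ 4 * 500 * 1e-6 * 5000
#' @export
expectedThetaNeutral <- function(nSeq, demography, mu, L, tauMax = 30) {
  n <- .checkNSeq(nSeq, min = 2L)
  stopifnot(is(demography, "DemographySchedule"))
  bwd <- .backwardPhases(demography)

  # output grid: geometric (resolves the fast initial decay from n lineages)
  # plus the phase boundaries in tau
  bounds <- cumsum(bwd$dtau)
  taug <- sort(unique(c(0, exp(seq(log(1e-9), log(tauMax), length.out = 1200)),
                        bounds[bounds < tauMax])))

  ks <- 2:n
  lam <- ks * (ks - 1) / 2
  y0 <- c(rep(0, n - 2L), 1)
  deriv <- function(t, y, parms) {
    flux <- lam * y
    dy <- -flux
    if (n > 2L) dy[-(n - 1L)] <- dy[-(n - 1L)] + flux[-1L]
    list(dy)
  }
  sol <- deSolve::ode(y = y0, times = taug, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  h <- as.numeric(sol[, -1, drop = FALSE] %*% ks)  # E[branch count | >= 2]

  f <- h * 2 * .sizeAtTau(taug, bwd)
  eT <- sum(diff(taug) * (f[-1] + f[-length(f)]) / 2)
  a1 <- harmonicNumbers(n)[["a1"]]
  mu * L * eT / a1
}
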