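#' @include popgen-stats.R
#' @useDynLib thetaSweep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Demographic timing of the two-branch human-like growth model. The anchor
# sizes are Ne = 10,000 ancestral, 9,210 after the shared slow-growth phase,
# and 512,210 at the end of the exponential branch; the bottleneck size at
# the split, the slow-growth duration and the final-epoch duration are a
# reconstruction from two-epoch human growth models (out-of-Africa
# bottleneck ~1,032 diploids, ~0.3 %/generation slow growth; see the
# package vignette) and are fully overridable here.
.DEMOG_DEFAULTS <- list(burnIn = 200000, bottleneckNe = 1032,
                        slowDuration = 715, finalDuration = 920,
                        ancestralNe = 10000, splitNe = 9210,
                        finalNe = 512210)

#' Two-branch growth demographies
#'
#' Convenience constructors for the two scenarios of the simulation study.
#' An ancestral population of `ancestralNe` diploids (held there for
#' `burnIn` generations to reach mutation-drift equilibrium) splits in two
#' daughter populations that start at `bottleneckNe` and grow at the same
#' slow exponential rate until they reach `splitNe`. The constant branch
#' then remains at `splitNe` for `finalDuration` generations, while the
#' exponential branch grows exponentially to `finalNe` over the same
#' period. Branches exchange no migrants, so each schedule describes the
#' sampled branch only.
#'
#' @param ancestralNe ancestral diploid size (default 10,000).
#' @param bottleneckNe daughter-population size at the split (default
#'   1,032, the classic out-of-Africa bottleneck estimate).
#' @param splitNe size at the end of the shared slow-growth phase (default
#'   9,210).
#' @param finalNe final size of the exponential branch (default 512,210).
#' @param burnIn equilibration duration in generations at `ancestralNe`.
#' @param slowDuration duration of the shared slow-growth phase (default
#'   715 generations, ~0.3 %/generation).
#' @param finalDuration duration of the final (constant or exponential)
#'   epoch.
#' @return A [DemographySchedule-class].
#' @examples
#' demographyConstant()
#' demographyExponential()
#' @export
demographyConstant <- function(ancestralNe = .DEMOG_DEFAULTS$ancestralNe,
                               bottleneckNe = .DEMOG_DEFAULTS$bottleneckNe,
                               splitNe = .DEMOG_DEFAULTS$splitNe,
                               burnIn = .DEMOG_DEFAULTS$burnIn,
                               slowDuration = .DEMOG_DEFAULTS$slowDuration,
                               finalDuration = .DEMOG_DEFAULTS$finalDuration) {
  DemographySchedule(
    duration = c(burnIn, slowDuration, finalDuration),
    startSize = c(ancestralNe, bottleneckNe, splitNe),
    endSize = c(ancestralNe, splitNe, splitNe),
    mode = c("constant", "exponential", "constant"),
    branch = "constant-branch")
}

#' @rdname demographyConstant
#' @export
demographyExponential <- function(ancestralNe = .DEMOG_DEFAULTS$ancestralNe,
                                  bottleneckNe = .DEMOG_DEFAULTS$bottleneckNe,
                                  splitNe = .DEMOG_DEFAULTS$splitNe,
                                  finalNe = .DEMOG_DEFAULTS$finalNe,
                                  burnIn = .DEMOG_DEFAULTS$burnIn,
                                  slowDuration = .DEMOG_DEFAULTS$slowDuration,
                                  finalDuration = .DEMOG_DEFAULTS$finalDuration) {
  DemographySchedule(
    duration = c(burnIn, slowDuration, finalDuration),
    startSize = c(ancestralNe, bottleneckNe, splitNe),
    endSize = c(ancestralNe, splitNe, finalNe),
    mode = c("constant", "exponential", "exponential"),
    branch = "exponential-branch")
}

#' Theta-preserving population rescaling
#'
#' Divides all population sizes and phase durations by `lambda` and
#' multiplies the mutation rate (and, through the unchanged scaled
#' coefficient gamma = 2*Ne*s, the selection coefficients) by `lambda`. All
#' population-scaled quantities -- theta = 4*Ne*mu, gamma, and the coalescent
#' time scale measured in units of 2*Ne generations -- are invariant, so the
#' expected neutral theta is unchanged (assertable with
#' [expectedThetaNeutral()]) while runtime shrinks by roughly lambda squared.
#'
#' @param config a [SimulationConfig-class].
#' @param lambda rescaling factor >= 1. Fails if the rescaled final
#'   population is too small for the largest requested haplotype sample.
#' @return The rescaled [SimulationConfig-class] (slot `lambda` records the
#'   cumulative factor).
#' @export
rescaleConfig <- function(config, lambda) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 1)
    stop("config error: lambda must be a single number >= 1", call. = FALSE)
  if (lambda == 1) return(config)
  dem <- config@demography
  ph <- dem@phases
  ph$duration <- ph$duration / lambda
  ph$startSize <- ph$startSize / lambda
  ph$endSize <- ph$endSize / lambda
  finalN <- ph$endSize[nrow(ph)]
  if (max(config@sampleSizes) > 2 * floor(finalN))
    stop(sprintf(
      "config error: lambda = %g leaves %g diploids, too few for %d haplotypes",
      lambda, floor(finalN), max(config@sampleSizes)), call. = FALSE)
  dem@phases <- ph
  config@demography <- dem
  config@mu <- config@mu * lambda
  config@lambda <- config@lambda * lambda
  validObject(config)
  config
}

.selectionScale <- function(config) {
  # rescaled mean selection coefficient: gamma = 2 * baseNe * s is held
  # fixed, so s' = s * lambda = meanGamma / (2 baseNe) * lambda
  config@dfe@meanGamma / (2 * config@baseNe) * config@lambda
}

#' Run the forward Wright-Fisher simulation
#'
#' Evolves `nReplicates` independent 5 kb loci through the configured
#' demographic schedule under the infinite-sites mutation model and genic
#' (semidominant) purifying selection with gamma-distributed scaled
#' coefficients, then draws the configured haplotype sample sizes (nested,
#' without replacement) at the final generation and folds each into minor-
#' allele site frequency spectra, separately for neutral and selected
#' mutations.
#'
#' Selection coefficients exceeding 1 after rescaling are capped at 1 (such
#' mutations are effectively lethal at any value past that point); the
#' capped fraction is reported in the result's `diagnostics`. All
#' stochasticity flows from `config@seed`: replicate r uses a deterministic
#' substream, so runs are bit-reproducible.
#'
#' @param config a [SimulationConfig-class], typically after
#'   [rescaleConfig()].
#' @return A list of class `"wfReplicates"`: one element per replicate, each
#'   a list with one entry per sample size holding the `neutral` and
#'   `constrained` [SiteFrequencySpectrum-class] objects; attribute
#'   `diagnostics` carries mutation/cap/fixation tallies and the config.
#' @seealso [summariseReplicates()] for the tidy per-replicate statistics
#'   table, [expectedThetaNeutral()] for the neutral expectation.
#' @export
runSimulation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  ph <- config@demography@phases
  gens <- pmax(1L, as.integer(round(ph$duration)))
  nf <- config@dfe@neutralFraction
  meanS <- .selectionScale(config)
  L <- as.integer(config@seqLength)
  szs <- sort(config@sampleSizes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config@seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, config@nReplicates)

  nsitesNeutral <- config@seqLength * nf
  nsitesSel <- config@seqLength * (1 - nf)
  diag <- c(n_mutations = 0, n_capped = 0, fixed_neutral = 0,
            fixed_selected = 0)
  reps <- vector("list", config@nReplicates)
  for (r in seq_len(config@nReplicates)) {
    set.seed(subSeeds[r])
    res <- .wf_simulate_locus(L, config@mu, gens, ph$startSize, ph$endSize,
                              as.integer(ph$mode == "exponential"),
                              config@dfe@shape, meanS, nf, szs)
    diag <- diag + unlist(res[c("n_mutations", "n_capped", "fixed_neutral",
                                "fixed_selected")])
    rep <- lapply(res$sfs, function(rec) {
      out <- list()
      if (nf > 0)
        out$neutral <- SiteFrequencySpectrum(
          rec$neutral, nSeq = rec$n, nSites = nsitesNeutral,
          siteClass = "neutral")
      if (nf < 1)
        out$constrained <- SiteFrequencySpectrum(
          rec$selected, nSeq = rec$n, nSites = nsitesSel,
          siteClass = "constrained")
      out
    })
    names(rep) <- paste0("n", szs)
    reps[[r]] <- rep
  }
  structure(reps, class = "wfReplicates",
            diagnostics = c(as.list(diag),
                            cappedFraction = unname(
                              if (diag[["n_mutations"]] > 0)
                                diag[["n_capped"]] / diag[["n_mutations"]]
                              else 0)),
            config = config)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Tidy per-replicate statistics of a simulation run
#'
#' Computes S, singleton count, per-site Watterson's theta and nucleotide
#' diversity for every replicate, sample size and site class of a
#' [runSimulation()] result.
#'
#' @param reps a `"wfReplicates"` object.
#' @return data.frame with columns `replicate`, `sample_size`, `site_class`,
#'   `S`, `singletons`, `theta_w`, `pi`, `n_sites`.
#' @export
summariseReplicates <- function(reps) {
  stopifnot(inherits(reps, "wfReplicates"))
  rows <- lapply(seq_along(reps), function(r) {
    szrecs <- reps[[r]]
    do.call(rbind, lapply(szrecs, function(classes) {
      do.call(rbind, lapply(classes, function(sfs) {
        data.frame(replicate = r, sample_size = nSeq(sfs),
                   site_class = siteClass(sfs), S = segSites(sfs),
                   singletons = unname(singletons(sfs)),
                   theta_w = wattersonTheta(sfs),
                   pi = nucleotideDiversity(sfs), n_sites = nSites(sfs))
      }))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean per-site theta and pi by sample size
#'
#' Replicate means of Watterson's theta and nucleotide diversity per sample
#' size for one site class, with Monte-Carlo standard errors.
#'
#' @param reps a `"wfReplicates"` object.
#' @param siteClass `"neutral"` or `"constrained"`.
#' @return data.frame with columns `sample_size`, `theta_w`, `theta_se`,
#'   `pi`, `pi_se`, `n_replicates`.
#' @export
meanThetaBySize <- function(reps, siteClass = c("neutral", "constrained")) {
  siteClass <- match.arg(siteClass)
  tab <- summariseReplicates(reps)
  tab <- tab[tab$site_class == siteClass, , drop = FALSE]
  if (!nrow(tab))
    stop("no replicates carry site class '", siteClass, "'", call. = FALSE)
  agg <- do.call(rbind, lapply(split(tab, tab$sample_size), function(d) {
    data.frame(sample_size = d$sample_size[1L], theta_w = mean(d$theta_w),
               theta_se = stats::sd(d$theta_w) / sqrt(nrow(d)),
               pi = mean(d$pi), pi_se = stats::sd(d$pi) / sqrt(nrow(d)),
               n_replicates = nrow(d))
  }))
  agg <- agg[order(agg$sample_size), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
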