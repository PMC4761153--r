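#' @import methods
NULL

.SITE_CLASSES <- c("synonymous", "nonsynonymous", "neutral", "constrained",
                   "unlabeled")

#' Folded site frequency spectrum
#'
#' Container for a folded (minor-allele) site frequency spectrum of one site
#' class: a histogram of segregating sites indexed by minor-allele count
#' m = 1 .. floor(nSeq/2), together with the number of sequences sampled and
#' the total number of surveyed sites (monomorphic sites included) used for
#' per-site scaling. All spectrum statistics in this package
#' ([wattersonTheta()], [nucleotideDiversity()], [tajimaD()], [fuLiDStar()])
#' operate on this class.
#'
#' @slot nSeq integer(1), number of sequences (haploid genomes) sampled;
#'   at least 2.
#' @slot counts numeric vector of length `floor(nSeq/2)`; `counts[m]` is the
#'   number of segregating sites whose minor allele occurs `m` times.
#' @slot nSites numeric(1), total surveyed sites; `sum(counts) <= nSites`.
#' @slot siteClass character(1), one of `"synonymous"`, `"nonsynonymous"`,
#'   `"neutral"`, `"constrained"`, `"unlabeled"`.
#'
#' @seealso [SiteFrequencySpectrum()] for the constructor,
#'   [sfsFromGenotypes()] to build one from a dosage matrix.
#' @name SiteFrequencySpectrum-class
#' @rdname SiteFrequencySpectrum-class
#' @exportClass SiteFrequencySpectrum
setClass("SiteFrequencySpectrum",
  representation(nSeq = "integer", counts = "numeric", nSites = "numeric",
                 siteClass = "character"))

setValidity("SiteFrequencySpectrum", function(object) {
  msg <- character()
  if (length(object@nSeq) != 1L || is.na(object@nSeq) || object@nSeq < 2L)
    msg <- c(msg, "nSeq must be a single integer >= 2")
  else {
    if (length(object@counts) != object@nSeq %/% 2L)
      msg <- c(msg, "length(counts) must equal floor(nSeq/2)")
    if (any(is.na(object@counts)) || any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(object@nSites) != 1L || is.na(object@nSites) ||
        object@nSites < 0)
      msg <- c(msg, "nSites must be a single non-negative number")
    else if (sum(object@counts) > object@nSites)
      msg <- c(msg, "sum(counts) (segregating sites) cannot exceed nSites")
  }
  if (length(object@siteClass) != 1L ||
      !object@siteClass %in% .SITE_CLASSES)
    msg <- c(msg, paste("siteClass must be one of:",
                        paste(.SITE_CLASSES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a folded site frequency spectrum
#'
#' @param counts numeric vector of segregating-site counts by minor-allele
#'   count `1 .. floor(nSeq/2)`. A named or shorter vector is right-padded
#'   with zeros.
#' @param nSeq number of sequences (haploid genomes) sampled.
#' @param nSites total number of surveyed sites.
#' @param siteClass site-class label.
#' @return A [SiteFrequencySpectrum-class] object.
#' @examples
#' sfs <- SiteFrequencySpectrum(c(5, 2, 1), nSeq = 10, nSites = 1000)
#' segSites(sfs)
#' wattersonTheta(sfs)
#' @export
SiteFrequencySpectrum <- function(counts, nSeq, nSites,
                                  siteClass = "unlabeled") {
  nSeq <- as.integer(nSeq)
  nb <- if (length(nSeq) == 1L && !is.na(nSeq) && nSeq >= 2L)
    nSeq %/% 2L else length(counts)
  if (length(counts) < nb)
    counts <- c(counts, rep(0, nb - length(counts)))
  new("SiteFrequencySpectrum", nSeq = nSeq, counts = as.numeric(counts),
      nSites = as.numeric(nSites), siteClass = siteClass)
}

#' McDonald-Kreitman counts
#'
#' The 2x2 McDonald-Kreitman contingency table: nonsynonymous and synonymous
#' polymorphic site counts within a species (`Pn`, `Ps`) against nonsynonymous
#' and synonymous fixed differences between species (`Dn`, `Ds`). Additive
#' under aggregation over genes (see [aggregateMK()]).
#'
#' @slot Pn,Ps,Dn,Ds numeric(1) non-negative counts.
#' @seealso [MKCounts()], [neutralityIndex()], [alphaAdaptive()]
#' @name MKCounts-class
#' @rdname MKCounts-class
#' @exportClass MKCounts
setClass("MKCounts",
  representation(Pn = "numeric", Ps = "numeric", Dn = "numeric",
                 Ds = "numeric"))

setValidity("MKCounts", function(object) {
  v <- c(object@Pn, object@Ps, object@Dn, object@Ds)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    "Pn, Ps, Dn, Ds must each be a single non-negative count"
  else TRUE
})

#' Construct a McDonald-Kreitman table
#'
#' @param Pn,Ps nonsynonymous / synonymous polymorphic site counts.
#' @param Dn,Ds nonsynonymous / synonymous fixed-difference counts.
#' @return An [MKCounts-class] object.
#' @examples
#' mk <- MKCounts(Pn = 10, Ps = 5, Dn = 4, Ds = 4)
#' neutralityIndex(mk)
#' alphaAdaptive(mk)
#' @export
MKCounts <- function(Pn = 0, Ps = 0, Dn = 0, Ds = 0) {
  new("MKCounts", Pn = as.numeric(Pn), Ps = as.numeric(Ps),
      Dn = as.numeric(Dn), Ds = as.numeric(Ds))
}

#' Demographic schedule of the sampled population
#'
#' An ordered, forward-in-time sequence of phases describing the diploid
#' effective size of the population the sample is drawn from. Each phase is
#' constant or exponential (size interpolated log-linearly from `startSize` to
#' `endSize` over `duration` generations). A size jump between consecutive
#' phases is an instantaneous event (a population split or bottleneck).
#' After the ancestral split the two branches exchange no
#' migrants, so only the sampled branch's size history enters any computation;
#' `branch` records which scenario the schedule describes.
#'
#' @slot phases data.frame with columns `duration` (generations, > 0),
#'   `startSize`, `endSize` (diploid Ne, > 0) and `mode`
#'   (`"constant"` or `"exponential"`); oldest phase first.
#' @slot branch character(1) scenario label, `"constant-branch"` or
#'   `"exponential-branch"`.
#' @seealso [DemographySchedule()], [demographyConstant()],
#'   [demographyExponential()]
#' @name DemographySchedule-class
#' @rdname DemographySchedule-class
#' @exportClass DemographySchedule
setClass("DemographySchedule",
  representation(phases = "data.frame", branch = "character"))

setValidity("DemographySchedule", function(object) {
  ph <- object@phases
  msg <- character()
  need <- c("duration", "startSize", "endSize", "mode")
  if (!all(need %in% names(ph)))
    return(paste("phases must have columns:", paste(need, collapse = ", ")))
  if (nrow(ph) < 1L) msg <- c(msg, "at least one phase is required")
  if (any(ph$duration <= 0)) msg <- c(msg, "phase durations must be > 0")
  if (any(ph$startSize <= 0) || any(ph$endSize <= 0))
    msg <- c(msg, "phase sizes must be > 0")
  if (!all(ph$mode %in% c("constant", "exponential")))
    msg <- c(msg, "phase mode must be 'constant' or 'exponential'")
  if (any(ph$mode == "constant" & ph$startSize != ph$endSize))
    msg <- c(msg, "constant phases must have startSize == endSize")
  if (length(object@branch) != 1L ||
      !object@branch %in% c("constant-branch", "exponential-branch"))
    msg <- c(msg, "branch must be 'constant-branch' or 'exponential-branch'")
  if (length(msg)) msg else TRUE
})

#' Construct a demographic schedule
#'
#' @param duration numeric vector of phase durations in generations, oldest
#'   phase first.
#' @param startSize,endSize numeric vectors of diploid effective sizes at the
#'   start and end of each phase.
#' @param mode character vector, `"constant"` or `"exponential"` per phase.
#' @param branch scenario label (`"constant-branch"` or
#'   `"exponential-branch"`).
#' @return A [DemographySchedule-class] object.
#' @export
DemographySchedule <- function(duration, startSize, endSize = startSize,
                               mode = ifelse(startSize == endSize,
                                             "constant", "exponential"),
                               branch = "constant-branch") {
  new("DemographySchedule",
      phases = data.frame(duration = as.numeric(duration),
                          startSize = as.numeric(startSize),
                          endSize = as.numeric(endSize),
                          mode = as.character(mode)),
      branch = branch)
}

#' Gamma distribution of fitness effects
#'
#' Configuration of the purifying-selection model: new non-neutral mutations
#' draw a population-scaled selection coefficient gamma = 2*Ne*s from a gamma
#' distribution with the given shape and mean. `neutralFraction` is the
#' probability that a new mutation is selectively neutral (1 gives a fully
#' neutral run, 0 a fully constrained one).
#'
#' @slot shape gamma shape parameter (> 0); default 0.206.
#' @slot meanGamma mean scaled selection coefficient 2*Ne*s (>= 0).
#' @slot neutralFraction fraction of mutations that are neutral, in \[0, 1\].
#' @seealso [DFEConfig()]
#' @name DFEConfig-class
#' @rdname DFEConfig-class
#' @exportClass DFEConfig
setClass("DFEConfig",
  representation(shape = "numeric", meanGamma = "numeric",
                 neutralFraction = "numeric"))

setValidity("DFEConfig", function(object) {
  msg <- character()
  if (length(object@shape) != 1L || object@shape <= 0)
    msg <- c(msg, "shape must be > 0")
  if (length(object@meanGamma) != 1L || object@meanGamma < 0)
    msg <- c(msg, "meanGamma must be >= 0")
  if (length(object@neutralFraction) != 1L ||
      object@neutralFraction < 0 || object@neutralFraction > 1)
    msg <- c(msg, "neutralFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a distribution-of-fitness-effects configuration
#'
#' @param shape gamma shape; 0.206 by default.
#' @param meanGamma mean scaled selection coefficient 2*Ne*s.
#' @param neutralFraction fraction of neutral mutations.
#' @return A [DFEConfig-class] object.
#' @export
DFEConfig <- function(shape = 0.206, meanGamma = 0, neutralFraction = 1) {
  new("DFEConfig", shape = as.numeric(shape),
      meanGamma = as.numeric(meanGamma),
      neutralFraction = as.numeric(neutralFraction))
}

#' Forward-simulation configuration
#'
#' Full configuration of one forward Wright-Fisher scenario: locus length,
#' baseline diploid size used to convert scaled selection coefficients to s,
#' per-site per-generation mutation rate, demographic schedule, distribution
#' of fitness effects, theta-preserving rescaling factor lambda, the haplotype
#' sample sizes to draw (nested, without replacement) at the final generation,
#' replicate count and seed. `lambda` records the rescaling already applied by
#' [rescaleConfig()]; slot values are stored on the rescaled scale.
#'
#' @slot seqLength locus length in base pairs.
#' @slot baseNe baseline (unrescaled) diploid effective size for the
#'   gamma = 2*Ne*s conversion.
#' @slot mu mutation rate per site per generation (rescaled scale).
#' @slot demography [DemographySchedule-class] (rescaled scale).
#' @slot dfe [DFEConfig-class].
#' @slot lambda rescaling factor applied so far (>= 1).
#' @slot sampleSizes integer vector of haplotype counts.
#' @slot nReplicates number of independent replicate loci.
#' @slot seed RNG seed.
#' @seealso [SimulationConfig()], [rescaleConfig()], [runSimulation()]
#' @name SimulationConfig-class
#' @rdname SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seqLength = "numeric", baseNe = "numeric", mu = "numeric",
                 demography = "DemographySchedule", dfe = "DFEConfig",
                 lambda = "numeric", sampleSizes = "integer",
                 nReplicates = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@seqLength < 1) msg <- c(msg, "seqLength must be >= 1")
  if (object@baseNe <= 0) msg <- c(msg, "baseNe must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@lambda < 1) msg <- c(msg, "lambda must be >= 1")
  if (length(object@sampleSizes) < 1L || any(object@sampleSizes < 2L))
    msg <- c(msg, "sampleSizes must contain counts >= 2")
  ph <- object@demography@phases
  finalN <- ph$endSize[nrow(ph)]
  if (max(object@sampleSizes) > 2 * finalN)
    msg <- c(msg, sprintf(
      "largest sample size (%d haplotypes) exceeds the final population (2N = %g)",
      max(object@sampleSizes), 2 * finalN))
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults follow the study conditions of the simulation scenarios: a 5 kb
#' locus, baseline Ne = 10,000 diploids, mutation rate 1e-8 per site per
#' generation, haplotype sample sizes 16, 32, 64, 128, 256, 512 and 1000
#' replicates.
#'
#' @param seqLength locus length (bp).
#' @param baseNe baseline diploid effective size.
#' @param mu mutation rate per site per generation.
#' @param demography a [DemographySchedule-class]; defaults to the
#'   constant-branch model of [demographyConstant()].
#' @param dfe a [DFEConfig-class]; neutral by default.
#' @param sampleSizes haplotype counts to sample.
#' @param nReplicates number of replicate loci.
#' @param seed RNG seed.
#' @return A [SimulationConfig-class] object (unrescaled; see
#'   [rescaleConfig()]).
#' @examples
#' cfg <- SimulationConfig(nReplicates = 10, seed = 1)
#' cfg <- rescaleConfig(cfg, lambda = 30)
#' @export
SimulationConfig <- function(seqLength = 5000, baseNe = 10000, mu = 1e-8,
                             demography = demographyConstant(),
                             dfe = DFEConfig(),
                             sampleSizes = c(16L, 32L, 64L, 128L, 256L, 512L),
                             nReplicates = 1000, seed = 1) {
  new("SimulationConfig", seqLength = as.numeric(seqLength),
      baseNe = as.numeric(baseNe), mu = as.numeric(mu),
      demography = demography, dfe = dfe, lambda = 1,
      sampleSizes = as.integer(sampleSizes),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Per-gene table of variants, divergence and constraint
#'
#' The substrate of the empirical sweep: per-gene summaries (divergence rates
#' dN and dS, their ratio, fixed-difference counts, synonymous and
#' nonsynonymous site totals) together with the bi-allelic SNV records of all
#' genes and a diploid genotype dosage matrix over a common sample panel.
#'
#' @slot genes data.frame with columns `gene_id`, `dn`, `ds`, `dn_ds`,
#'   `div_n`, `div_s`, `syn_sites`, `nonsyn_sites`.
#' @slot snvs data.frame with columns `gene_id`, `pos` (0-based), `class`
#'   (`"synonymous"` or `"nonsynonymous"`); one row per SNV, aligned with the
#'   rows of `dosages`.
#' @slot dosages integer matrix, SNVs x individuals, entries 0..ploidy.
#' @slot sampleIds character vector of individual identifiers (columns of
#'   `dosages`).
#' @slot ploidy integer(1), 2 for diploid data.
#' @seealso [GeneTable()], [readGeneTable()], [syntheticGeneTable()],
#'   [plantedGeneTable()], [runSweep()]
#' @name GeneTable-class
#' @rdname GeneTable-class
#' @exportClass GeneTable
setClass("GeneTable",
  representation(genes = "data.frame", snvs = "data.frame",
                 dosages = "matrix", sampleIds = "character",
                 ploidy = "integer"))

setValidity("GeneTable", function(object) {
  msg <- character()
  need <- c("gene_id", "dn", "ds", "dn_ds", "div_n", "div_s", "syn_sites",
            "nonsyn_sites")
  if (!all(need %in% names(object@genes)))
    msg <- c(msg, paste("genes must have columns:",
                        paste(need, collapse = ", ")))
  sneed <- c("gene_id", "pos", "class")
  if (!all(sneed %in% names(object@snvs)))
    msg <- c(msg, paste("snvs must have columns:",
                        paste(sneed, collapse = ", ")))
  else {
    if (!all(object@snvs$class %in% c("synonymous", "nonsynonymous")))
      msg <- c(msg, "snv class must be 'synonymous' or 'nonsynonymous'")
    if (nrow(object@snvs) != nrow(object@dosages))
      msg <- c(msg, "dosages must have one row per SNV")
    if (nrow(object@snvs) &&
        !all(object@snvs$gene_id %in% object@genes$gene_id))
      msg <- c(msg, "every SNV must belong to a gene in the gene table")
  }
  if (ncol(object@dosages) != length(object@sampleIds))
    msg <- c(msg, "dosages must have one column per sample id")
  if (length(object@ploidy) != 1L || object@ploidy < 1L)
    msg <- c(msg, "ploidy must be a single integer >= 1")
  else if (length(object@dosages) &&
           (min(object@dosages) < 0 || max(object@dosages) > object@ploidy))
    msg <- c(msg, "dosages must lie in 0..ploidy")
  if (length(msg)) msg else TRUE
})

#' Construct a gene table
#'
#' @param genes per-gene data.frame (see [GeneTable-class]).
#' @param snvs per-SNV data.frame.
#' @param dosages integer matrix, SNVs x individuals.
#' @param sampleIds individual identifiers.
#' @param ploidy ploidy of the genotype calls (2 for diploid).
#' @return A [GeneTable-class] object.
#' @export
GeneTable <- function(genes, snvs, dosages, sampleIds, ploidy = 2L) {
  storage.mode(dosages) <- "integer"
  new("GeneTable", genes = genes, snvs = snvs, dosages = dosages,
      sampleIds = as.character(sampleIds), ploidy = as.integer(ploidy))
}

#' Result of a sample-size sweep
#'
#' Tidy results of [runSweep()]: one row of `stats` per redraw, sample size,
#' gene bin and site class, plus `summaries` of per-series log2-log2
#' regression slopes, large-vs-small deltas and ratios, and correlation
#' tests, and the run metadata.
#'
#' @slot stats data.frame of per-group statistics.
#' @slot summaries data.frame of per-series summaries.
#' @slot meta list of run metadata (sizes, seed, redraw count, sample unit).
#' @seealso [runSweep()], [sweepStats()], [sweepSummary()]
#' @name SweepResult-class
#' @rdname SweepResult-class
#' @exportClass SweepResult
setClass("SweepResult",
  representation(stats = "data.frame", summaries = "data.frame",
                 meta = "list"))

#' Synthetic exome generator configuration
#'
#' Parameters of the synthetic panel emulating the shape of a large human
#' exome polymorphism dataset: panel size, gene count, per-gene synonymous and
#' nonsynonymous site totals, the dN/dS distribution, the sampled-spectrum
#' model used to draw SNV frequencies, per-site SNV densities and the
#' divergence model. See [syntheticGeneTable()].
#'
#' @slot nIndividuals diploid panel size (default 1008 = 16+32+64+128+256+512).
#' @slot nGenes number of genes.
#' @slot synSites,nonsynSites per-gene synonymous / nonsynonymous site counts.
#' @slot sfsModel `"neutral"`, `"growth"` or `"selection"`; `"growth"` adds a
#'   singleton excess of weight `growthTilt`, `"selection"` additionally adds
#'   `constraintTilt * (1 - dN/dS)` for nonsynonymous SNVs.
#' @slot growthTilt,constraintTilt singleton-excess weights in \[0, 1\].
#' @slot synDensity,nonsynDensity expected SNVs per synonymous /
#'   nonsynonymous site.
#' @slot seed RNG seed.
#' @name SynthConfig-class
#' @rdname SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nIndividuals = "integer", nGenes = "integer",
                 synSites = "integer", nonsynSites = "integer",
                 sfsModel = "character", growthTilt = "numeric",
                 constraintTilt = "numeric", synDensity = "numeric",
                 nonsynDensity = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@synSites < 1L || object@nonsynSites < 1L)
    msg <- c(msg, "site counts must be >= 1")
  if (!object@sfsModel %in% c("neutral", "growth", "selection"))
    msg <- c(msg, "sfsModel must be 'neutral', 'growth' or 'selection'")
  if (object@growthTilt < 0 || object@growthTilt > 1 ||
      object@constraintTilt < 0 || object@constraintTilt > 1)
    msg <- c(msg, "tilt weights must lie in [0, 1]")
  if (object@synDensity < 0 || object@synDensity > 1 ||
      object@nonsynDensity < 0 || object@nonsynDensity > 1)
    msg <- c(msg, "SNV densities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic exome configuration
#'
#' @param nIndividuals diploid panel size.
#' @param nGenes number of genes.
#' @param synSites,nonsynSites per-gene site totals.
#' @param sfsModel spectrum model (see [SynthConfig-class]).
#' @param growthTilt,constraintTilt singleton-excess weights.
#' @param synDensity,nonsynDensity per-site SNV densities.
#' @param seed RNG seed.
#' @return A [SynthConfig-class] object.
#' @export
SynthConfig <- function(nIndividuals = 1008, nGenes = 500, synSites = 300,
                        nonsynSites = 900, sfsModel = "selection",
                        growthTilt = 0.37, constraintTilt = 0.25,
                        synDensity = 0.03, nonsynDensity = 0.015,
                        seed = 1) {
  new("SynthConfig", nIndividuals = as.integer(nIndividuals),
      nGenes = as.integer(nGenes), synSites = as.integer(synSites),
      nonsynSites = as.integer(nonsynSites), sfsModel = sfsModel,
      growthTilt = as.numeric(growthTilt),
      constraintTilt = as.numeric(constraintTilt),
      synDensity = as.numeric(synDensity),
      nonsynDensity = as.numeric(nonsynDensity), seed = as.integer(seed))
}
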