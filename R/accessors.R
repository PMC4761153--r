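#' @include AllGenerics.R
NULL

#' Accessors for SiteFrequencySpectrum
#'
#' `nSeq` returns the number of sequences sampled; `sfsCounts` the folded
#' spectrum; `nSites` the surveyed site total; `siteClass` the class label;
#' `segSites` the number of segregating sites S; `singletons` the number of
#' minor-allele singleton sites.
#'
#' @param x a [SiteFrequencySpectrum-class].
#' @return A scalar (or, for `sfsCounts`, a numeric vector indexed by
#'   minor-allele count).
#' @name sfs-accessors
#' @aliases nSeq sfsCounts nSites siteClass segSites singletons
NULL

#' @rdname sfs-accessors
#' @export
setMethod("nSeq", "SiteFrequencySpectrum", function(x) x@nSeq)
#' @rdname sfs-accessors
#' @export
setMethod("sfsCounts", "SiteFrequencySpectrum", function(x) x@counts)
#' @rdname sfs-accessors
#' @export
setMethod("nSites", "SiteFrequencySpectrum", function(x) x@nSites)
#' @rdname sfs-accessors
#' @export
setMethod("siteClass", "SiteFrequencySpectrum", function(x) x@siteClass)
#' @rdname sfs-accessors
#' @export
setMethod("segSites", "SiteFrequencySpectrum", function(x) sum(x@counts))
#' @rdname sfs-accessors
#' @export
setMethod("singletons", "SiteFrequencySpectrum", function(x) x@counts[1L])

setMethod("show", "SiteFrequencySpectrum", function(object) {
  cat(sprintf(
    "SiteFrequencySpectrum: n = %d sequences, %s sites\n  S = %g segregating (%g singletons) of %g surveyed sites\n",
    object@nSeq, object@siteClass, sum(object@counts), object@counts[1L],
    object@nSites))
})

#' Accessor for MKCounts
#'
#' Returns the four counts of the 2x2 McDonald-Kreitman table as a named
#' numeric vector.
#'
#' @param x an [MKCounts-class].
#' @return Named numeric vector `c(Pn, Ps, Dn, Ds)`.
#' @export
setMethod("mkCounts", "MKCounts", function(x)
  c(Pn = x@Pn, Ps = x@Ps, Dn = x@Dn, Ds = x@Ds))

setMethod("show", "MKCounts", function(object) {
  cat(sprintf("MKCounts: Pn = %g, Ps = %g, Dn = %g, Ds = %g\n",
              object@Pn, object@Ps, object@Dn, object@Ds))
})

setMethod("show", "DemographySchedule", function(object) {
  cat(sprintf("DemographySchedule (%s), %d phase(s):\n", object@branch,
              nrow(object@phases)))
  print(object@phases, row.names = FALSE)
})

setMethod("show", "DFEConfig", function(object) {
  if (object@neutralFraction >= 1 || object@meanGamma == 0)
    cat("DFEConfig: neutral\n")
  else
    cat(sprintf(
      "DFEConfig: gamma(shape = %g, mean 2Ns = %g), neutral fraction %g\n",
      object@shape, object@meanGamma, object@neutralFraction))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: L = %g bp, base Ne = %g, mu = %g, lambda = %g\n",
    object@seqLength, object@baseNe, object@mu, object@lambda))
  cat(sprintf("  sample sizes: %s; replicates: %d; seed: %d\n",
              paste(object@sampleSizes, collapse = ", "),
              object@nReplicates, object@seed))
  show(object@dfe)
  show(object@demography)
})

#' Accessors for GeneTable
#'
#' `geneSummary` returns the per-gene data.frame, `snvRecords` the per-SNV
#' data.frame, `dosageMatrix` the SNV x individual dosage matrix and
#' `sampleIds` the individual identifiers.
#'
#' @param x a [GeneTable-class].
#' @return The corresponding component.
#' @name genetable-accessors
#' @aliases geneSummary snvRecords dosageMatrix sampleIds
NULL

#' @rdname genetable-accessors
#' @export
setMethod("geneSummary", "GeneTable", function(x) x@genes)
#' @rdname genetable-accessors
#' @export
setMethod("snvRecords", "GeneTable", function(x) x@snvs)
#' @rdname genetable-accessors
#' @export
setMethod("dosageMatrix", "GeneTable", function(x) x@dosages)
#' @rdname genetable-accessors
#' @export
setMethod("sampleIds", "GeneTable", function(x) x@sampleIds)

setMethod("show", "GeneTable", function(object) {
  cat(sprintf(
    "GeneTable: %d genes, %d SNVs, %d individuals (ploidy %d)\n",
    nrow(object@genes), nrow(object@snvs), length(object@sampleIds),
    object@ploidy))
  tab <- table(object@snvs$class)
  if (length(tab))
    cat("  SNVs by class:",
        paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
})

#' Accessors for SweepResult
#'
#' `sweepStats` returns the per-group statistics table, `sweepSummary` the
#' per-series summaries (slopes, deltas, ratios, correlations) and
#' `sweepMeta` the run metadata.
#'
#' @param x a [SweepResult-class].
#' @return A data.frame (`sweepStats`, `sweepSummary`) or list (`sweepMeta`).
#' @name sweep-accessors
#' @aliases sweepStats sweepSummary sweepMeta
NULL

#' @rdname sweep-accessors
#' @export
setMethod("sweepStats", "SweepResult", function(x) x@stats)
#' @rdname sweep-accessors
#' @export
setMethod("sweepSummary", "SweepResult", function(x) x@summaries)
#' @rdname sweep-accessors
#' @export
setMethod("sweepMeta", "SweepResult", function(x) x@meta)

setMethod("show", "SweepResult", function(object) {
  cat(sprintf(
    "SweepResult: %d stat rows (%d redraws x sizes %s), %d series summaries\n",
    nrow(object@stats), object@meta$nRedraws,
    paste(object@meta$sizes, collapse = ", "), nrow(object@summaries)))
})
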