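#' @include accessors.R
NULL

#' Aggregate McDonald-Kreitman tables over genes
#'
#' Element-wise sum of per-gene 2x2 tables. Counts are pooled before any
#' ratio is taken: per-gene Neutrality Index or alpha values are frequently
#' undefined (zero cells), so exome-wide statistics are computed once from
#' the aggregated counts.
#'
#' @param geneRecords list of [MKCounts-class] objects (may be empty).
#' @return A single [MKCounts-class] with summed counts.
#' @examples
#' aggregateMK(list(MKCounts(1, 2, 3, 4), MKCounts(1, 0, 0, 1)))
#' @export
aggregateMK <- function(geneRecords) {
  if (!length(geneRecords)) return(MKCounts(0, 0, 0, 0))
  stopifnot(all(vapply(geneRecords, is, logical(1), "MKCounts")))
  MKCounts(Pn = sum(vapply(geneRecords, slot, numeric(1), "Pn")),
           Ps = sum(vapply(geneRecords, slot, numeric(1), "Ps")),
           Dn = sum(vapply(geneRecords, slot, numeric(1), "Dn")),
           Ds = sum(vapply(geneRecords, slot, numeric(1), "Ds")))
}

#' Neutrality Index
#'
#' `NI = (Pn/Ps) / (Dn/Ds)`, the ratio of the polymorphism ratio to the
#' divergence ratio. NI > 1 indicates an excess of segregating (mostly
#' weakly deleterious) nonsynonymous variation relative to what fixes.
#' Undefined when `Ps = 0` or `Dn = 0`; returns `NA_real_` with a warning.
#'
#' @param x an [MKCounts-class].
#' @return NI (numeric scalar), or `NA_real_` if undefined.
#' @export
setMethod("neutralityIndex", "MKCounts", function(x) {
  validObject(x)
  if (x@Ps == 0 || x@Dn == 0) {
    warning("Neutrality Index is undefined for Ps = 0 or Dn = 0; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  (x@Pn / x@Ps) / (x@Dn / x@Ds)
})

#' Proportion of adaptive nonsynonymous substitutions
#'
#' `alpha = 1 - (Ds * Pn) / (Dn * Ps)`, the fraction of nonsynonymous fixed
#' differences attributable to positive selection; identically `1 - NI`
#' wherever both are defined. Segregating deleterious nonsynonymous variants
#' inflate Pn and push alpha down, which is why alpha shrinks as sample size
#' grows and rare variants surface. Undefined when `Dn = 0` or `Ps = 0`;
#' returns `NA_real_` with a warning.
#'
#' @param x an [MKCounts-class].
#' @return alpha (numeric scalar), or `NA_real_` if undefined.
#' @export
setMethod("alphaAdaptive", "MKCounts", function(x) {
  validObject(x)
  if (x@Dn == 0 || x@Ps == 0) {
    warning("alpha is undefined for Dn = 0 or Ps = 0; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  1 - (x@Ds * x@Pn) / (x@Dn * x@Ps)
})
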