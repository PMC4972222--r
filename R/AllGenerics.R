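#' @include AllClasses.R
NULL

#' Individual identifiers of a genotype container
#' @param x a [GenotypeTable-class] or related object.
#' @return Character vector of ids.
#' @export
setGeneric("indivNames", function(x) standardGeneric("indivNames"))

#' Locus names of a genotype container
#' @param x a [GenotypeTable-class] or [AlleleFrequencyTable-class].
#' @return Character vector of locus names.
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Numeric values of a matrix-like S4 container
#' @param x a [RelatednessMatrix-class] or [GMatrix-class].
#' @return Base numeric matrix.
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' Estimator tag of a relatedness matrix
#' @param x a [RelatednessMatrix-class].
#' @return Character scalar.
#' @export
setGeneric("estimatorTag", function(x) standardGeneric("estimatorTag"))

#' Genet groups of a clone assignment
#' @param x a [CloneAssignment-class].
#' @return Named list of member id vectors.
#' @export
setGeneric("cloneGroups", function(x) standardGeneric("cloneGroups"))

#' Representative patch per genet
#' @param x a [CloneAssignment-class].
#' @return Named character vector, one representative id per group.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Variance components of an animal-model fit
#' @param x a [VarianceComponentFit-class].
#' @return Named numeric `c(va = , ve = )`.
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))

setMethod("indivNames", "GenotypeTable", function(x) x@ids)
setMethod("lociNames", "GenotypeTable", function(x) x@loci)
setMethod("lociNames", "AlleleFrequencyTable", function(x) names(x@freq))
setMethod("indivNames", "RelatednessMatrix", function(x) rownames(x@values))
setMethod("relValues", "RelatednessMatrix", function(x) x@values)
setMethod("relValues", "GMatrix", function(x) x@values)
setMethod("estimatorTag", "RelatednessMatrix", function(x) x@estimator)
setMethod("cloneGroups", "CloneAssignment", function(x) x@groups)
setMethod("representatives", "CloneAssignment", function(x) x@representatives)
setMethod("varianceComponents", "VarianceComponentFit",
          function(x) c(va = x@va, ve = x@ve))

setMethod("show", "GenotypeTable", function(object) {
  nmiss <- sum(is.na(object@alleles[, , 1]))
  cat(sprintf("GenotypeTable: %d individuals x %d loci (%d missing calls)\n",
              length(object@ids), length(object@loci), nmiss))
  cat("  loci:", paste(object@loci, collapse = ", "), "\n")
  if (length(object@site))
    cat("  sites:", paste(unique(object@site), collapse = ", "), "\n")
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  k <- vapply(object@freq, length, integer(1))
  cat(sprintf("AlleleFrequencyTable: %d loci, %d-%d alleles per locus\n",
              length(k), min(k), max(k)))
})

setMethod("show", "RelatednessMatrix", function(object) {
  v <- object@values
  cat(sprintf("RelatednessMatrix (%s): %d x %d%s\n", object@estimator,
              nrow(v), ncol(v), if (isTRUE(object@psd)) ", PSD" else ""))
  off <- v[upper.tri(v)]
  cat(sprintf("  off-diagonal mean %.4f, range [%.3f, %.3f], %d unusable pairs\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), object@nMissingPairs))
})

setMethod("show", "CloneAssignment", function(object) {
  sizes <- lengths(object@groups)
  cat(sprintf("CloneAssignment: %d patches -> %d genets (threshold %.3g, seed %d)\n",
              length(object@ids), length(object@groups), object@threshold,
              object@seed))
  cat(sprintf("  %d genets with clonal replicates (largest group: %d patches)\n",
              sum(sizes > 1), max(sizes)))
})

setMethod("show", "VarianceComponentFit", function(object) {
  cat(sprintf("Animal-model REML fit: %s (n = %d)\n", object@trait, object@n))
  cat(sprintf("  Va = %.4g (SE %.3g), Ve = %.4g (SE %.3g)\n",
              object@va, object@seVa, object@ve, object@seVe))
  cat(sprintf("  h2 = %.3f [%.3f, %.3f], Z-test p = %.3g\n",
              object@h2, object@h2CI[1], object@h2CI[2], object@zP))
  if (object@nonIdentifiable)
    cat("  NOTE: relatedness matrix ~ identity; Va and Ve are confounded\n")
})

setMethod("show", "GMatrix", function(object) {
  cat(sprintf("GMatrix: %d traits\n", length(object@traits)))
  print(round(object@values, 4))
})
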