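#' @import methods
NULL

#' Diploid multilocus SSR genotypes
#'
#' Container for individuals-by-loci diploid allele-size calls. Alleles are
#' stored as an integer array of dimension `n x L x 2` (allele sizes in
#' base pairs, sorted within each call so that the unordered-pair convention
#' is canonical); a missing call has `NA` in both slots.
#'
#' @slot ids character, unique individual (patch) identifiers.
#' @slot loci character, locus names.
#' @slot alleles integer array `n x L x 2` of allele sizes; `NA`/`NA` for a
#'   missing call.
#' @slot site character, per-individual site label (may be empty).
#'
#' @seealso [GenotypeTable()], [readGenotypes()], [alleleFrequencies()]
#' @export
setClass("GenotypeTable",
  representation(ids = "character", loci = "character",
                 alleles = "array", site = "character"))

setValidity("GenotypeTable", function(object) {
  n <- length(object@ids); L <- length(object@loci)
  d <- dim(object@alleles)
  if (length(d) != 3L || d[1] != n || d[2] != L || d[3] != 2L)
    return(sprintf("alleles array must be %d x %d x 2", n, L))
  if (anyDuplicated(object@ids)) return("individual ids must be unique")
  if (length(object@site) != 0L && length(object@site) != n)
    return("site must be empty or one label per individual")
  a <- object@alleles
  if (any(a[!is.na(a)] <= 0)) return("allele sizes must be positive")
  half <- is.na(a[, , 1, drop = FALSE]) != is.na(a[, , 2, drop = FALSE])
  if (any(half)) return("a call must have both alleles present or both missing")
  TRUE
})

#' Construct a GenotypeTable
#'
#' @param ids character vector of unique individual ids.
#' @param loci character vector of locus names.
#' @param alleles integer array `n x L x 2`; within-call allele order is
#'   irrelevant (calls are sorted internally).
#' @param site optional character vector of site labels.
#' @return A validated [GenotypeTable-class] object.
#' @examples
#' a <- array(NA_integer_, c(2, 1, 2))
#' a[1, 1, ] <- c(101L, 103L); a[2, 1, ] <- c(101L, 101L)
#' GenotypeTable(c("p1", "p2"), "locA", a)
#' @export
GenotypeTable <- function(ids, loci, alleles, site = character()) {
  storage.mode(alleles) <- "integer"
  ## canonical within-call order: smaller allele first
  a1 <- alleles[, , 1, drop = FALSE]; a2 <- alleles[, , 2, drop = FALSE]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  alleles[, , 1] <- lo; alleles[, , 2] <- hi
  dimnames(alleles) <- list(ids, loci, c("a1", "a2"))
  new("GenotypeTable", ids = as.character(ids), loci = as.character(loci),
      alleles = alleles, site = as.character(site))
}

#' Per-locus allele frequencies
#'
#' @slot freq named list (one element per locus) of named numeric vectors;
#'   names are allele sizes, values are relative frequencies summing to 1.
#' @slot nGenes integer, number of gene copies counted per locus.
#' @export
setClass("AlleleFrequencyTable",
  representation(freq = "list", nGenes = "integer"))

setValidity("AlleleFrequencyTable", function(object) {
  for (l in names(object@freq)) {
    p <- object@freq[[l]]
    if (any(p < 0)) return(sprintf("negative frequency at locus %s", l))
    if (abs(sum(p) - 1) > 1e-9)
      return(sprintf("frequencies at locus %s do not sum to 1", l))
  }
  if (length(object@nGenes) != length(object@freq))
    return("nGenes must align with freq")
  TRUE
})

#' Pairwise relatedness matrix
#'
#' Symmetric matrix of pairwise relatedness coefficients between unique
#' genotypes, tagged with the moment estimator that produced it.
#'
#' @slot values symmetric numeric matrix with dimnames; `NA` marks pairs
#'   with no usable locus.
#' @slot estimator one of `"qg"`, `"li"`, `"lr"`, `"wang"`.
#' @slot psd logical, `TRUE` after [nearPositiveDefinite()].
#' @slot nMissingPairs integer, count of unusable pairs (before filling).
#' @export
setClass("RelatednessMatrix",
  representation(values = "matrix", estimator = "character",
                 psd = "logical", nMissingPairs = "integer"))

setValidity("RelatednessMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    return("matrix must be symmetric")
  if (!object@estimator %in% c("qg", "li", "lr", "wang"))
    return("unknown estimator tag")
  TRUE
})

#' Clonal genotype assignment
#'
#' Partition of sampled patches into genets (clonal genotype groups) with a
#' randomly drawn representative patch per group.
#'
#' @slot ids all patch ids, in input order.
#' @slot groups named list: group id -> character vector of member patch ids.
#' @slot representatives named character: group id -> representative patch id.
#' @slot threshold numeric distance threshold used.
#' @slot seed integer seed used for representative selection.
#' @slot nUnusablePairs integer, pairs with no shared typed locus (kept
#'   distinct by convention).
#' @export
setClass("CloneAssignment",
  representation(ids = "character", groups = "list",
                 representatives = "character", threshold = "numeric",
                 seed = "integer", nUnusablePairs = "integer"))

setValidity("CloneAssignment", function(object) {
  members <- unlist(object@groups, use.names = FALSE)
  if (!setequal(members, object@ids) || length(members) != length(object@ids))
    return("groups must partition the patch ids")
  ok <- vapply(names(object@groups), function(g)
    object@representatives[[g]] %in% object@groups[[g]], logical(1))
  if (!all(ok)) return("each representative must belong to its group")
  TRUE
})

#' Univariate REML animal-model fit
#'
#' Result of partitioning one trait's phenotypic variance into additive
#' genetic (Va) and residual (Ve) components against a relatedness matrix.
#'
#' @slot trait trait name.
#' @slot va,ve REML estimates of the additive genetic and residual variance.
#' @slot seVa,seVe,covVaVe standard errors and sampling covariance of the
#'   components (expected-information based).
#' @slot logLik REML log-likelihood at the optimum.
#' @slot h2 narrow-sense heritability Va/(Va+Ve).
#' @slot h2SE delta-method standard error of h2.
#' @slot h2CI length-2 numeric, 95% confidence bounds (not truncated).
#' @slot zP one-sided Z-test p-value for Va > 0.
#' @slot lambda variance ratio Va/Ve at the optimum.
#' @slot n number of complete cases used.
#' @slot wald data.frame of incremental Wald F tests for the fixed terms.
#' @slot converged,nonIdentifiable logical diagnostics.
#' @slot dropped character, aliased design columns removed before fitting.
#' @export
setClass("VarianceComponentFit",
  representation(trait = "character", va = "numeric", ve = "numeric",
                 seVa = "numeric", seVe = "numeric", covVaVe = "numeric",
                 logLik = "numeric", h2 = "numeric", h2SE = "numeric",
                 h2CI = "numeric", zP = "numeric", lambda = "numeric",
                 n = "integer", wald = "data.frame", converged = "logical",
                 nonIdentifiable = "logical", dropped = "character"))

setValidity("VarianceComponentFit", function(object) {
  if (!is.na(object@va) && object@va < 0) return("va must be >= 0")
  if (!is.na(object@ve) && object@ve < 0) return("ve must be >= 0")
  if (!is.na(object@h2) && (object@h2 < 0 || object@h2 > 1))
    return("h2 must lie in [0, 1]")
  if (length(object@h2CI) == 2L && !anyNA(object@h2CI) &&
      diff(object@h2CI) < 0) return("CI bounds out of order")
  TRUE
})

#' Additive genetic (co)variance matrix across traits
#'
#' @slot traits trait names.
#' @slot values symmetric matrix; diagonal = univariate additive variances,
#'   off-diagonal = bivariate additive covariances.
#' @slot zP matrix of Z-test p-values (one-sided on the diagonal, two-sided
#'   off it).
#' @export
setClass("GMatrix",
  representation(traits = "character", values = "matrix", zP = "matrix"))

setValidity("GMatrix", function(object) {
  v <- object@values
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    return("G matrix must be symmetric")
  if (any(diag(v) < 0, na.rm = TRUE)) return("additive variances must be >= 0")
  TRUE
})
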