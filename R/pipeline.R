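#' @include AllClasses.R clonal-id.R relatedness.R animal-model.R
#' @include performance-models.R synthetic-data.R
NULL

#' Paper-scale synthetic preset
#'
#' Generates a study-scale synthetic dataset: 939 unique genotypes
#' sampled as 1061 patches after clonal duplication, 12 sites in a
#' 3 transect x 2 elevation x 2 microhabitat layout, and six traits
#' simulated under the additive model with declared heritabilities and
#' per-trait total variances. The default population descends from a
#' small founding cohort (51 founders, two descendant cohorts of 444),
#' mimicking a locally founded stand whose half- and full-sib family
#' structure gives a 7-locus SSR panel usable relatedness signal.
#'
#' @param seed integer seed.
#' @param nFounders founding cohort size (default 51; with the default
#'   cohorts this yields 939 genets).
#' @param nGenerations,nPerGeneration descendant cohorts (defaults 2 x 444).
#' @param h2 true heritabilities of the six traits.
#' @param totalVariance per-trait total phenotypic variances.
#' @param cloneRate fraction of genets duplicated as clonal patches
#'   (default 0.13: 122 clonal patches, 1061 patches in total).
#' @return list: `genotypes` (all patches), `phenotypes` (per-patch trait
#'   table with factors), `truth` (pedigree, A, clone map, trait truth).
#' @export
paperLikePreset <- function(seed = 1L, nFounders = 51L, nGenerations = 2L,
    nPerGeneration = 444L,
    h2 = c(leaf_size = 0.061, change_in_stem_number = 0.071,
           proportion_flowering_stems = 0.034,
           snowmelt_to_leaf_expansion = 0.178,
           gdd_to_leaf_expansion = 0.141, gdd_to_flowering = 0.181),
    totalVariance = c(2.080, 0.223, 0.037, 58.202, 0.773, 0.855),
    cloneRate = 0.13) {
  sim <- simulateGenotypes(nFounders = nFounders, nGenerations = nGenerations,
                           nPerGeneration = nPerGeneration,
                           cloneRate = cloneRate, seed = seed)
  A <- sim$truth$A
  tr <- simulateTraits(A, h2 = unname(h2), totalVariance = totalVariance,
                       effects = list(microhabitat = 0.3, elevation = 0.1,
                                      transectSD = 0.1),
                       traitNames = names(h2), seed = seed + 1L)
  ## patches inherit their genet's breeding value and site; clonal patches
  ## get independent residual draws via the genet phenotype (one record per
  ## patch, but downstream analysis keeps one representative per genet)
  genet <- sim$truth$cloneMap
  idx <- match(genet, tr$phenotypes$id)
  ph <- tr$phenotypes[idx, ]
  ph$id <- names(genet)
  rownames(ph) <- NULL
  list(genotypes = sim$genotypes, phenotypes = ph,
       truth = c(sim$truth, list(traits = tr$truth, h2 = h2,
                                 totalVariance = totalVariance)))
}

#' Run the full marker-based quantitative-genetics pipeline
#'
#' Orchestrates: genotype intake, clone identification and filtering,
#' per-estimator relatedness with unit diagonal and nearest-PD
#' conditioning, per-trait univariate REML heritabilities (one table per
#' estimator), cross-estimator heritability correlations, optional G
#' matrices, and the two performance regressions. All defaults match the
#' study design this pipeline emulates: clone threshold 0.05, all four
#' relatedness estimators with Lynch-Ritland reported first, GDD base
#' 5 degC upstream.
#'
#' @param genotypes a [GenotypeTable-class] of all patches (or a file path
#'   with `format` given).
#' @param phenotypes data.frame with `id` (patch), the factor columns
#'   `transect`, `elevation`, `microhabitat`, `site`, and trait columns.
#' @param traits character, trait columns to analyse.
#' @param estimators relatedness estimators to run (default all four;
#'   first one is the headline estimator).
#' @param cloneThreshold Lynch-distance threshold (default 0.05).
#' @param seed integer seed (clone representative selection).
#' @param doGMatrix fit pairwise bivariate models for G matrices
#'   (default TRUE).
#' @param performanceResponses response columns for the performance
#'   regressions (set `character()` to skip).
#' @param performanceTraits predictor traits for the regressions.
#' @param format when `genotypes` is a path: `"genepop"` or `"table"`.
#' @return list of class `qgPipelineResult`: `counts`, `clones`
#'   ([CloneAssignment-class]), `h2Tables` (one data.frame per estimator),
#'   `h2Correlations`, `gMatrices`, `performance`, `log`, `seed`.
#' @export
runPipeline <- function(genotypes, phenotypes,
                        traits = c("leaf_size", "change_in_stem_number",
                                   "proportion_flowering_stems",
                                   "snowmelt_to_leaf_expansion",
                                   "gdd_to_leaf_expansion",
                                   "gdd_to_flowering"),
                        estimators = c("lr", "qg", "li", "wang"),
                        cloneThreshold = 0.05, seed = 1L,
                        doGMatrix = TRUE,
                        performanceResponses = c("change_in_stem_number",
                                                 "proportion_flowering_stems"),
                        performanceTraits = c("leaf_size",
                                              "snowmelt_to_leaf_expansion",
                                              "gdd_to_leaf_expansion",
                                              "gdd_to_flowering"),
                        format = c("genepop", "table")) {
  logLines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    message("[pipeline] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.character(genotypes))
    genotypes <- readGenotypes(genotypes, match.arg(format))
  stopifnot(is(genotypes, "GenotypeTable"), is.data.frame(phenotypes))
  nPatches <- length(genotypes@ids)
  say("genotypes: %d patches x %d loci", nPatches, length(genotypes@loci))

  ca <- stage("clone identification",
              assignClones(lynchDistance(genotypes),
                           threshold = cloneThreshold, seed = seed))
  gUnique <- filterClones(genotypes, ca)
  nGenets <- length(gUnique@ids)
  say("clones: %d unique genotypes, %d clonal replicates removed (seed %d)",
      nGenets, nPatches - nGenets, seed)

  ph <- phenotypes[match(gUnique@ids, phenotypes$id), , drop = FALSE]
  if (anyNA(ph$id)) stop("phenotypes missing for some representative patches",
                         call. = FALSE)
  X <- stage("fixed design", buildFixedDesign(ph))
  f <- stage("allele frequencies", alleleFrequencies(gUnique))

  h2Tables <- list(); gMatrices <- list(); fits1 <- list()
  for (est in estimators) {
    M <- stage(paste0("relatedness (", est, ")"), {
      m <- pairwiseRelatedness(gUnique, estimator = est, f = f)
      nearPositiveDefinite(setDiagonalUnity(m))
    })
    eM <- eigen((relValues(M) + t(relValues(M))) / 2, symmetric = TRUE)
    tab <- lapply(traits, function(tr) {
      fit <- stage(paste0("REML ", est, " / ", tr),
                   remlUnivariate(ph[[tr]], X, relValues(M), trait = tr,
                                  eigenM = if (anyNA(ph[[tr]])) NULL else eM))
      data.frame(trait = tr, h2 = fit@h2, lowCI = fit@h2CI[1],
                 upCI = fit@h2CI[2], Va = fit@va, Vr = fit@ve,
                 p = fit@zP, n = fit@n, stringsAsFactors = FALSE)
    })
    h2Tables[[est]] <- do.call(rbind, tab)
    say("h2 (%s): %s", est,
        paste(sprintf("%s=%.3f", traits, h2Tables[[est]]$h2), collapse = " "))
    if (doGMatrix)
      gMatrices[[est]] <- stage(paste0("G matrix (", est, ")"),
                                gMatrix(ph[, traits], X, relValues(M)))
  }

  h2Correlations <- NULL
  if (length(estimators) > 1L) {
    H <- sapply(h2Tables, function(t) t$h2)
    h2Correlations <- stats::cor(H)
    off <- h2Correlations[upper.tri(h2Correlations)]
    say("cross-estimator h2 Pearson correlations: %.2f-%.2f",
        min(off), max(off))
  }

  performance <- list()
  for (resp in performanceResponses) {
    if (!resp %in% names(ph)) next
    pf <- stage(paste0("performance regression (", resp, ")"),
                fitPerformanceModel(ph, resp, traits = performanceTraits))
    perHab <- if (any(pf$interactionSignificant))
      stage("per-microhabitat refit", refitByMicrohabitat(pf)) else NULL
    performance[[resp]] <- list(fit = pf, perMicrohabitat = perHab)
    say("performance (%s): interactions significant for %s", resp,
        if (any(pf$interactionSignificant))
          paste(names(which(pf$interactionSignificant)), collapse = ", ")
        else "none")
  }

  out <- list(counts = c(patchesIn = nPatches, uniqueGenotypes = nGenets,
                         cloneReplicates = nPatches - nGenets),
              clones = ca, h2Tables = h2Tables,
              h2Correlations = h2Correlations, gMatrices = gMatrices,
              performance = performance, log = logLines,
              seed = as.integer(seed))
  class(out) <- "qgPipelineResult"
  out
}

#' @export
print.qgPipelineResult <- function(x, ...) {
  cat("Marker-based quantitative-genetics pipeline\n")
  cat(sprintf("  %d patches -> %d unique genotypes (%d clonal replicates)\n",
              x$counts["patchesIn"], x$counts["uniqueGenotypes"],
              x$counts["cloneReplicates"]))
  est1 <- names(x$h2Tables)[1]
  cat(sprintf("  heritabilities (%s estimator):\n", est1))
  print(transform(x$h2Tables[[est1]],
                  h2 = round(h2, 3), lowCI = round(lowCI, 3),
                  upCI = round(upCI, 3), Va = signif(Va, 4),
                  Vr = signif(Vr, 4), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
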