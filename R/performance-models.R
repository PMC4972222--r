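#' @include AllClasses.R phenotypes.R
#' @importFrom nlme lme lmeControl VarCorr fixef
NULL

#' Standardized-trait performance regression with nested random effects
#'
#' Multiple regression of a performance measure (clonal reproduction:
#' change in stem number; or sexual reproduction: proportion of flowering
#' stems) on standardized traits, microhabitat, and trait x microhabitat
#' interactions, fit as a Gaussian linear mixed model (REML) with random
#' intercepts for transect and site nested within transect. Standardizing
#' the traits makes the slopes comparable across traits, in the spirit of
#' a selection-gradient analysis (though the responses are performance
#' proxies, not fitness). Per-term marginal Wald F tests use nlme's
#' containment denominator degrees of freedom.
#'
#' @param data data.frame with the response, the trait columns, and
#'   `microhabitat`, `transect`, `site` factors.
#' @param response response column name.
#' @param traits trait column names (standardized internally over the
#'   complete cases actually used).
#' @param alpha significance gate for trait x microhabitat interactions
#'   (default 0.05, no multiplicity correction).
#' @return Object of class `PerformanceModelFit`: list with `table`
#'   (term, Est., numDF, denDF, F, p), `interactionSignificant` (named
#'   logical per trait), `ranefSD`, `model` (the `lme` fit), `data`,
#'   `traits`, `response`, `alpha`.
#' @seealso [refitByMicrohabitat()]
#' @export
fitPerformanceModel <- function(data, response,
    traits = c("leaf_size", "snowmelt_to_leaf_expansion",
               "gdd_to_leaf_expansion", "gdd_to_flowering"),
    alpha = 0.05) {
  needed <- c(response, traits, "microhabitat", "transect", "site")
  missingCols <- setdiff(needed, names(data))
  if (length(missingCols))
    stop("data lacking column(s): ", paste(missingCols, collapse = ", "),
         call. = FALSE)
  dd <- data[stats::complete.cases(data[, needed]), needed, drop = FALSE]
  if (length(unique(dd$site)) < 3L)
    stop("fewer than 3 sites: the transect/site random structure collapses; ",
         "fit a fixed-effects-only regression instead", call. = FALSE)
  if (length(unique(dd$microhabitat)) < 2L)
    stop("microhabitat factor is constant", call. = FALSE)
  dd$microhabitat <- factor(dd$microhabitat)
  dd$transect <- factor(dd$transect)
  dd$site <- factor(dd$site)
  zn <- paste0("z_", traits)
  for (k in seq_along(traits)) dd[[zn[k]]] <- standardizeTraits(dd[[traits[k]]])
  fml <- stats::as.formula(paste(
    response, "~", paste(zn, collapse = " + "), "+ microhabitat +",
    paste(paste0(zn, ":microhabitat"), collapse = " + ")))
  fit <- nlme::lme(fixed = fml, random = ~ 1 | transect / site, data = dd,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                              msMaxIter = 200, niterEM = 50,
                                              returnObject = TRUE))
  av <- stats::anova(fit, type = "marginal")
  est <- nlme::fixef(fit)
  terms <- rownames(av)
  tab <- data.frame(term = terms,
                    Est = NA_real_,
                    numDF = av$numDF, denDF = av$denDF,
                    Fvalue = av$`F-value`, p = av$`p-value`,
                    stringsAsFactors = FALSE)
  ## single-df terms carry their coefficient as the estimate
  lev2 <- levels(dd$microhabitat)[2]
  coefKey <- gsub(paste0("microhabitat", lev2), "microhabitat",
                  names(est), fixed = TRUE)
  for (i in seq_along(terms)) {
    if (av$numDF[i] == 1) {
      hit <- which(coefKey == terms[i])
      if (length(hit) == 1) tab$Est[i] <- est[hit]
    }
  }
  intTerms <- paste0(zn, ":microhabitat")
  intP <- tab$p[match(intTerms, tab$term)]
  interactionSignificant <- !is.na(intP) & intP < alpha
  names(interactionSignificant) <- traits
  vc <- nlme::VarCorr(fit)
  ranefSD <- suppressWarnings(c(
    transect = as.numeric(vc[2, "StdDev"]),
    siteInTransect = as.numeric(vc[4, "StdDev"]),
    residual = as.numeric(vc[nrow(vc), "StdDev"])))
  out <- list(table = tab, interactionSignificant = interactionSignificant,
              ranefSD = ranefSD, model = fit, data = dd,
              traits = traits, response = response, alpha = alpha)
  class(out) <- "PerformanceModelFit"
  out
}

#' @export
print.PerformanceModelFit <- function(x, ...) {
  cat(sprintf("Performance regression: %s ~ 4 standardized traits x microhabitat (n = %d)\n",
              x$response, nrow(x$data)))
  print(transform(x$table, Est = round(Est, 3), Fvalue = round(Fvalue, 3),
                  p = round(p, 4)), row.names = FALSE)
  sig <- names(x$interactionSignificant)[x$interactionSignificant]
  cat(if (length(sig))
        paste("significant trait x microhabitat interaction:",
              paste(sig, collapse = ", "), "\n")
      else "no significant trait x microhabitat interaction\n")
  invisible(x)
}

#' Per-microhabitat refits for traits with significant interactions
#'
#' When a trait x microhabitat interaction passes the significance gate,
#' the regression is refit separately within each microhabitat (same
#' traits, same transect/site random structure) so the habitat-specific
#' slope signs can be read off directly.
#'
#' @param fit a `PerformanceModelFit` from [fitPerformanceModel()].
#' @return Named list (one element per microhabitat level) of coefficient
#'   data.frames: `term`, `Est`, `SE`, `df`, `t`, `p`.
#' @export
refitByMicrohabitat <- function(fit) {
  stopifnot(inherits(fit, "PerformanceModelFit"))
  if (!any(fit$interactionSignificant))
    stop("no significant trait x microhabitat interaction; ",
         "per-habitat refit not triggered", call. = FALSE)
  dd <- fit$data
  zn <- paste0("z_", fit$traits)
  fml <- stats::as.formula(paste(fit$response, "~",
                                 paste(zn, collapse = " + ")))
  out <- lapply(levels(dd$microhabitat), function(h) {
    sub <- droplevels(dd[dd$microhabitat == h, , drop = FALSE])
    if (nrow(sub) < length(zn) + 3L || length(unique(sub$site)) < 2L)
      stop("microhabitat subset '", h, "' too small for the refit",
           call. = FALSE)
    m <- nlme::lme(fixed = fml, random = ~ 1 | transect / site, data = sub,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
    tt <- summary(m)$tTable
    data.frame(term = rownames(tt), Est = tt[, "Value"],
               SE = tt[, "Std.Error"], df = tt[, "DF"],
               t = tt[, "t-value"], p = tt[, "p-value"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- levels(dd$microhabitat)
  out
}
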