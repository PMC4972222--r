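#' @include AllClasses.R relatedness.R
#' @importFrom stats model.matrix optimize pnorm qnorm pf var optim optimHess
NULL

#' Fixed-effect design for the across-site animal model
#'
#' Treatment-coded design with intercept for transect (3 levels), elevation
#' (2), microhabitat (2) and the microhabitat x elevation and
#' microhabitat x transect interactions. Aliased (rank-deficient) columns —
#' e.g. with a single site — are dropped with a warning and reported.
#'
#' @param data data.frame with columns `transect`, `elevation`,
#'   `microhabitat` (character or factor).
#' @param formula model formula (default the five stated terms).
#' @return Numeric design matrix with attributes `assign`, `termLabels` and
#'   `dropped` (names of removed columns).
#' @examples
#' d <- expand.grid(transect = c("T1", "T2", "T3"),
#'                  elevation = c("low", "high"),
#'                  microhabitat = c("ridge", "snowbed"))
#' ncol(buildFixedDesign(d))  # 8
#' @export
buildFixedDesign <- function(data,
    formula = ~ transect + elevation + microhabitat +
      microhabitat:elevation + microhabitat:transect) {
  vars <- all.vars(formula)
  missingVars <- setdiff(vars, names(data))
  if (length(missingVars))
    stop("missing factor column(s): ", paste(missingVars, collapse = ", "),
         call. = FALSE)
  for (v in vars) {
    if (anyNA(data[[v]])) stop("factor ", v, " has missing values", call. = FALSE)
    data[[v]] <- factor(data[[v]])
  }
  ## constant factors carry no contrast: drop every term involving them
  constant <- vars[vapply(vars, function(v) nlevels(data[[v]]) < 2L, logical(1))]
  if (length(constant)) {
    labs <- attr(stats::terms(formula), "term.labels")
    hit <- vapply(labs, function(tl)
      any(constant %in% strsplit(tl, ":", fixed = TRUE)[[1]]), logical(1))
    warning("dropping aliased term(s) with a constant factor: ",
            paste(labs[hit], collapse = ", "), call. = FALSE)
    labs <- labs[!hit]
    formula <- if (length(labs))
      stats::reformulate(labs) else ~ 1
  }
  X <- stats::model.matrix(formula, data)
  asg <- attr(X, "assign")
  qrX <- qr(X)
  dropped <- character()
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    asg <- asg[keep]
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "assign") <- asg
  attr(X, "termLabels") <- attr(stats::terms(formula), "term.labels")
  attr(X, "dropped") <- dropped
  X
}

## Profile REML log-likelihood over lambda = va/ve, in the eigenbasis of M.
## ytil, Xtil: rotated response/design; d: eigenvalues of M.
## Returns list(ll, sigmaE, beta, logdetB).
.profileREML <- function(lambda, ytil, Xtil, d) {
  n <- length(ytil); p <- ncol(Xtil)
  w <- lambda * d + 1
  Xw <- Xtil / w
  B <- crossprod(Xtil, Xw)
  cB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cB)) return(list(ll = -Inf))
  beta <- backsolve(cB, forwardsolve(t(cB), crossprod(Xw, ytil)))
  r <- ytil - Xtil %*% beta
  rss <- sum(r^2 / w)
  sigmaE <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(sigmaE) + 1 + log(2 * pi)) +
                sum(log(w)) + 2 * sum(log(diag(cB))))
  list(ll = ll, sigmaE = sigmaE, beta = beta)
}

## Expected (Fisher) information for (va, ve) at the optimum, computed in
## the eigenbasis where V = diag(va * d + ve).
.remlInformation <- function(va, ve, ytil, Xtil, d) {
  v <- va * d + ve
  Xv <- Xtil / v
  B <- crossprod(Xtil, Xv)
  P <- diag(1 / v) - Xv %*% solve(B, t(Xv))
  P2 <- P * P
  I11 <- 0.5 * as.numeric(t(d) %*% P2 %*% d)
  I12 <- 0.5 * sum(P2 %*% d)
  I22 <- 0.5 * sum(P2)
  matrix(c(I11, I12, I12, I22), 2, 2)
}

#' Univariate REML animal model with a marker-inferred relatedness matrix
#'
#' Fits `y = X beta + a + e` with `Var(a) = va * M`, `Var(e) = ve * I` by
#' restricted maximum likelihood. A single spectral decomposition of `M`
#' reduces the problem to a one-dimensional profile over the variance ratio
#' `lambda = va/ve`, searched on a log grid (including the `lambda = 0`
#' boundary) and refined by Brent's method. Standard errors come from the
#' inverse expected information in `(va, ve)`; the heritability confidence
#' interval is delta-method based and is not truncated at 0 or 1.
#'
#' @param y numeric response (one record per unique genotype); `NA`s are
#'   dropped listwise together with the matching rows of `X` and `M`.
#' @param X fixed-effect design from [buildFixedDesign()] (or any full-rank
#'   numeric matrix with an intercept).
#' @param M [RelatednessMatrix-class] or symmetric PSD base matrix, aligned
#'   with `y`.
#' @param trait trait name carried into the fit object.
#' @param eigenM optional precomputed `eigen(M, symmetric = TRUE)` to reuse
#'   across traits.
#' @param lambdaBounds search bounds for `va/ve` (default `c(1e-6, 1e6)`).
#' @param gridPoints points of the coarse log-spaced grid (default 61).
#' @return A [VarianceComponentFit-class].
#' @seealso [heritability()], [heritabilityCI()], [varianceZTest()],
#'   [waldFTests()], [remlBivariate()]
#' @export
remlUnivariate <- function(y, X, M, trait = "trait", eigenM = NULL,
                           lambdaBounds = c(1e-6, 1e6), gridPoints = 61L) {
  if (is(M, "RelatednessMatrix")) M <- M@values
  if (is.null(dim(X))) X <- cbind(`(Intercept)` = X)
  stopifnot(length(y) == nrow(X), nrow(M) == length(y))
  xattr <- attributes(X)[c("assign", "termLabels", "dropped")]
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    M <- M[keep, keep, drop = FALSE]
    eigenM <- NULL
  }
  attr(X, "assign") <- xattr$assign
  attr(X, "termLabels") <- xattr$termLabels
  attr(X, "dropped") <- xattr$dropped
  n <- length(y)
  if (n < ncol(X) + 2L) stop("too few complete cases", call. = FALSE)
  if (stats::var(y) == 0) stop("constant response", call. = FALSE)
  off <- M[upper.tri(M)]
  if (any(off >= 1 - 1e-8))
    stop("relatedness matrix contains identical genotypes (r = 1); ",
         "filter clonal replicates first (see assignClones/filterClones)",
         call. = FALSE)
  nonIdent <- all(abs(off) < 1e-10)
  if (is.null(eigenM)) {
    eigenM <- eigen((M + t(M)) / 2, symmetric = TRUE)
    if (min(eigenM$values) < -1e-6)
      stop("relatedness matrix is not positive semi-definite; ",
           "apply nearPositiveDefinite() first", call. = FALSE)
  }
  d <- pmax(eigenM$values, 0)
  U <- eigenM$vectors
  ytil <- as.numeric(crossprod(U, y))
  Xtil <- crossprod(U, X)
  p <- ncol(Xtil)

  grid <- c(0, exp(seq(log(lambdaBounds[1]), log(lambdaBounds[2]),
                       length.out = gridPoints)))
  lls <- vapply(grid, function(l) .profileREML(l, ytil, Xtil, d)$ll, numeric(1))
  best <- which.max(lls)
  lambda <- grid[best]
  if (best > 1L) {
    lo <- grid[max(best - 1L, 2L)]; hi <- grid[min(best + 1L, length(grid))]
    opt <- stats::optimize(function(ll)
      .profileREML(exp(ll), ytil, Xtil, d)$ll,
      interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-10)
    if (opt$objective > lls[best]) lambda <- exp(opt$maximum)
  }
  ## re-check the boundary: a flat profile can favour lambda = 0
  fit0 <- .profileREML(0, ytil, Xtil, d)
  fitL <- .profileREML(lambda, ytil, Xtil, d)
  if (fit0$ll >= fitL$ll) { lambda <- 0; fitL <- fit0 }

  ve <- fitL$sigmaE
  va <- lambda * ve
  info <- .remlInformation(va, ve, ytil, Xtil, d)
  Cmat <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, 2, 2))
  seVa <- sqrt(Cmat[1, 1]); seVe <- sqrt(Cmat[2, 2]); covVaVe <- Cmat[1, 2]

  h2 <- if (nonIdent) NA_real_ else va / (va + ve)
  h2SE <- if (nonIdent || anyNA(Cmat)) NA_real_ else {
    gr <- c(ve, -va) / (va + ve)^2
    sqrt(max(0, as.numeric(t(gr) %*% Cmat %*% gr)))
  }
  h2CI <- if (is.na(h2SE)) c(NA_real_, NA_real_) else
    h2 + c(-1, 1) * stats::qnorm(0.975) * h2SE
  zP <- if (is.na(seVa) || nonIdent) NA_real_ else
    stats::pnorm(va / seVa, lower.tail = FALSE)

  wald <- .waldTable(Xtil, ytil, lambda, d, ve, n, p, X)

  new("VarianceComponentFit", trait = trait,
      va = if (nonIdent) NA_real_ else va,
      ve = if (nonIdent) NA_real_ else ve,
      seVa = seVa, seVe = seVe, covVaVe = covVaVe,
      logLik = fitL$ll, h2 = h2, h2SE = h2SE, h2CI = h2CI, zP = zP,
      lambda = lambda, n = as.integer(n), wald = wald,
      converged = TRUE, nonIdentifiable = nonIdent,
      dropped = as.character(attr(X, "dropped") %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Incremental (sequential) Wald F per fixed term at the estimated V.
.waldTable <- function(Xtil, ytil, lambda, d, sigmaE, n, p, X) {
  asg <- attr(X, "assign"); labels <- attr(X, "termLabels")
  if (is.null(asg) || is.null(labels) || !length(labels))
    return(data.frame(term = character(), df = integer(),
                      Fvalue = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  w <- lambda * d + 1
  rssFor <- function(cols) {
    Xs <- Xtil[, cols, drop = FALSE]
    Xw <- Xs / w
    B <- crossprod(Xs, Xw)
    beta <- solve(B, crossprod(Xw, ytil))
    sum((ytil - Xs %*% beta)^2 / w)
  }
  present <- sort(unique(asg[asg > 0]))
  rssPrev <- rssFor(which(asg == 0))
  ddf <- n - p
  rows <- lapply(present, function(tj) {
    cols <- which(asg <= tj)
    rssj <- rssFor(cols)
    q <- sum(asg == tj)
    Fv <- (rssPrev - rssj) / q / sigmaE
    rssPrev <<- rssj
    data.frame(term = labels[tj], df = q, Fvalue = Fv,
               p = stats::pf(Fv, q, ddf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "denDf") <- ddf
  out
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = Va / (Va + Ve)` — the fraction of phenotypic variance explained by
#' additive genetic variance.
#'
#' @param va additive genetic variance (>= 0).
#' @param ve residual variance (>= 0; not both zero).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' heritability(10.360, 47.842)  # 0.178
#' @export
heritability <- function(va, ve) {
  if (any(va < 0) || any(ve < 0)) stop("variances must be >= 0", call. = FALSE)
  if (any(va + ve == 0)) stop("Va + Ve must be positive", call. = FALSE)
  va / (va + ve)
}

#' Delta-method confidence interval for heritability
#'
#' Propagates the sampling (co)variance of `(Va, Ve)` through the ratio
#' `Va/(Va+Ve)`; bounds are deliberately not truncated, so the lower bound
#' of a weakly supported heritability can fall below zero.
#'
#' @param fit a [VarianceComponentFit-class].
#' @param level confidence level (default 0.95).
#' @return Numeric `c(low, up)`.
#' @export
heritabilityCI <- function(fit, level = 0.95) {
  stopifnot(is(fit, "VarianceComponentFit"))
  if (is.na(fit@h2SE)) {
    warning("CI unavailable (singular information)", call. = FALSE)
    return(c(NA_real_, NA_real_))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  fit@h2 + c(-1, 1) * z * fit@h2SE
}

#' One-sided Z-test for the additive genetic variance
#'
#' `Z = Va / SE(Va)`; one-sided because variances cannot be negative. At
#' the `Va = 0` boundary the convention is `p = 0.5`.
#'
#' @param fit a [VarianceComponentFit-class].
#' @return p-value.
#' @export
varianceZTest <- function(fit) {
  stopifnot(is(fit, "VarianceComponentFit"))
  fit@zP
}

#' Incremental Wald F tests for the fixed terms
#'
#' Sequential F statistics computed at the estimated covariance, with
#' residual-method denominator degrees of freedom `n - rank(X)`.
#'
#' @param fit a [VarianceComponentFit-class].
#' @return data.frame `term`, `df`, `Fvalue`, `p` with attribute `denDf`.
#' @export
waldFTests <- function(fit) {
  stopifnot(is(fit, "VarianceComponentFit"))
  fit@wald
}

## ---- bivariate REML ----------------------------------------------------

## Negative REML log-likelihood for two traits in the eigenbasis of M.
## theta parameterizes Cholesky factors of G0 and R0:
## (t1, t2, t3, t4, t5, t6) -> LG = [[exp(t1),0],[t2,exp(t3)]], LR likewise.
.bivNegREML <- function(theta, z1, z2, Xtil, d, epsR = 0) {
  LG <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  LR <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
  G0 <- LG %*% t(LG); R0 <- LR %*% t(LR) + diag(epsR, 2)
  .bivNegREMLdirect(c(G0[1, 1], G0[2, 2], G0[1, 2],
                      R0[1, 1], R0[2, 2], R0[1, 2]), z1, z2, Xtil, d)
}

## Same likelihood in the direct parameterization
## (va1, va2, cova, ve1, ve2, cove); used for Hessian-based SEs.
.bivNegREMLdirect <- function(par, z1, z2, Xtil, d) {
  va1 <- par[1]; va2 <- par[2]; cva <- par[3]
  ve1 <- par[4]; ve2 <- par[5]; cve <- par[6]
  n <- length(z1); p <- ncol(Xtil)
  v11 <- va1 * d + ve1; v22 <- va2 * d + ve2; v12 <- cva * d + cve
  det2 <- v11 * v22 - v12^2
  if (any(det2 <= 0) || any(v11 <= 0)) return(1e10)
  al <- v22 / det2; be <- -v12 / det2; ga <- v11 / det2
  C11 <- crossprod(Xtil, Xtil * al)
  C12 <- crossprod(Xtil, Xtil * be)
  C22 <- crossprod(Xtil, Xtil * ga)
  C <- rbind(cbind(C11, C12), cbind(C12, C22))
  b <- c(crossprod(Xtil, al * z1 + be * z2),
         crossprod(Xtil, be * z1 + ga * z2))
  cC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(cC)) return(1e10)
  quad <- sum(al * z1^2 + 2 * be * z1 * z2 + ga * z2^2)
  bCb <- sum(b * backsolve(cC, forwardsolve(t(cC), b)))
  0.5 * (sum(log(det2)) + 2 * sum(log(diag(cC))) + quad - bCb +
         (2 * n - 2 * p) * log(2 * pi))
}

#' Bivariate REML animal model: additive genetic covariance of two traits
#'
#' Maximizes the two-trait REML likelihood with `Var(a) = G0 (x) M` and
#' `Var(e) = R0 (x) I`, the 2x2 matrices `G0` and `R0` parameterized via
#' Cholesky factors so they stay positive semi-definite. Optimization
#' (Nelder-Mead then BFGS polish) starts from the univariate fits with zero
#' covariance. Only jointly complete cases are used.
#'
#' @param y1,y2 numeric trait vectors aligned with `M`.
#' @param X fixed-effect design (shared by both traits).
#' @param M relatedness matrix ([RelatednessMatrix-class] or base matrix).
#' @param eigenM optional precomputed spectral decomposition of `M`.
#' @param maxit Nelder-Mead iteration budget (default 2000).
#' @return list with `covA` (additive covariance), `seCovA`, `zP`
#'   (two-sided), `G0`, `R0`, `logLik`, `convergence`, `n`.
#' @export
remlBivariate <- function(y1, y2, X, M, eigenM = NULL, maxit = 2000L) {
  if (is(M, "RelatednessMatrix")) M <- M@values
  stopifnot(length(y1) == length(y2), length(y1) == nrow(M))
  keep <- !is.na(y1) & !is.na(y2)
  if (!all(keep)) {
    y1 <- y1[keep]; y2 <- y2[keep]
    X <- X[keep, , drop = FALSE]; M <- M[keep, keep, drop = FALSE]
    eigenM <- NULL
  }
  if (is.null(eigenM)) eigenM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ## perfectly collinear traits make the 2x2 residual structure singular;
  ## the additive covariance then equals the (scaled) univariate variance
  rho <- stats::cor(y1, y2)
  if (abs(rho) >= 1 - 1e-12) {
    f1 <- remlUnivariate(y1, X, M, eigenM = eigenM)
    sc <- sign(rho) * stats::sd(y2) / stats::sd(y1)
    return(list(covA = sc * f1@va, seCovA = abs(sc) * f1@seVa,
                zP = f1@zP, G0 = matrix(c(f1@va, sc * f1@va, sc * f1@va,
                                          sc^2 * f1@va), 2, 2),
                R0 = matrix(c(f1@ve, sc * f1@ve, sc * f1@ve,
                              sc^2 * f1@ve), 2, 2),
                logLik = NA_real_, convergence = 0L, n = length(y1),
                collinear = TRUE))
  }
  d <- pmax(eigenM$values, 0); U <- eigenM$vectors
  z1 <- as.numeric(crossprod(U, y1)); z2 <- as.numeric(crossprod(U, y2))
  Xtil <- crossprod(U, X)

  f1 <- remlUnivariate(y1, X, M, eigenM = eigenM)
  f2 <- remlUnivariate(y2, X, M, eigenM = eigenM)
  lg1 <- 0.5 * log(max(f1@va, 1e-4 * stats::var(y1)))
  lg3 <- 0.5 * log(max(f2@va, 1e-4 * stats::var(y2)))
  lr1 <- 0.5 * log(max(f1@ve, 1e-4 * stats::var(y1)))
  lr3 <- 0.5 * log(max(f2@ve, 1e-4 * stats::var(y2)))
  start <- c(lg1, 0, lg3, lr1, 0, lr3)
  ## tiny relative ridge on R0 keeps the restricted likelihood bounded when
  ## the two traits are (near-)collinear, without affecting regular fits
  epsR <- 1e-8 * sqrt(stats::var(y1) * stats::var(y2))

  nm <- stats::optim(start, .bivNegREML, z1 = z1, z2 = z2, Xtil = Xtil, d = d,
                     epsR = epsR, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12))
  bf <- tryCatch(
    stats::optim(nm$par, .bivNegREML, z1 = z1, z2 = z2, Xtil = Xtil, d = d,
                 epsR = epsR, method = "BFGS", control = list(maxit = 200)),
    error = function(e) nm)
  best <- if (bf$value <= nm$value) bf else nm
  theta <- best$par
  LG <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  LR <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
  G0 <- LG %*% t(LG); R0 <- LR %*% t(LR) + diag(epsR, 2)

  par0 <- c(G0[1, 1], G0[2, 2], G0[1, 2], R0[1, 1], R0[2, 2], R0[1, 2])
  H <- tryCatch(stats::optimHess(par0, .bivNegREMLdirect,
                                 z1 = z1, z2 = z2, Xtil = Xtil, d = d),
                error = function(e) NULL)
  seCovA <- NA_real_
  if (!is.null(H)) {
    Cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Cov) && Cov[3, 3] > 0) seCovA <- sqrt(Cov[3, 3])
  }
  zP <- if (is.na(seCovA)) NA_real_ else
    2 * stats::pnorm(abs(G0[1, 2] / seCovA), lower.tail = FALSE)
  list(covA = G0[1, 2], seCovA = seCovA, zP = zP, G0 = G0, R0 = R0,
       logLik = -best$value, convergence = best$convergence,
       n = length(z1))
}

#' Additive genetic (co)variance matrix across traits
#'
#' Diagonal entries come from univariate REML fits (so they equal the
#' per-trait additive variances exactly); off-diagonals from pairwise
#' bivariate fits. Significance flags are one-sided Z-tests on the
#' diagonal and two-sided on the covariances.
#'
#' @param traits data.frame or matrix of trait values (columns = traits),
#'   rows aligned with `M`.
#' @param X fixed-effect design from [buildFixedDesign()].
#' @param M relatedness matrix.
#' @return A [GMatrix-class].
#' @export
gMatrix <- function(traits, X, M) {
  if (is(M, "RelatednessMatrix")) M <- M@values
  Y <- as.matrix(traits)
  tn <- colnames(Y)
  if (is.null(tn)) tn <- paste0("trait", seq_len(ncol(Y)))
  if (ncol(Y) < 2L) stop("need at least two traits", call. = FALSE)
  k <- ncol(Y)
  V <- matrix(NA_real_, k, k, dimnames = list(tn, tn))
  P <- matrix(NA_real_, k, k, dimnames = list(tn, tn))
  complete <- !anyNA(Y)
  eigenM <- if (complete) eigen((M + t(M)) / 2, symmetric = TRUE) else NULL
  for (i in seq_len(k)) {
    fi <- remlUnivariate(Y[, i], X, M, trait = tn[i], eigenM = eigenM)
    V[i, i] <- fi@va; P[i, i] <- fi@zP
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    b <- remlBivariate(Y[, i], Y[, j], X, M, eigenM = eigenM)
    V[i, j] <- V[j, i] <- b$covA
    P[i, j] <- P[j, i] <- b$zP
  }
  new("GMatrix", traits = tn, values = V, zP = P)
}
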