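## Shared fixtures and independent oracles for the markerQG suite.

## Build a GenotypeTable from a list of per-individual locus calls, e.g.
## list(i1 = list(c(101, 103), c(200, 200)), ...). NULL = missing call.
makeGT <- function(calls, loci = NULL, site = character()) {
  n <- length(calls); L <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (j in seq_len(L))
    if (!is.null(calls[[i]][[j]])) a[i, j, ] <- as.integer(calls[[i]][[j]])
  GenotypeTable(names(calls), loci, a, site)
}

## Canonical form of a partition (list of member vectors) for set equality.
canonPartition <- function(part)
  sort(unname(vapply(part, function(m) paste(sort(m), collapse = "|"),
                     character(1))))

## Independent dense REML log-likelihood (full-matrix route: chol of V),
## same definitional constant as the package reports.
denseREMLll <- function(y, X, va, ve, M) {
  n <- length(y); p <- ncol(X)
  V <- va * M + ve * diag(n)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (2 * sum(log(diag(cV))) + determinant(B)$modulus[1] +
                     t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}

## Brute-force profile over a lambda grid using the dense oracle: at each
## lambda the residual variance is profiled out analytically.
denseGridMax <- function(y, X, M, nGrid = 1000) {
  n <- length(y); p <- ncol(X)
  lam <- exp(seq(log(1e-6), log(1e6), length.out = nGrid))
  lls <- vapply(lam, function(l) {
    W <- l * M + diag(n)
    Wi <- chol2inv(chol(W))
    B <- t(X) %*% Wi %*% X
    beta <- solve(B, t(X) %*% Wi %*% y)
    r <- y - X %*% beta
    se <- as.numeric(t(r) %*% Wi %*% r) / (n - p)
    denseREMLll(y, X, l * se, se, M)
  }, numeric(1))
  max(lls)
}

## Converged alternating-projections oracle for the nearest PSD matrix
## with unit diagonal: eigenvalue clipping + diagonal restoration iterated.
apNearPD <- function(v, tol = 1e-9, maxit = 5000) {
  x <- v
  for (k in seq_len(maxit)) {
    e <- eigen(x, symmetric = TRUE)
    y <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    diag(y) <- 1
    if (max(abs(y - x)) < tol &&
        min(eigen(y, symmetric = TRUE, only.values = TRUE)$values) > -1e-9)
      return(y)
    x <- y
  }
  x
}

## Exhaustive genotype-pair enumeration oracle for single-locus PI.
enumPI <- function(p) {
  p <- unname(p)
  K <- length(p)
  tot <- 0
  for (i in 1:K) for (j in i:K) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pg^2
  }
  tot
}

## Small deterministic two-locus GENEPOP fixture text.
genepopFixture <- function(commaLoci = FALSE) {
  locusLines <- if (commaLoci) "locA, locB" else c("locA", "locB")
  c("toy data", locusLines, "pop",
    "i1 , 101103 200202",
    "i2 , 101101 200200",
    "i3 , 103103 0000",
    "pop",
    "i4 , 101103 202202")
}
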