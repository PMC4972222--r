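## frequency table helper for hand-built cases
freqTab <- function(...) {
  fr <- list(...)
  new("AlleleFrequencyTable", freq = fr,
      nGenes = stats::setNames(rep(10L, length(fr)), names(fr)))
}

test_that("all four estimators give r = 1 for duplicated homozygous genotypes", {
  g <- makeGT(list(x = list(c(1, 1), c(5, 5)), y = list(c(1, 1), c(5, 5))))
  f <- freqTab(L1 = c(`1` = 0.5, `2` = 0.5), L2 = c(`5` = 0.3, `6` = 0.7))
  for (est in c("qg", "li", "lr", "wang"))
    expect_equal(pairRelatedness(g, cbind(1, 2), est, f = f), 1,
                 tolerance = 1e-9, label = est)
})

test_that("single-locus values match hand-evaluated estimator formulas", {
  f <- freqTab(L1 = c(`1` = 0.5, `2` = 0.3, `3` = 0.2))
  ## x = (A,B), y = (A,C): QG directions -0.3/0.2 and -0.2/0.3
  g <- makeGT(list(x = list(c(1, 2)), y = list(c(1, 3))))
  expect_equal(pairRelatedness(g, cbind(1, 2), "qg", f = f),
               mean(c(-0.3 / 0.2, -0.2 / 0.3)), tolerance = 1e-12)
  ## x = (A,A), y = (A,B): QG = (0 + 1)/2, LR = (0 + 0)/2, Li = 0.375
  g2 <- makeGT(list(x = list(c(1, 1)), y = list(c(1, 2))))
  expect_equal(pairRelatedness(g2, cbind(1, 2), "qg", f = f), 0.5,
               tolerance = 1e-12)
  expect_equal(pairRelatedness(g2, cbind(1, 2), "lr", f = f), 0,
               tolerance = 1e-12)
  expect_equal(pairRelatedness(g2, cbind(1, 2), "li", f = f),
               (0.75 - 0.6) / (1 - 0.6), tolerance = 1e-12)
  ## Wang: independent solve of the moment system in test code
  p <- c(0.5, 0.3, 0.2)
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
  b <- 2 * a2^2 - a4
  A <- rbind(c(1 - b, a2 - 2 * a2^2 + a4),
             c(-4 * (a3 - a4), 2 * (a2 - 3 * a3 + 2 * a4)),
             c(-4 * (a2 - a2^2 - 2 * a3 + 2 * a4),
               1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4))
  ## genotype pair (AA, AB): categories P1 = 0, P2 = 1, P3 = 0
  rhs <- c(0 - b, 1 - 4 * (a3 - a4), 0 - 4 * (a2 - a2^2 - 2 * a3 + 2 * a4))
  th <- qr.solve(A, rhs)             # least squares
  expect_equal(pairRelatedness(g2, cbind(1, 2), "wang", f = f),
               th[1] + th[2] / 2, tolerance = 1e-10)
})

test_that("estimators are calibrated on simulated unrelated and parent-offspring dyads", {
  ur <- simulateDyads(400, "unrelated", seed = 101)
  po <- simulateDyads(400, "parent-offspring", seed = 102)
  for (est in c("qg", "li", "lr", "wang")) {
    mUR <- mean(pairRelatedness(ur$genotypes, ur$pairs, est, f = ur$freq))
    mPO <- mean(pairRelatedness(po$genotypes, po$pairs, est, f = po$freq))
    expect_lt(abs(mUR), 0.03, label = paste(est, "unrelated"))
    expect_lt(abs(mPO - 0.5), 0.05, label = paste(est, "parent-offspring"))
  }
})

test_that("relatedness matrices are symmetric with unit diagonal and flag unusable pairs", {
  g <- makeGT(list(a = list(c(1, 2), NULL), b = list(NULL, c(9, 9)),
                   c = list(c(1, 1), c(9, 9))))
  f <- freqTab(L1 = c(`1` = 0.5, `2` = 0.5), L2 = c(`8` = 0.4, `9` = 0.6))
  m <- suppressMessages(pairwiseRelatedness(g, "qg", f = f))
  v <- relValues(m)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(1, 3))
  expect_true(is.na(v["a", "b"]))
  expect_equal(m@nMissingPairs, 1L)
  ## conditioning fills the unusable pair with 0 and yields PSD
  mp <- suppressMessages(nearPositiveDefinite(setDiagonalUnity(m)))
  expect_false(anyNA(relValues(mp)))
  expect_gte(min(eigen(relValues(mp), symmetric = TRUE)$values), -1e-8)
})

test_that("estimator matrices rank-correlate on mixed-pedigree data", {
  sim <- simulateGenotypes(nFounders = 40, nGenerations = 1, seed = 55)
  g <- sim$genotypes
  ests <- c("qg", "li", "lr", "wang")
  tri <- lapply(ests, function(e) {
    v <- relValues(pairwiseRelatedness(g, e))
    v[upper.tri(v)]
  })
  for (i in 1:3) for (j in (i + 1):4) {
    rho <- cor(tri[[i]], tri[[j]], method = "spearman", use = "complete.obs")
    expect_gt(rho, 0.5, label = paste(ests[i], "vs", ests[j]))
  }
})

test_that("setDiagonalUnity touches only the diagonal", {
  set.seed(2)
  v <- matrix(rnorm(25, 0, 0.1), 5); v <- (v + t(v)) / 2; diag(v) <- 0.9
  m <- new("RelatednessMatrix", values = v, estimator = "lr", psd = FALSE,
           nMissingPairs = 0L)
  out <- relValues(setDiagonalUnity(m))
  expect_equal(unname(diag(out)), rep(1, 5))
  expect_identical(out[upper.tri(out)], v[upper.tri(v)])
  ## base-matrix input stays a base matrix; identity is a fixed point
  expect_equal(setDiagonalUnity(diag(5) * 0.5), diag(5))
  expect_equal(setDiagonalUnity(diag(5)), diag(5))
})

test_that("nearPositiveDefinite agrees with the alternating-projections oracle", {
  ## already-PD matrix: unchanged within 1e-10
  set.seed(4)
  B <- matrix(rnorm(36, 0, 0.1), 6); S <- crossprod(B) / 6
  v <- stats::cov2cor(S + diag(6))
  out <- relValues(nearPositiveDefinite(v))
  expect_equal(out, v, tolerance = 1e-10)
  ## 2x2 textbook case vs converged oracle
  v2 <- matrix(c(1, 1.2, 1.2, 1), 2)
  o2 <- apNearPD(v2)
  h2 <- relValues(nearPositiveDefinite(v2))
  expect_equal(h2, o2, tolerance = 1e-6)
  ## indefinite 50x50: PSD output, no farther than the converged oracle
  set.seed(7)
  n <- 50
  Bn <- matrix(rnorm(n * n, 0, 0.05), n); Sn <- (Bn + t(Bn)) / 2; diag(Sn) <- 0
  c0 <- -1.03 / min(eigen(Sn, symmetric = TRUE)$values)
  vn <- diag(n) + c0 * Sn          # one eigenvalue at -0.03
  hn <- relValues(nearPositiveDefinite(vn))
  expect_gte(min(eigen(hn, symmetric = TRUE)$values), -1e-8)
  on <- apNearPD(vn)
  expect_lte(norm(hn - vn, "F"), norm(on - vn, "F") + 1e-6)
  ## idempotence
  hn2 <- relValues(nearPositiveDefinite(hn))
  expect_equal(hn2, hn, tolerance = 1e-10)
})
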