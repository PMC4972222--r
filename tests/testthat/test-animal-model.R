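test_that("the 3x2x2 layout with the two stated interactions gives 8 design columns", {
  d <- expand.grid(transect = c("T1", "T2", "T3"), elevation = c("low", "high"),
                   microhabitat = c("ridge", "snowbed"),
                   stringsAsFactors = FALSE)
  X <- buildFixedDesign(d)
  expect_equal(ncol(X), 8L)            # 1 + 2 + 1 + 1 + 1 + 2
  expect_equal(qr(X)$rank, 8L)
  expect_length(attr(X, "dropped"), 0L)
  ## degenerate single-site input: aliased columns dropped with a warning
  d1 <- data.frame(transect = "T1", elevation = "low",
                   microhabitat = "ridge")[rep(1, 10), ]
  expect_warning(X1 <- buildFixedDesign(d1), "aliased")
  expect_equal(ncol(X1), qr(X1)$rank)
  expect_error(buildFixedDesign(data.frame(transect = 1:3)), "missing factor")
})

test_that("heritability is the additive fraction of phenotypic variance", {
  ## printed variance components reproduce the printed heritabilities
  expect_equal(round(heritability(10.360, 47.842), 3), 0.178)
  expect_equal(round(heritability(0.109, 0.664), 3), 0.141)
  expect_equal(round(heritability(0.155, 0.700), 3), 0.181)
  expect_equal(heritability(0, 3), 0)
  expect_equal(heritability(2, 2), 0.5)
  expect_error(heritability(-1, 2), ">= 0")
  expect_error(heritability(0, 0), "positive")
})

test_that("optimizer REML log-likelihood dominates a dense brute-force grid", {
  for (s in 1:4) {
    sim <- simulateGenotypes(nFounders = 25, nGenerations = 1, seed = s)
    tr <- simulateTraits(sim$truth$A, h2 = 0.4, seed = s + 50)
    X <- buildFixedDesign(tr$phenotypes)
    y <- tr$phenotypes$trait1
    fit <- remlUnivariate(y, X, sim$truth$A)
    gridMax <- denseGridMax(y, X, sim$truth$A, nGrid = 400)
    expect_gte(fit@logLik, gridMax - 1e-6)
    ## and the dense oracle evaluated at the fitted components agrees
    expect_equal(fit@logLik, denseREMLll(y, X, fit@va, fit@ve, sim$truth$A),
                 tolerance = 1e-8)
  }
})

test_that("REML estimates respect location and scale equivariance", {
  sim <- simulateGenotypes(nFounders = 60, nGenerations = 1, seed = 13)
  tr <- simulateTraits(sim$truth$A, h2 = 0.35, seed = 14)
  X <- buildFixedDesign(tr$phenotypes)
  y <- tr$phenotypes$trait1
  f0 <- remlUnivariate(y, X, sim$truth$A)
  fShift <- remlUnivariate(y + 100, X, sim$truth$A)
  expect_equal(varianceComponents(fShift), varianceComponents(f0),
               tolerance = 1e-6)
  fScale <- remlUnivariate(3 * y, X, sim$truth$A)
  expect_equal(unname(fScale@va), unname(9 * f0@va), tolerance = 1e-4)
  expect_equal(fScale@h2, f0@h2, tolerance = 1e-5)
  ## shuffled rows give the same fit
  perm <- sample(length(y))
  fPerm <- remlUnivariate(y[perm], X[perm, , drop = FALSE],
                          sim$truth$A[perm, perm])
  expect_equal(fPerm@h2, f0@h2, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with actionable messages", {
  sim <- simulateGenotypes(nFounders = 30, nGenerations = 1, seed = 3)
  A <- sim$truth$A
  n <- nrow(A)
  X <- cbind(rep(1, n))
  expect_error(remlUnivariate(rep(2, n), X, A), "constant response")
  ## clones retained: r = 1 off-diagonal
  A1 <- A; A1[1, 2] <- A1[2, 1] <- 1
  expect_error(remlUnivariate(rnorm(n), X, A1), "clonal")
  ## non-PSD matrix points at the conditioning step
  A2 <- A; A2[1, 2] <- A2[2, 1] <- -5
  expect_error(remlUnivariate(rnorm(n), X, A2), "nearPositiveDefinite")
  ## M = I: additive and residual variance are confounded
  set.seed(1)
  fI <- remlUnivariate(rnorm(n), X, diag(n))
  expect_true(fI@nonIdentifiable)
  expect_true(is.na(fI@h2))
})

test_that("Z-test and boundary conventions behave as documented", {
  ## truly non-heritable trait often lands on the va = 0 boundary
  sim <- simulateGenotypes(nFounders = 50, nGenerations = 1, seed = 17)
  tr <- simulateTraits(sim$truth$A, h2 = 0, seed = 18)
  X <- buildFixedDesign(tr$phenotypes)
  fit <- remlUnivariate(tr$phenotypes$trait1, X, sim$truth$A)
  if (fit@va == 0) expect_equal(varianceZTest(fit), 0.5)
  expect_gte(varianceZTest(fit), 0.05)   # must not reject under the null here
  ## null rejection rate stays at or below nominal (boundary-conservative)
  rej <- vapply(1:30, function(s) {
    simn <- simulateGenotypes(nFounders = 50, nGenerations = 1, seed = 300 + s)
    trn <- simulateTraits(simn$truth$A, h2 = 0, seed = 400 + s)
    Xn <- buildFixedDesign(trn$phenotypes)
    fn <- remlUnivariate(trn$phenotypes$trait1, Xn, simn$truth$A)
    varianceZTest(fn) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.12)
})

test_that("incremental Wald F reduces to classical ANOVA when va = 0", {
  set.seed(4)
  A <- simulateGenotypes(nFounders = 20, nGenerations = 1, nPerGeneration = 40,
                         seed = 5)$truth$A
  d <- data.frame(microhabitat = rep(c("ridge", "snowbed"), each = 30))
  X <- stats::model.matrix(~ microhabitat, d)
  attr(X, "assign") <- c(0L, 1L); attr(X, "termLabels") <- "microhabitat"
  y <- rnorm(60) + 0.8 * (d$microhabitat == "snowbed")
  fit <- remlUnivariate(y, X, A)
  skipCheck <- fit@lambda > 0     # only the boundary case has the ANOVA oracle
  if (!skipCheck) {
    w <- waldFTests(fit)
    a <- anova(lm(y ~ microhabitat, d))
    expect_equal(w$Fvalue, a$`F value`[1], tolerance = 1e-8)
    expect_equal(w$p, a$`Pr(>F)`[1], tolerance = 1e-8)
  }
  ## full design reports one row per requested term
  sim <- simulateGenotypes(nFounders = 60, nGenerations = 1, seed = 6)
  tr <- simulateTraits(sim$truth$A, h2 = 0.3,
                       effects = list(microhabitat = 1), seed = 7)
  Xf <- buildFixedDesign(tr$phenotypes)
  ff <- remlUnivariate(tr$phenotypes$trait1, Xf, sim$truth$A)
  w <- waldFTests(ff)
  expect_equal(w$term, attr(Xf, "termLabels"))
  expect_true(all(w$p >= 0 & w$p <= 1))
  ## the planted microhabitat effect is detected
  expect_lt(w$p[w$term == "microhabitat"], 0.01)
  ## listwise deletion keeps the term bookkeeping intact
  yNA <- tr$phenotypes$trait1; yNA[1:10] <- NA
  wNA <- waldFTests(remlUnivariate(yNA, Xf, sim$truth$A))
  expect_equal(wNA$term, attr(Xf, "termLabels"))
})

test_that("delta-method heritability SE tracks the parametric bootstrap", {
  sim <- simulateGenotypes(nFounders = 60, nGenerations = 1, seed = 23)
  A <- sim$truth$A
  tr <- simulateTraits(A, h2 = 0.4, seed = 24)
  X <- buildFixedDesign(tr$phenotypes)
  fit <- remlUnivariate(tr$phenotypes$trait1, X, A)
  ci <- heritabilityCI(fit)
  expect_equal(mean(ci), fit@h2, tolerance = 1e-10)   # symmetric by construction
  expect_equal(diff(ci), 2 * 1.96 * fit@h2SE, tolerance = 1e-3)
  ## parametric bootstrap at the fitted components
  eA <- eigen(A, symmetric = TRUE)
  LA <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
  n <- nrow(A)
  set.seed(99)
  h2b <- vapply(1:150, function(b) {
    yb <- as.numeric(X %*% rep(0, ncol(X))) +
      sqrt(fit@va) * as.numeric(LA %*% rnorm(n)) + rnorm(n, 0, sqrt(fit@ve))
    remlUnivariate(yb, X, A, eigenM = eA)@h2
  }, numeric(1))
  expect_lt(abs(sd(h2b) - fit@h2SE) / sd(h2b), 0.40)
})

test_that("heritability is recovered without systematic bias", {
  h2hat <- vapply(1:8, function(s) {
    sim <- simulateGenotypes(nFounders = 200, nGenerations = 2, seed = 600 + s)
    tr <- simulateTraits(sim$truth$A, h2 = 0.3,
                         effects = list(microhabitat = 0.5, transectSD = 0.2),
                         seed = 700 + s)
    X <- buildFixedDesign(tr$phenotypes)
    remlUnivariate(tr$phenotypes$trait1, X, sim$truth$A)@h2
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.3), 0.1)
})

test_that("bivariate REML handles duplication, independence and correlation", {
  sim <- simulateGenotypes(nFounders = 100, nGenerations = 1, seed = 33)
  A <- sim$truth$A
  tr <- simulateTraits(A, h2 = 0.4, seed = 34)
  X <- buildFixedDesign(tr$phenotypes)
  y <- tr$phenotypes$trait1
  ## same trait twice: additive covariance equals the univariate variance
  fu <- remlUnivariate(y, X, A)
  fb <- remlBivariate(y, y, X, A)
  expect_equal(fb$covA, fu@va, tolerance = 1e-4)
  ## independent traits: covariance near zero, not significant
  tr2 <- simulateTraits(A, h2 = c(0.4, 0.4), geneticCorrelation = 0,
                        seed = 35)
  b0 <- remlBivariate(tr2$phenotypes$trait1, tr2$phenotypes$trait2, X, A)
  expect_lt(abs(b0$covA), 0.25)
  ## strong genetic correlation is recovered
  sim2 <- simulateGenotypes(nFounders = 250, nGenerations = 1, seed = 36)
  tr3 <- simulateTraits(sim2$truth$A, h2 = c(0.4, 0.4),
                        geneticCorrelation = 0.8, seed = 37)
  X2 <- buildFixedDesign(tr3$phenotypes)
  b8 <- remlBivariate(tr3$phenotypes$trait1, tr3$phenotypes$trait2, X2,
                      sim2$truth$A)
  rg <- b8$covA / sqrt(b8$G0[1, 1] * b8$G0[2, 2])
  expect_gte(rg, 0.5); expect_lte(rg, 1.0)
})

test_that("the G matrix is symmetric with univariate variances on the diagonal", {
  sim <- simulateGenotypes(nFounders = 75, nGenerations = 1, seed = 41)
  A <- sim$truth$A
  tr <- simulateTraits(A, h2 = c(0.3, 0.3, 0.2), geneticCorrelation = 0,
                       seed = 42)
  X <- buildFixedDesign(tr$phenotypes)
  Y <- tr$phenotypes[, c("trait1", "trait2", "trait3")]
  G <- gMatrix(Y, X, A)
  V <- relValues(G)
  expect_equal(V, t(V))
  for (k in 1:3)
    expect_equal(V[k, k], remlUnivariate(Y[[k]], X, A)@va, tolerance = 1e-8)
  expect_true(validObject(G))
})
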