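#' @include AllClasses.R genotype-io.R
#' @importFrom stats rnorm rgamma rbinom runif
NULL

## Local RNG scope: run code with a given seed without disturbing the
## caller's random stream.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Pedigree additive-relationship matrix by the tabular method.
## ped: data.frame(id, sire, dam) in an order where parents precede
## offspring; founders have NA parents.
.pedigreeA <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s <- match(ped$sire, ped$id); d <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (is.na(s[i])) {            # founder
      A[i, i] <- 1
    } else {
      if (i > 1) {
        prev <- seq_len(i - 1L)
        A[i, prev] <- 0.5 * (A[s[i], prev] + A[d[i], prev])
        A[prev, i] <- A[i, prev]
      }
      A[i, i] <- 1 + 0.5 * A[s[i], d[i]]
    }
  }
  A
}

#' Simulate SSR genotypes with pedigree and clonal structure
#'
#' Founders draw alleles from a skewed per-locus frequency spectrum
#' (symmetric Dirichlet); each descendant generation is produced by
#' Mendelian inheritance from two distinct parents sampled at random from
#' the previous generation. A fraction `cloneRate` of individuals is then
#' duplicated as exact genotype copies (clonal ramets of the same genet,
#' with no genotyping error). The pedigree-based additive relationship
#' matrix A and the full clone map are recorded as ground truth.
#'
#' @param nFounders founder population size.
#' @param nGenerations number of descendant generations (each of size
#'   `nPerGeneration`).
#' @param nPerGeneration descendants per generation (default `nFounders`).
#' @param nLoci number of SSR loci (default 7, a typical highly variable
#'   microsatellite panel).
#' @param allelesPerLocus alleles segregating per locus (default 23).
#' @param cloneRate fraction of individuals duplicated as clones
#'   (default 0).
#' @param dirichletAlpha concentration of the founder allele-frequency
#'   spectrum (default 0.5: many rare plus a few common alleles,
#'   expected heterozygosity about 0.88 at 23 alleles).
#' @param seed integer seed; the run is byte-reproducible given the seed.
#' @return list with `genotypes` (a [GenotypeTable-class] of all patches,
#'   clones included) and `truth`: `pedigree`, `A` (genet-level additive
#'   relationship matrix), `freq` (true [AlleleFrequencyTable-class]),
#'   `cloneMap` (patch id -> genet id), `seed`.
#' @export
simulateGenotypes <- function(nFounders = 300L, nGenerations = 2L,
                              nPerGeneration = nFounders, nLoci = 7L,
                              allelesPerLocus = 23L, cloneRate = 0,
                              dirichletAlpha = 0.5, seed = 1L) {
  stopifnot(nFounders > 1, nGenerations >= 0, nLoci >= 1,
            allelesPerLocus >= 1, cloneRate >= 0, cloneRate < 1)
  .withSeed(seed, {
    sizes <- 100L + 2L * (seq_len(allelesPerLocus) - 1L)  # dinucleotide ladder
    freqs <- lapply(seq_len(nLoci), function(l) {
      p <- stats::rgamma(allelesPerLocus, dirichletAlpha)
      p <- p / sum(p)
      names(p) <- sizes
      p
    })
    nGen <- nFounders + nGenerations * nPerGeneration
    ids <- sprintf("g%04d", seq_len(nGen))
    a <- array(NA_integer_, c(nGen, nLoci, 2L))
    for (l in seq_len(nLoci))
      a[seq_len(nFounders), l, ] <- sample(sizes, 2L * nFounders,
                                           replace = TRUE, prob = freqs[[l]])
    sire <- dam <- rep(NA_character_, nGen)
    prevGen <- seq_len(nFounders)
    at <- nFounders
    for (g in seq_len(nGenerations)) {
      for (k in seq_len(nPerGeneration)) {
        at <- at + 1L
        par2 <- sample(prevGen, 2L)
        sire[at] <- ids[par2[1]]; dam[at] <- ids[par2[2]]
        for (l in seq_len(nLoci)) {
          a[at, l, 1] <- a[par2[1], l, sample(2L, 1L)]
          a[at, l, 2] <- a[par2[2], l, sample(2L, 1L)]
        }
      }
      prevGen <- (at - nPerGeneration + 1L):at
    }
    ped <- data.frame(id = ids, sire = sire, dam = dam,
                      stringsAsFactors = FALSE)
    A <- .pedigreeA(ped)
    nClones <- round(cloneRate * nGen)
    cloneOf <- if (nClones > 0) sample(nGen, nClones) else integer()
    allIdx <- c(seq_len(nGen), cloneOf)
    patchIds <- c(ids, sprintf("c%04d", seq_along(cloneOf)))
    gt <- GenotypeTable(patchIds, sprintf("loc%02d", seq_len(nLoci)),
                        a[allIdx, , , drop = FALSE])
    cloneMap <- stats::setNames(ids[allIdx], patchIds)
    ftab <- new("AlleleFrequencyTable",
                freq = stats::setNames(freqs, sprintf("loc%02d", seq_len(nLoci))),
                nGenes = stats::setNames(rep(NA_integer_, nLoci),
                                         sprintf("loc%02d", seq_len(nLoci))))
    list(genotypes = gt,
         truth = list(pedigree = ped, A = A, freq = ftab,
                      cloneMap = cloneMap, seed = as.integer(seed)))
  })
}

#' Simulate dyads of known relationship for estimator calibration
#'
#' Generates `nPairs` independent dyads from a known allele-frequency
#' spectrum: either two unrelated Hardy-Weinberg draws, or a parent and an
#' offspring that inherits one parental allele (chosen at random) plus one
#' population allele per locus. The true generating frequencies are
#' returned so relatedness estimators can be evaluated without
#' sample-frequency noise (expected r: 0 for unrelated, 0.5 for
#' parent-offspring).
#'
#' @param nPairs number of dyads.
#' @param type `"unrelated"` or `"parent-offspring"`.
#' @param nLoci,allelesPerLocus,dirichletAlpha marker panel as in
#'   [simulateGenotypes()].
#' @param seed integer seed.
#' @return list: `genotypes` ([GenotypeTable-class] of `2 * nPairs`
#'   individuals), `pairs` (two-column index matrix, one row per dyad),
#'   `freq` (true [AlleleFrequencyTable-class]).
#' @export
simulateDyads <- function(nPairs, type = c("unrelated", "parent-offspring"),
                          nLoci = 7L, allelesPerLocus = 23L,
                          dirichletAlpha = 0.5, seed = 1L) {
  type <- match.arg(type)
  .withSeed(seed, {
    sizes <- 100L + 2L * (seq_len(allelesPerLocus) - 1L)
    lociNames <- sprintf("loc%02d", seq_len(nLoci))
    freqs <- lapply(seq_len(nLoci), function(l) {
      p <- stats::rgamma(allelesPerLocus, dirichletAlpha)
      p <- p / sum(p); names(p) <- sizes; p
    })
    names(freqs) <- lociNames
    n <- 2L * nPairs
    a <- array(NA_integer_, c(n, nLoci, 2L))
    i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
    for (l in seq_len(nLoci)) {
      a[i1, l, ] <- sample(sizes, 2L * nPairs, replace = TRUE,
                           prob = freqs[[l]])
      if (type == "unrelated") {
        a[i2, l, ] <- sample(sizes, 2L * nPairs, replace = TRUE,
                             prob = freqs[[l]])
      } else {
        fromParent <- ifelse(stats::runif(nPairs) < 0.5, 1L, 2L)
        a[i2, l, 1] <- a[cbind(i1, l, fromParent)]
        a[i2, l, 2] <- sample(sizes, nPairs, replace = TRUE,
                              prob = freqs[[l]])
      }
    }
    gt <- GenotypeTable(sprintf("d%05d", seq_len(n)), lociNames, a)
    ftab <- new("AlleleFrequencyTable", freq = freqs,
                nGenes = stats::setNames(rep(NA_integer_, nLoci), lociNames))
    list(genotypes = gt, pairs = cbind(i1, i2), freq = ftab)
  })
}

## 12-site field layout: 3 transects x 2 elevations x 2 microhabitats.
.siteLayout <- function() {
  g <- expand.grid(microhabitat = c("ridge", "snowbed"),
                   elevation = c("low", "high"),
                   transect = c("T1", "T2", "T3"),
                   stringsAsFactors = FALSE)
  g$site <- sprintf("%s_%s_%s", g$transect, g$elevation, g$microhabitat)
  g
}

#' Simulate traits under the additive genetic model
#'
#' Forward simulation of `y = X beta + a + e` with breeding values
#' `a ~ N(0, va * A)` (drawn through a PSD factorization of `A`) and
#' i.i.d. residuals `e ~ N(0, ve)`, where `va = h2 * totalVariance`.
#' Individuals are assigned at random to a 12-site layout (3 transects x
#' 2 elevations x 2 microhabitats) and the declared fixed effects are
#' added. Multiple traits can be generated jointly with a declared genetic
#' correlation.
#'
#' @param A additive relationship matrix (PSD), e.g. from
#'   [simulateGenotypes()] ground truth.
#' @param h2 true narrow-sense heritability, one value per trait.
#' @param totalVariance total phenotypic variance per trait (recycled).
#' @param effects list of fixed-effect sizes: `microhabitat` (snowbed minus
#'   ridge), `elevation` (high minus low), `transectSD` (sd of transect
#'   deviations). Defaults 0.
#' @param geneticCorrelation optional correlation of breeding values
#'   between consecutive traits (scalar, used when `length(h2) > 1`).
#' @param traitNames optional trait names.
#' @param seed integer seed.
#' @return list: `phenotypes` (data.frame of id, site factors and one
#'   column per trait), `truth` (breeding values, va, ve, beta, seed).
#' @export
simulateTraits <- function(A, h2, totalVariance = 1,
                           effects = list(), geneticCorrelation = NULL,
                           traitNames = NULL, seed = 1L) {
  stopifnot(all(h2 >= 0), all(h2 <= 1))
  n <- nrow(A)
  k <- length(h2)
  totalVariance <- rep_len(totalVariance, k)
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(k))
  eff <- utils::modifyList(list(microhabitat = 0, elevation = 0,
                                transectSD = 0), effects)
  .withSeed(seed, {
    eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
    if (min(eA$values) < -1e-6) stop("A must be PSD", call. = FALSE)
    LA <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
    layout <- .siteLayout()
    siteIdx <- sample(rep_len(seq_len(nrow(layout)), n))
    fac <- layout[siteIdx, ]
    rownames(fac) <- NULL
    trEff <- stats::setNames(stats::rnorm(3, 0, eff$transectSD),
                             c("T1", "T2", "T3"))
    va <- h2 * totalVariance
    ve <- (1 - h2) * totalVariance
    ## breeding values: LA %*% Z %*% t(LG) has Var = G0 (x) A
    Z <- matrix(stats::rnorm(n * k), n, k)
    G0 <- diag(sqrt(va), k) %*%
      (if (!is.null(geneticCorrelation) && k > 1) {
        R <- matrix(geneticCorrelation, k, k); diag(R) <- 1; R
      } else diag(k)) %*% diag(sqrt(va), k)
    dimnames(G0) <- list(traitNames, traitNames)
    LG <- if (any(va > 0)) {
      eg <- eigen(G0, symmetric = TRUE)
      eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    } else matrix(0, k, k)
    aMat <- LA %*% Z %*% t(LG)
    eMat <- sapply(seq_len(k), function(t) stats::rnorm(n, 0, sqrt(ve[t])))
    eMat <- matrix(eMat, n, k)
    fixed <- eff$microhabitat * (fac$microhabitat == "snowbed") +
      eff$elevation * (fac$elevation == "high") + trEff[fac$transect]
    Y <- aMat + eMat + fixed
    colnames(Y) <- traitNames
    ph <- data.frame(id = rownames(A) %||% sprintf("g%04d", seq_len(n)),
                     site = fac$site, microhabitat = fac$microhabitat,
                     elevation = fac$elevation, transect = fac$transect,
                     stringsAsFactors = FALSE)
    ph <- cbind(ph, as.data.frame(Y))
    list(phenotypes = ph,
         truth = list(breedingValues = aMat, va = va, ve = ve, G0 = G0,
                      effects = eff, transectEffects = trEff,
                      seed = as.integer(seed)))
  })
}

#' Simulate a soil-temperature logger series
#'
#' Near-zero flat readings (snow insulation) until the planted snowmelt
#' day, then a seasonal warm curve with a diurnal cycle, at 2-h
#' resolution with Gaussian noise.
#'
#' @param snowmeltDay planted day-of-year of melt-out.
#' @param site site label.
#' @param startDay,endDay series range in day-of-year.
#' @param winterMean,winterSD under-snow mean and noise sd (degC).
#' @param summerPeak peak of the post-melt seasonal curve (degC).
#' @param diurnalAmplitude half-amplitude of the daily cycle (degC).
#' @param noiseSD post-melt reading noise sd (degC).
#' @param seed integer seed.
#' @return data.frame `site`, `doy`, `hour`, `timestamp` (ISO 8601, a
#'   nominal non-leap year), `temp_c`.
#' @export
simulateTemperature <- function(snowmeltDay, site = "S1", startDay = 100L,
                                endDay = 260L, winterMean = 0,
                                winterSD = 0.15, summerPeak = 12,
                                diurnalAmplitude = 2, noiseSD = 0.8,
                                seed = 1L) {
  stopifnot(startDay < snowmeltDay, snowmeltDay <= endDay)
  .withSeed(seed, {
    doy <- rep(startDay:endDay, each = 12L)
    hour <- rep(seq(0, 22, by = 2), times = endDay - startDay + 1L)
    melted <- doy >= snowmeltDay
    seasonal <- 4 + (summerPeak - 4) *
      sin(pi * pmin((doy - snowmeltDay + 15) / 170, 1))
    base <- ifelse(melted, seasonal, winterMean)
    diurnal <- ifelse(melted,
                      diurnalAmplitude * sin(2 * pi * (hour - 8) / 24), 0)
    noise <- stats::rnorm(length(doy), 0, ifelse(melted, noiseSD, winterSD))
    ts0 <- as.POSIXct(sprintf("2011-01-01 %02d:00:00", hour), tz = "UTC") +
      (doy - 1) * 86400
    data.frame(site = site, doy = doy, hour = hour,
               timestamp = format(ts0, "%Y-%m-%dT%H:%M:%S"),
               temp_c = base + diurnal + noise,
               stringsAsFactors = FALSE)
  })
}

#' Simulate data for the performance-regression design
#'
#' Patches in a 12-site layout receive four standardized traits (i.i.d.
#' standard normal) and a Gaussian response built from declared
#' common slopes, habitat-specific slopes, transect and site random
#' intercepts, and residual noise — the forward model of
#' [fitPerformanceModel()].
#'
#' @param n number of patches.
#' @param slopes length-4 numeric, slopes common to both microhabitats.
#' @param habitatSlopes length-4 numeric, added in snowbed and subtracted
#'   in ridge (so a value `s` means slopes differ by `2 s` between
#'   habitats).
#' @param transectSD,siteSD random-intercept sds.
#' @param residSD residual sd.
#' @param seed integer seed.
#' @return list: `data` (data.frame with response `performance`, traits
#'   `t1..t4`, factors) and `truth` (slopes per habitat, seed).
#' @export
simulatePerformanceData <- function(n = 800L,
                                    slopes = c(0.15, 0.1, 0.1, 0),
                                    habitatSlopes = c(0, 0, 0, 0.2),
                                    transectSD = 0.1, siteSD = 0.2,
                                    residSD = 0.5, seed = 1L) {
  .withSeed(seed, {
    layout <- .siteLayout()
    fac <- layout[sample(rep_len(seq_len(nrow(layout)), n)), ]
    rownames(fac) <- NULL
    Tm <- matrix(stats::rnorm(n * 4), n, 4,
                 dimnames = list(NULL, paste0("t", 1:4)))
    trEff <- stats::setNames(stats::rnorm(3, 0, transectSD), c("T1", "T2", "T3"))
    siteEff <- stats::setNames(stats::rnorm(nrow(layout), 0, siteSD), layout$site)
    sgn <- ifelse(fac$microhabitat == "snowbed", 1, -1)
    y <- as.numeric(Tm %*% slopes) + as.numeric((Tm * sgn) %*% habitatSlopes) +
      trEff[fac$transect] + siteEff[fac$site] + stats::rnorm(n, 0, residSD)
    dat <- cbind(data.frame(performance = y), as.data.frame(Tm), fac)
    slopeRidge <- slopes - habitatSlopes
    slopeSnowbed <- slopes + habitatSlopes
    list(data = dat,
         truth = list(slopeRidge = slopeRidge, slopeSnowbed = slopeSnowbed,
                      transectEffects = trEff, siteEffects = siteEff,
                      seed = as.integer(seed)))
  })
}
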