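#' @include AllClasses.R genotype-io.R clonal-id.R
NULL

## Precompute, per locus, integer allele codes for each individual and the
## frequency vector aligned to those codes. Errors if a called allele is
## absent from the frequency table (frequencies must come from the same,
## clone-filtered, sample or from the generating truth).
.relPrep <- function(g, f) {
  stopifnot(is(g, "GenotypeTable"), is(f, "AlleleFrequencyTable"))
  if (!all(g@loci %in% names(f@freq)))
    stop("frequency table lacks loci: ",
         paste(setdiff(g@loci, names(f@freq)), collapse = ", "), call. = FALSE)
  lapply(seq_along(g@loci), function(j) {
    p <- f@freq[[g@loci[j]]]
    sizes <- as.integer(names(p))
    c1 <- match(g@alleles[, j, 1], sizes)
    c2 <- match(g@alleles[, j, 2], sizes)
    bad <- !is.na(g@alleles[, j, 1]) & is.na(c1)
    if (any(bad))
      stop(sprintf("locus %s: allele(s) absent from frequency table",
                   g@loci[j]), call. = FALSE)
    list(p = as.numeric(p), c1 = c1, c2 = c2)
  })
}

## Core pair-wise engine: r for estimator `est` over pair index vectors.
## Returns numeric vector with attr nSkipped (locus-direction skips from
## zero denominators).
.relPairs <- function(prep, est, I, J, equalWeights = FALSE) {
  np <- length(I)
  nSkipped <- 0L
  if (est == "qg" || est == "lr") {
    numx <- numeric(np); denx <- numeric(np)
    numy <- numeric(np); deny <- numeric(np)
    cntx <- integer(np); cnty <- integer(np)
  } else {
    if (est == "li") {
      num <- numeric(np); den <- numeric(np); cnt <- integer(np)
    } else { # wang
      A11 <- A12 <- A21 <- A22 <- A31 <- A32 <- numeric(np)
      R1 <- R2 <- R3 <- numeric(np)
    }
  }
  for (lp in prep) {
    p <- lp$p
    xa <- lp$c1[I]; xb <- lp$c2[I]; ya <- lp$c1[J]; yb <- lp$c2[J]
    use <- which(!is.na(xa) & !is.na(ya))
    if (!length(use)) next
    xa <- xa[use]; xb <- xb[use]; ya <- ya[use]; yb <- yb[use]
    d11 <- as.numeric(xa == ya); d12 <- as.numeric(xa == yb)
    d21 <- as.numeric(xb == ya); d22 <- as.numeric(xb == yb)
    if (est == "qg") {
      pxa <- p[xa]; pxb <- p[xb]; pya <- p[ya]; pyb <- p[yb]
      sxy <- 0.5 * (d11 + d12 + d21 + d22)
      dl <- 1 + (xa == xb) - pxa - pxb
      nl <- sxy - pxa - pxb
      okx <- abs(dl) > 1e-12
      nSkipped <- nSkipped + sum(!okx)
      ii <- use[okx]
      if (equalWeights) {
        numx[ii] <- numx[ii] + nl[okx] / dl[okx]; cntx[ii] <- cntx[ii] + 1L
      } else {
        numx[ii] <- numx[ii] + nl[okx]; denx[ii] <- denx[ii] + dl[okx]
        cntx[ii] <- cntx[ii] + 1L
      }
      dly <- 1 + (ya == yb) - pya - pyb
      nly <- sxy - pya - pyb
      oky <- abs(dly) > 1e-12
      nSkipped <- nSkipped + sum(!oky)
      ii <- use[oky]
      if (equalWeights) {
        numy[ii] <- numy[ii] + nly[oky] / dly[oky]; cnty[ii] <- cnty[ii] + 1L
      } else {
        numy[ii] <- numy[ii] + nly[oky]; deny[ii] <- deny[ii] + dly[oky]
        cnty[ii] <- cnty[ii] + 1L
      }
    } else if (est == "lr") {
      pxa <- p[xa]; pxb <- p[xb]; pya <- p[ya]; pyb <- p[yb]
      nlx <- pxa * (d21 + d22) + pxb * (d11 + d12) - 4 * pxa * pxb
      dlx <- (1 + (xa == xb)) * (pxa + pxb) - 4 * pxa * pxb
      nly <- pya * (d12 + d22) + pyb * (d11 + d21) - 4 * pya * pyb
      dly <- (1 + (ya == yb)) * (pya + pyb) - 4 * pya * pyb
      okx <- abs(dlx) > 1e-12; oky <- abs(dly) > 1e-12
      nSkipped <- nSkipped + sum(!okx) + sum(!oky)
      ii <- use[okx]
      if (equalWeights) {
        numx[ii] <- numx[ii] + nlx[okx] / dlx[okx]; cntx[ii] <- cntx[ii] + 1L
      } else {
        ## Lynch-Ritland locus weights W = den / (2 pa pb)
        wx <- 2 * pxa[okx] * pxb[okx]
        numx[ii] <- numx[ii] + nlx[okx] / wx
        denx[ii] <- denx[ii] + dlx[okx] / wx
        cntx[ii] <- cntx[ii] + 1L
      }
      ii <- use[oky]
      if (equalWeights) {
        numy[ii] <- numy[ii] + nly[oky] / dly[oky]; cnty[ii] <- cnty[ii] + 1L
      } else {
        wy <- 2 * pya[oky] * pyb[oky]
        numy[ii] <- numy[ii] + nly[oky] / wy
        deny[ii] <- deny[ii] + dly[oky] / wy
        cnty[ii] <- cnty[ii] + 1L
      }
    } else {
      ## genotype-similarity categories shared by Li and Wang
      ident <- d11 * d22      # calls are sorted, so identical iff a1==c1 & a2==c2
      inB1 <- (xa == ya) | (xa == yb)
      inB2 <- ((xb == ya) | (xb == yb)) & (xb != xa)
      m <- as.numeric(inB1) + as.numeric(inB2)
      hetX <- xa != xb; hetY <- ya != yb
      threeAl <- m == 1 & (hetX + hetY == 1)   # hom vs het sharing the hom allele
      hetShare <- m == 1 & hetX & hetY
      a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
      if (est == "li") {
        S <- ifelse(ident == 1, 1, ifelse(threeAl, 0.75,
                                          ifelse(hetShare, 0.5, 0)))
        S0 <- 2 * a2 - a3
        if (1 - S0 > 1e-12) {
          if (equalWeights) {
            num[use] <- num[use] + (S - S0) / (1 - S0); cnt[use] <- cnt[use] + 1L
          } else {
            num[use] <- num[use] + (S - S0)
            den[use] <- den[use] + (1 - S0)
            cnt[use] <- cnt[use] + 1L
          }
        } else nSkipped <- nSkipped + length(use)
      } else { # wang: method-of-moments on category probabilities
        P1 <- ident
        P2 <- as.numeric(threeAl)
        P3 <- as.numeric(hetShare)
        b <- 2 * a2^2 - a4
        cc <- a2 - 2 * a2^2 + a4
        dd <- 4 * (a3 - a4)
        ee <- 2 * (a2 - 3 * a3 + 2 * a4)
        ffc <- 4 * (a2 - a2^2 - 2 * a3 + 2 * a4)
        gg <- 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4
        u <- 2 * a2 - a3
        w <- if (equalWeights) 1 else 1 / u
        A11[use] <- A11[use] + w * (1 - b);  A12[use] <- A12[use] + w * cc
        A21[use] <- A21[use] - w * dd;       A22[use] <- A22[use] + w * ee
        A31[use] <- A31[use] - w * ffc;      A32[use] <- A32[use] + w * gg
        R1[use] <- R1[use] + w * (P1 - b)
        R2[use] <- R2[use] + w * (P2 - dd)
        R3[use] <- R3[use] + w * (P3 - ffc)
      }
    }
  }
  r <- if (est %in% c("qg", "lr")) {
    if (equalWeights) { rx <- numx / cntx; ry <- numy / cnty }
    else { rx <- numx / denx; ry <- numy / deny }
    rx[cntx == 0] <- NA_real_; ry[cnty == 0] <- NA_real_
    out <- rowMeans(cbind(rx, ry), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  } else if (est == "li") {
    out <- if (equalWeights) num / cnt else num / den
    out[cnt == 0] <- NA_real_
    out[is.nan(out)] <- NA_real_
    out
  } else {
    N11 <- A11^2 + A21^2 + A31^2
    N12 <- A11 * A12 + A21 * A22 + A31 * A32
    N22 <- A12^2 + A22^2 + A32^2
    B1 <- A11 * R1 + A21 * R2 + A31 * R3
    B2 <- A12 * R1 + A22 * R2 + A32 * R3
    det <- N11 * N22 - N12^2
    Delta <- (N22 * B1 - N12 * B2) / det
    phi <- (N11 * B2 - N12 * B1) / det
    out <- Delta + phi / 2
    out[!is.finite(out) | abs(det) < 1e-12] <- NA_real_
    out
  }
  attr(r, "nSkipped") <- nSkipped
  r
}

#' Pairwise relatedness under a published moment estimator
#'
#' Computes the full symmetric matrix of pairwise relatedness coefficients
#' for one of four estimators: Queller-Goodnight (`"qg"`), Li (`"li"`),
#' Lynch-Ritland (`"lr"`) and Wang (`"wang"`). Loci are combined with each
#' estimator's published multilocus weighting (QG and Li: ratio of summed
#' numerators and denominators; LR: inverse-variance locus weights; Wang:
#' 1/(2a2 - a3) locus weights on the category-probability moment
#' equations); `equalLocusWeights = TRUE` switches all of them to a simple
#' average of per-locus values. The asymmetric estimators (QG, LR) are
#' symmetrized as the average over the two reference-individual directions.
#' Loci missing in either member of a pair are skipped; zero-denominator
#' locus-directions (e.g. a reference individual homozygous for a
#' frequency-1 allele) are skipped and counted.
#'
#' @param g a clone-filtered [GenotypeTable-class].
#' @param estimator `"qg"`, `"li"`, `"lr"` or `"wang"`.
#' @param f an [AlleleFrequencyTable-class]; defaults to frequencies of `g`
#'   itself (no reference panel).
#' @param equalLocusWeights logical, use unweighted per-locus averages.
#' @return A [RelatednessMatrix-class] with unit diagonal. Pairs with no
#'   usable locus are `NA` and counted in the `nMissingPairs` slot.
#' @seealso [pairRelatedness()] for selected pairs only,
#'   [nearPositiveDefinite()] for mixed-model conditioning.
#' @export
pairwiseRelatedness <- function(g, estimator = c("lr", "qg", "li", "wang"),
                                f = NULL, equalLocusWeights = FALSE) {
  estimator <- match.arg(estimator)
  if (is.null(f)) f <- alleleFrequencies(g)
  prep <- .relPrep(g, f)
  n <- length(g@ids)
  pr <- .pairIndices(n)
  r <- .relPairs(prep, estimator, pr[, 1], pr[, 2], equalLocusWeights)
  if (attr(r, "nSkipped") > 0)
    message(sprintf("pairwiseRelatedness: skipped %d zero-denominator locus evaluations",
                    attr(r, "nSkipped")))
  m <- matrix(1, n, n, dimnames = list(g@ids, g@ids))
  m[pr] <- r; m[pr[, 2:1, drop = FALSE]] <- r
  nMiss <- sum(is.na(r))
  if (nMiss > 0)
    message(sprintf("pairwiseRelatedness: %d pairs with no usable locus (NA)",
                    nMiss))
  new("RelatednessMatrix", values = m, estimator = estimator,
      psd = FALSE, nMissingPairs = as.integer(nMiss))
}

#' Relatedness for selected pairs
#'
#' Same estimators as [pairwiseRelatedness()] but evaluated only for the
#' requested pairs (useful for Monte-Carlo calibration on simulated dyads).
#'
#' @param g a [GenotypeTable-class].
#' @param pairs two-column matrix of individual ids or integer indices.
#' @inheritParams pairwiseRelatedness
#' @return Numeric vector, one coefficient per row of `pairs`.
#' @export
pairRelatedness <- function(g, pairs, estimator = c("lr", "qg", "li", "wang"),
                            f = NULL, equalLocusWeights = FALSE) {
  estimator <- match.arg(estimator)
  if (is.null(f)) f <- alleleFrequencies(g)
  pairs <- as.matrix(pairs)
  if (is.character(pairs))
    pairs <- cbind(match(pairs[, 1], g@ids), match(pairs[, 2], g@ids))
  if (anyNA(pairs)) stop("unknown ids in pairs", call. = FALSE)
  prep <- .relPrep(g, f)
  r <- .relPairs(prep, estimator, pairs[, 1], pairs[, 2], equalLocusWeights)
  attributes(r) <- NULL
  r
}

#' Set the diagonal of a relatedness matrix to one
#'
#' A genotype's relatedness with itself is 1 by definition; off-diagonal
#' entries are untouched.
#'
#' @param m a [RelatednessMatrix-class] (or base matrix).
#' @return Same class as the input, diagonal exactly 1.
#' @export
setDiagonalUnity <- function(m) {
  if (is(m, "RelatednessMatrix")) {
    diag(m@values) <- 1
    m
  } else {
    diag(m) <- 1
    m
  }
}

#' Nearest positive-(semi)definite relatedness matrix
#'
#' Higham alternating-projections nearest correlation-structured matrix
#' (unit diagonal restored at every iteration), via [Matrix::nearPD()].
#' Pairs that had no usable locus (`NA`) are filled with 0 — the
#' expectation of every estimator for a random pair — before projection,
#' and their count is reported. A matrix that is already positive
#' semi-definite (all eigenvalues at least `eps`) with unit diagonal is
#' returned unchanged, which also makes the operation idempotent.
#'
#' @param m a [RelatednessMatrix-class] or symmetric base matrix.
#' @param eps smallest admissible eigenvalue (default 1e-8).
#' @param maxit maximum Higham iterations (default 300); non-convergence is
#'   an error reporting the iteration count.
#' @return A [RelatednessMatrix-class] with `psd = TRUE`.
#' @export
nearPositiveDefinite <- function(m, eps = 1e-8, maxit = 300L) {
  isS4in <- is(m, "RelatednessMatrix")
  v <- if (isS4in) m@values else as.matrix(m)
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    stop("input must be symmetric", call. = FALSE)
  v <- (v + t(v)) / 2
  nNA <- sum(is.na(v[upper.tri(v)]))
  if (nNA > 0) {
    message(sprintf("nearPositiveDefinite: filling %d unusable pairs with 0", nNA))
    v[is.na(v)] <- 0
  }
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (all(abs(diag(v) - 1) < 1e-12) && min(ev) >= eps) {
    out <- v
  } else {
    res <- Matrix::nearPD(v, corr = TRUE, do2eigen = TRUE,
                          eig.tol = 1e-6, conv.tol = 1e-7, maxit = maxit)
    if (!res$converged)
      stop(sprintf("nearPD did not converge within %d iterations", res$iterations),
           call. = FALSE)
    out <- as.matrix(res$mat)
    dimnames(out) <- dimnames(v)
    out <- (out + t(out)) / 2
    e2 <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    if (min(e2) < -1e-8)
      stop("projection failed to reach positive semi-definiteness", call. = FALSE)
  }
  if (isS4in)
    new("RelatednessMatrix", values = out, estimator = m@estimator,
        psd = TRUE, nMissingPairs = m@nMissingPairs)
  else
    new("RelatednessMatrix", values = out, estimator = "lr",
        psd = TRUE, nMissingPairs = as.integer(nNA))
}
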