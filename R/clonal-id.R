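#' @include AllClasses.R genotype-io.R
NULL

## Per-locus band-sharing similarity between two diploid calls, on distinct
## allele sets: s = 2|A n B| / (|A| + |B|). Vectorized over pairs.
.bandSharing <- function(xa, xb, ya, yb) {
  inB1 <- (xa == ya) | (xa == yb)
  inB2 <- ((xb == ya) | (xb == yb)) & (xb != xa)
  m <- as.numeric(inB1) + as.numeric(inB2)
  sizeX <- 1 + (xa != xb); sizeY <- 1 + (ya != yb)
  2 * m / (sizeX + sizeY)
}

#' Lynch band-sharing distance between all pairs of genotypes
#'
#' For each pair, the per-locus similarity is
#' `s = 2 |A n B| / (|A| + |B|)` on the sets of distinct alleles (a
#' heterozygote contributes two alleles, a homozygote one), and the distance
#' is `1 - mean(s)` over the loci typed in both individuals. Identical
#' multilocus genotypes score 0; fully disjoint ones score 1.
#'
#' @param g a [GenotypeTable-class].
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal and the
#'   individual ids as dimnames. Pairs with no shared typed locus get `NA`
#'   (they cannot be merged as clones); their count is in
#'   `attr(, "nUnusablePairs")`.
#' @export
lynchDistance <- function(g) {
  stopifnot(is(g, "GenotypeTable"))
  n <- length(g@ids)
  pr <- .pairIndices(n)
  sSum <- numeric(nrow(pr)); sCnt <- numeric(nrow(pr))
  for (l in seq_along(g@loci)) {
    a1 <- g@alleles[, l, 1]; a2 <- g@alleles[, l, 2]
    xa <- a1[pr[, 1]]; xb <- a2[pr[, 1]]
    ya <- a1[pr[, 2]]; yb <- a2[pr[, 2]]
    use <- !is.na(xa) & !is.na(ya)
    s <- .bandSharing(xa[use], xb[use], ya[use], yb[use])
    sSum[use] <- sSum[use] + s
    sCnt[use] <- sCnt[use] + 1
  }
  d <- 1 - sSum / sCnt          # NaN where no shared locus
  d[sCnt == 0] <- NA_real_
  m <- matrix(0, n, n, dimnames = list(g@ids, g@ids))
  m[pr] <- d; m[pr[, 2:1, drop = FALSE]] <- d
  attr(m, "nUnusablePairs") <- sum(sCnt == 0)
  m
}

## union-find with path compression
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

#' Group clonal replicates and pick representatives
#'
#' Single-linkage grouping of all pairs with distance strictly below the
#' threshold (transitive closure: if a~b and b~c, then {a,b,c} form one
#' genet even when d(a,c) is large). One representative patch per genet is
#' drawn uniformly at random with the given seed, using a dedicated random
#' stream that does not disturb the session RNG.
#'
#' @param d symmetric distance matrix from [lynchDistance()] (or a
#'   [GenotypeTable-class], in which case the distance is computed first).
#' @param threshold merge pairs with `d < threshold` (default 0.05).
#' @param seed integer seed for representative selection.
#' @return A [CloneAssignment-class].
#' @export
assignClones <- function(d, threshold = 0.05, seed = 1L) {
  if (is(d, "GenotypeTable")) d <- lynchDistance(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  nUnusable <- attr(d, "nUnusablePairs")
  if (is.null(nUnusable)) nUnusable <- sum(is.na(d[upper.tri(d)]))
  pr <- .pairIndices(nrow(d))
  dv <- d[pr]
  edges <- pr[!is.na(dv) & dv < threshold, , drop = FALSE]
  comp <- .unionFind(nrow(d), edges)
  groups <- split(ids, comp)
  names(groups) <- sprintf("genet%04d", seq_along(groups))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  reps <- vapply(groups, function(m) if (length(m) == 1L) m else sample(m, 1L),
                 character(1))
  new("CloneAssignment", ids = ids, groups = groups,
      representatives = reps, threshold = threshold,
      seed = as.integer(seed), nUnusablePairs = as.integer(nUnusable))
}

#' Keep one representative patch per genet
#'
#' @param g a [GenotypeTable-class] of all patches.
#' @param ca a [CloneAssignment-class] on the same ids.
#' @return A [GenotypeTable-class] restricted to the representative patches,
#'   in the order the representatives appear in `g`.
#' @export
filterClones <- function(g, ca) {
  stopifnot(is(g, "GenotypeTable"), is(ca, "CloneAssignment"))
  keep <- g@ids %in% ca@representatives
  GenotypeTable(g@ids[keep], g@loci,
                g@alleles[keep, , , drop = FALSE],
                if (length(g@site)) g@site[keep] else character())
}

#' Multilocus probability of identity
#'
#' Probability that two independent individuals drawn from
#' Hardy-Weinberg proportions share the same multilocus genotype:
#' per locus `PI_l = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`, multiplied
#' across the chosen loci.
#'
#' @param f an [AlleleFrequencyTable-class].
#' @param loci character vector of locus names (default: all loci in `f`).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' \dontrun{probabilityOfIdentity(f, c("locA", "locB"))}
#' @export
probabilityOfIdentity <- function(f, loci = NULL) {
  stopifnot(is(f, "AlleleFrequencyTable"))
  if (is.null(loci)) loci <- names(f@freq)
  if (!length(loci)) stop("empty locus subset", call. = FALSE)
  missing <- setdiff(loci, names(f@freq))
  if (length(missing)) stop("unknown loci: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  pi1 <- vapply(loci, function(l) {
    p <- f@freq[[l]]
    2 * sum(p^2)^2 - sum(p^4)
  }, numeric(1))
  prod(pi1)
}

#' Probability-of-identity profile over marker-panel sizes
#'
#' For each panel size k, PI over all k-locus combinations (min/mean/max),
#' showing how quickly identity-by-chance decays as markers are added.
#'
#' @param f an [AlleleFrequencyTable-class].
#' @return data.frame with columns `nLoci`, `minPI`, `meanPI`, `maxPI`.
#' @export
piProfile <- function(f) {
  loci <- names(f@freq)
  out <- lapply(seq_along(loci), function(k) {
    combos <- utils::combn(loci, k, simplify = FALSE)
    pis <- vapply(combos, function(s) probabilityOfIdentity(f, s), numeric(1))
    data.frame(nLoci = k, minPI = min(pis), meanPI = mean(pis),
               maxPI = max(pis))
  })
  do.call(rbind, out)
}
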