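#' @include AllClasses.R
NULL

## --- GENEPOP parsing helpers -------------------------------------------

.parseGenepopToken <- function(tok, line) {
  nc <- nchar(tok)
  if (nc == 4L) w <- 2L
  else if (nc == 6L) w <- 3L
  else stop(sprintf("line %d: genotype token '%s' is not 4- or 6-digit coded",
                    line, tok), call. = FALSE)
  a <- c(as.integer(substr(tok, 1L, w)), as.integer(substr(tok, w + 1L, 2L * w)))
  if (anyNA(a))
    stop(sprintf("line %d: non-numeric genotype token '%s'", line, tok),
         call. = FALSE)
  if (any(a == 0L)) a <- c(NA_integer_, NA_integer_)  # 0/00/000 = missing
  a
}

#' Read diploid SSR genotypes
#'
#' Reads a GENEPOP text file or a delimited table into a
#' [GenotypeTable-class]. Both common GENEPOP dialects are accepted: locus
#' names on separate lines or on a single comma-separated line, and 2- or
#' 3-digit allele coding (allele code 0 means missing). The delimited table
#' has columns `id`, optionally `site`, then two columns per locus named
#' `<locus>_a1` and `<locus>_a2` (tab- or comma-separated; `NA` or 0 marks
#' a missing allele).
#'
#' @param path path to the input file.
#' @param format `"genepop"` or `"table"`.
#' @return A [GenotypeTable-class]. For GENEPOP input the population blocks
#'   are recorded in the `site` slot as `pop1`, `pop2`, ...
#' @examples
#' f <- tempfile()
#' writeLines(c("toy", "locA", "locB", "pop",
#'              "i1 , 101103 200200", "i2 , 101101 0000"), f)
#' readGenotypes(f, "genepop")
#' @export
readGenotypes <- function(path, format = c("genepop", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genepop") .readGenepop(path) else .readGenotypeTable(path)
}

.readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (sum(keep) < 2L) stop("no individuals in GENEPOP file", call. = FALSE)
  lineNo <- seq_along(lines)[keep]
  lines <- trimws(lines[keep])
  isPop <- tolower(lines) == "pop"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop) || firstPop < 2L)
    stop("no individuals in GENEPOP file (no 'pop' line)", call. = FALSE)
  locusLines <- lines[2:(firstPop - 1L)]
  loci <- if (any(grepl(",", locusLines))) {
    trimws(unlist(strsplit(paste(locusLines, collapse = ","), ",")))
  } else locusLines
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  ids <- character(); site <- character(); calls <- list()
  popIdx <- 0L
  for (k in firstPop:length(lines)) {
    if (isPop[k]) { popIdx <- popIdx + 1L; next }
    ln <- lines[k]
    commaAt <- regexpr(",", ln, fixed = TRUE)
    if (commaAt < 0L)
      stop(sprintf("line %d: malformed GENEPOP row (no comma after id)",
                   lineNo[k]), call. = FALSE)
    id <- trimws(substr(ln, 1L, commaAt - 1L))
    toks <- strsplit(trimws(substr(ln, commaAt + 1L, nchar(ln))), "[[:space:]]+")[[1]]
    if (length(toks) != L)
      stop(sprintf("line %d: expected %d genotype tokens, found %d",
                   lineNo[k], L, length(toks)), call. = FALSE)
    g <- vapply(toks, .parseGenepopToken, integer(2), line = lineNo[k])
    ids <- c(ids, id); site <- c(site, paste0("pop", popIdx))
    calls[[length(calls) + 1L]] <- g
  }
  if (!length(ids)) stop("no individuals in GENEPOP file", call. = FALSE)
  a <- array(NA_integer_, c(length(ids), L, 2L))
  for (i in seq_along(calls)) a[i, , ] <- t(calls[[i]])
  GenotypeTable(ids, loci, a, site)
}

.readGenotypeTable <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("no individuals in table file", call. = FALSE)
  if (!"id" %in% names(df)) stop("table must have an 'id' column", call. = FALSE)
  site <- if ("site" %in% names(df)) as.character(df$site) else character()
  acols <- grep("_a[12]$", names(df), value = TRUE)
  loci <- unique(sub("_a[12]$", "", acols))
  bad <- loci[!(paste0(loci, "_a1") %in% names(df) &
                paste0(loci, "_a2") %in% names(df))]
  if (length(bad))
    stop("locus columns must come in _a1/_a2 pairs; incomplete: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!length(loci)) stop("no locus columns found", call. = FALSE)
  a <- array(NA_integer_, c(nrow(df), length(loci), 2L))
  for (j in seq_along(loci)) {
    a1 <- suppressWarnings(as.integer(df[[paste0(loci[j], "_a1")]]))
    a2 <- suppressWarnings(as.integer(df[[paste0(loci[j], "_a2")]]))
    a1[!is.na(a1) & a1 == 0L] <- NA_integer_
    a2[!is.na(a2) & a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    a[, j, 1] <- a1; a[, j, 2] <- a2
  }
  GenotypeTable(as.character(df$id), loci, a, site)
}

#' Write a GenotypeTable as a GENEPOP file
#'
#' Uses 3-digit allele coding; missing calls are written as `000000`.
#' Individuals sharing a `site` label are written as one population block.
#'
#' @param x a [GenotypeTable-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGenepop <- function(x, path) {
  a <- x@alleles
  if (any(a[!is.na(a)] > 999L))
    stop("allele sizes above 999 cannot be 3-digit GENEPOP coded", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("markerQG export", con)
  writeLines(x@loci, con)
  site <- if (length(x@site)) x@site else rep("pop1", length(x@ids))
  for (s in unique(site)) {
    writeLines("pop", con)
    for (i in which(site == s)) {
      g <- vapply(seq_along(x@loci), function(j) {
        al <- a[i, j, ]
        if (anyNA(al)) "000000" else sprintf("%03d%03d", al[1], al[2])
      }, character(1))
      writeLines(paste(x@ids[i], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a GenotypeTable as a delimited table
#'
#' Columns `id`, `site` (if present) and `<locus>_a1`/`<locus>_a2` pairs,
#' tab-separated; missing alleles as `NA`.
#'
#' @param x a [GenotypeTable-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGenotypeTable <- function(x, path) {
  df <- data.frame(id = x@ids, stringsAsFactors = FALSE)
  if (length(x@site)) df$site <- x@site
  for (j in seq_along(x@loci)) {
    df[[paste0(x@loci[j], "_a1")]] <- x@alleles[, j, 1]
    df[[paste0(x@loci[j], "_a2")]] <- x@alleles[, j, 2]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus allele frequencies
#'
#' Counts each non-missing diploid call as two gene copies; missing calls
#' are excluded locus-wise (never imputed).
#'
#' @param g a [GenotypeTable-class].
#' @return An [AlleleFrequencyTable-class].
#' @examples
#' a <- array(NA_integer_, c(2, 1, 2))
#' a[1, 1, ] <- c(101L, 101L); a[2, 1, ] <- c(101L, 103L)
#' alleleFrequencies(GenotypeTable(c("x", "y"), "locA", a))
#' @export
alleleFrequencies <- function(g) {
  stopifnot(is(g, "GenotypeTable"))
  fr <- list(); ng <- integer()
  for (j in seq_along(g@loci)) {
    al <- c(g@alleles[, j, 1], g@alleles[, j, 2])
    al <- al[!is.na(al)]
    if (!length(al))
      stop("locus entirely missing: ", g@loci[j], call. = FALSE)
    tab <- table(al)
    fr[[g@loci[j]]] <- as.numeric(tab) / length(al)
    names(fr[[g@loci[j]]]) <- names(tab)
    ng <- c(ng, length(al))
  }
  names(ng) <- g@loci
  new("AlleleFrequencyTable", freq = fr, nGenes = ng)
}

#' Per-locus summary statistics
#'
#' Observed heterozygosity Ho, expected (Nei) heterozygosity
#' He = 1 - sum(p^2), and the effective number of alleles
#' Ae = 1 / sum(p^2), computed from non-missing calls.
#'
#' @param g a [GenotypeTable-class].
#' @return data.frame with one row per locus: `locus`, `nTyped`, `nAlleles`,
#'   `Ho`, `He`, `Ae`.
#' @export
locusSummary <- function(g) {
  f <- alleleFrequencies(g)
  out <- lapply(seq_along(g@loci), function(j) {
    a1 <- g@alleles[, j, 1]; a2 <- g@alleles[, j, 2]
    typed <- !is.na(a1)
    p <- f@freq[[j]]
    s2 <- sum(p^2)
    data.frame(locus = g@loci[j], nTyped = sum(typed),
               nAlleles = length(p),
               Ho = mean(a1[typed] != a2[typed]),
               He = 1 - s2, Ae = 1 / s2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## shared helper: unordered pair indices for n items (column-major i < j)
.pairIndices <- function(n) {
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  j <- rep.int(2:n, 1:(n - 1L))
  i <- sequence(1:(n - 1L))
  cbind(i = i, j = j)
}
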