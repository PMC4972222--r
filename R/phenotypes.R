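#' @include AllClasses.R
NULL

## Daily means from a 2-h soil-temperature series for one site/logger.
## Accepts columns (doy, temp_c) or (timestamp, temp_c) with ISO 8601
## timestamps. Returns data.frame(doy, meanT, nReadings).
.dailyMeans <- function(series) {
  if (!"doy" %in% names(series)) {
    if (!"timestamp" %in% names(series))
      stop("temperature series needs a 'doy' or 'timestamp' column",
           call. = FALSE)
    lt <- as.POSIXlt(series$timestamp, tz = "UTC")
    series$doy <- lt$yday + 1L
  }
  if (!"temp_c" %in% names(series))
    stop("temperature series needs a 'temp_c' column", call. = FALSE)
  agg <- stats::aggregate(series$temp_c, list(doy = series$doy),
                          function(x) c(mean(x), length(x)))
  data.frame(doy = agg$doy, meanT = agg$x[, 1], nReadings = agg$x[, 2])
}

#' Detect the day of snowmelt from a soil-temperature series
#'
#' Under snow cover, soil temperature at 5 cm depth sits near 0 degC with
#' almost no variation (the insulation signature); at melt-out it rises
#' sharply. The detector finds the first day whose daily mean exceeds
#' `riseThreshold` after at least `minFlatDays` consecutive days whose
#' daily means stay within `+/- flatBand` of 0 degC.
#'
#' @param series data.frame with `temp_c` and either `doy` (1-based
#'   day-of-year) or ISO 8601 `timestamp`; 2-h sampling assumed but not
#'   required. An optional `logger` column triggers per-logger detection
#'   with the site value taken as the median over loggers.
#' @param flatBand half-width of the near-zero band in degC (default 0.5).
#' @param minFlatDays minimum consecutive flat days (default 5).
#' @param riseThreshold daily-mean threshold marking melt-out (default 1.5).
#' @return Integer day-of-year.
#' @export
detectSnowmeltDay <- function(series, flatBand = 0.5, minFlatDays = 5L,
                              riseThreshold = 1.5) {
  if ("logger" %in% names(series) && length(unique(series$logger)) > 1L) {
    days <- vapply(split(series, series$logger), detectSnowmeltDay,
                   numeric(1), flatBand = flatBand,
                   minFlatDays = minFlatDays, riseThreshold = riseThreshold)
    return(as.integer(round(stats::median(days))))
  }
  dm <- .dailyMeans(series)
  dm <- dm[order(dm$doy), ]
  flat <- abs(dm$meanT) <= flatBand
  run <- integer(nrow(dm)); rl <- 0L
  for (i in seq_len(nrow(dm))) {
    rl <- if (flat[i]) rl + 1L else 0L
    run[i] <- rl
  }
  qual <- which(run >= minFlatDays)
  if (!length(qual))
    stop("no snow-cover signature (no ", minFlatDays,
         "-day near-zero flat period)", call. = FALSE)
  after <- which(dm$meanT > riseThreshold & seq_len(nrow(dm)) > qual[1])
  if (!length(after))
    stop("no melt-out rise above ", riseThreshold,
         " degC after the snow-cover period", call. = FALSE)
  as.integer(dm$doy[after[1]])
}

#' Growing-degree days above a base temperature
#'
#' Accumulates `max(0, dailyMean - base)` over the inclusive day window
#' `[startDay, endDay]`. Daily means are taken over the (nominally twelve)
#' 2-h readings; a day missing more than `maxMissingFrac` of its readings
#' is excluded and reported in `attr(, "excludedDays")`. With
#' `subDaily = TRUE` the truncation is applied per reading instead
#' (each reading contributing `1/readingsPerDay` of a day).
#'
#' @param series temperature series as in [detectSnowmeltDay()].
#' @param startDay,endDay inclusive day-of-year window (`startDay <= endDay`).
#' @param base base temperature in degC (default 5).
#' @param subDaily accumulate at the reading level (default FALSE).
#' @param maxMissingFrac maximum tolerated fraction of missing readings per
#'   day (default 0.25).
#' @return Numeric degree-days (degC * day).
#' @examples
#' s <- data.frame(doy = rep(1:5, each = 12), temp_c = 10)
#' gdd(s, 1, 5)  # (10 - 5) * 5 = 25
#' @export
gdd <- function(series, startDay, endDay, base = 5, subDaily = FALSE,
                maxMissingFrac = 0.25) {
  if (startDay > endDay) stop("startDay must be <= endDay", call. = FALSE)
  dm <- .dailyMeans(series)
  dm <- dm[dm$doy >= startDay & dm$doy <= endDay, ]
  if (!nrow(dm)) stop("series does not cover the window", call. = FALSE)
  expected <- max(dm$nReadings)
  ok <- dm$nReadings >= (1 - maxMissingFrac) * expected
  excluded <- dm$doy[!ok]
  if (length(excluded))
    message("gdd: excluding ", length(excluded),
            " day(s) with >25% missing readings")
  out <- if (subDaily) {
    sel <- series
    if (!"doy" %in% names(sel)) {
      lt <- as.POSIXlt(sel$timestamp, tz = "UTC"); sel$doy <- lt$yday + 1L
    }
    sel <- sel[sel$doy >= startDay & sel$doy <= endDay &
               sel$doy %in% dm$doy[ok], ]
    sum(pmax(sel$temp_c - base, 0)) / expected
  } else {
    sum(pmax(dm$meanT[ok] - base, 0))
  }
  attr(out, "excludedDays") <- excluded
  out
}

#' Elliptical leaf area
#'
#' `pi * (length/2) * (width/2)`, the ellipse approximation for leaf
#' blades.
#'
#' @param length,width leaf dimensions in mm (vectors allowed; `NA`
#'   propagates).
#' @return Area in mm^2.
#' @examples
#' leafArea(4, 2)  # 2 * pi
#' @export
leafArea <- function(length, width) {
  if (any(length < 0, na.rm = TRUE) || any(width < 0, na.rm = TRUE))
    stop("leaf dimensions must be non-negative", call. = FALSE)
  pi * (length / 2) * (width / 2)
}

#' Standardize to z-scores
#'
#' `(x - mean) / sd` over the non-missing entries, with the `n - 1` sd
#' denominator; missing values stay missing.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return z-scored vector.
#' @export
standardizeTraits <- function(x) {
  v <- x[!is.na(x)]
  if (length(unique(v)) < 2L)
    stop("cannot standardize a constant vector", call. = FALSE)
  (x - mean(v)) / stats::sd(v)
}

#' Derive analysis traits from phenology records and temperature series
#'
#' Builds the six analysis traits per patch: elliptical `leaf_size` (mm^2),
#' `snowmelt_to_leaf_expansion` (days), `gdd_to_leaf_expansion` and
#' `gdd_to_flowering` (degree-days above `gddBase` accumulated from the
#' site's snowmelt day, inclusive, to the phenophase day),
#' `change_in_stem_number` (stems 2012 / stems 2011) and
#' `proportion_flowering_stems` (flowering stems / stems 2012). A patch
#' missing any component gets `NA` for that trait only. Phenophase days
#' earlier than the site's snowmelt day are flagged
#' (`flag_negative_interval`) and the interval/GDD traits set missing
#' rather than silently used. Zero stems in 2011 (ratio undefined) or 2012
#' (proportion undefined) likewise give `NA`.
#'
#' @param records data.frame with columns `patch`, `site`, `microhabitat`,
#'   `elevation`, `transect`, `leaf_expansion_day`, `flowering_day`,
#'   `stems_2011`, `stems_2012`, `flowering_stems_2012`, `leaf_length`,
#'   `leaf_width`.
#' @param temperature data.frame with `site`, `temp_c` and `doy`/`timestamp`
#'   (and optionally `logger`); required unless `snowmeltDays` is given.
#' @param snowmeltDays optional named vector of snowmelt day-of-year per
#'   site, overriding detection from `temperature`.
#' @param gddBase base temperature for GDD (default 5 degC).
#' @param standardize add z-scored copies (`z_` prefix) of the six traits.
#' @param ... further arguments passed to [detectSnowmeltDay()].
#' @return data.frame: factors, `snowmelt_day`, the six traits, flags.
#' @export
deriveTraits <- function(records, temperature = NULL, snowmeltDays = NULL,
                         gddBase = 5, standardize = FALSE, ...) {
  needed <- c("patch", "site", "leaf_expansion_day", "flowering_day",
              "stems_2011", "stems_2012", "flowering_stems_2012",
              "leaf_length", "leaf_width")
  missingCols <- setdiff(needed, names(records))
  if (length(missingCols))
    stop("records lacking column(s): ", paste(missingCols, collapse = ", "),
         call. = FALSE)
  sites <- unique(as.character(records$site))
  bySite <- if (!is.null(temperature))
    split(temperature, as.character(temperature$site)) else NULL
  if (is.null(snowmeltDays)) {
    if (is.null(bySite))
      stop("either temperature or snowmeltDays must be supplied", call. = FALSE)
    snowmeltDays <- vapply(sites, function(s) {
      if (is.null(bySite[[s]])) stop("no temperature series for site ", s,
                                     call. = FALSE)
      as.numeric(detectSnowmeltDay(bySite[[s]], ...))
    }, numeric(1))
  }
  ## cumulative degree-days per site for fast windowed GDD
  gddTo <- function(s, fromDay, toDay) {
    if (is.na(toDay)) return(NA_real_)
    if (is.null(bySite) || is.null(bySite[[s]])) return(NA_real_)
    as.numeric(gdd(bySite[[s]], fromDay, toDay, base = gddBase))
  }
  out <- data.frame(patch = records$patch, site = records$site,
                    stringsAsFactors = FALSE)
  for (v in c("microhabitat", "elevation", "transect"))
    if (v %in% names(records)) out[[v]] <- records[[v]]
  smd <- snowmeltDays[as.character(records$site)]
  out$snowmelt_day <- as.numeric(smd)
  out$leaf_size <- leafArea(records$leaf_length, records$leaf_width)
  interval <- records$leaf_expansion_day - out$snowmelt_day
  out$flag_negative_interval <- !is.na(interval) & interval < 0
  interval[out$flag_negative_interval] <- NA_real_
  out$snowmelt_to_leaf_expansion <- interval
  out$gdd_to_leaf_expansion <- vapply(seq_len(nrow(records)), function(i) {
    if (is.na(interval[i])) return(NA_real_)
    gddTo(as.character(records$site[i]), out$snowmelt_day[i],
          records$leaf_expansion_day[i])
  }, numeric(1))
  flday <- records$flowering_day
  flbad <- !is.na(flday) & flday < out$snowmelt_day
  out$flag_negative_interval <- out$flag_negative_interval | flbad
  flday[flbad] <- NA_real_
  out$gdd_to_flowering <- vapply(seq_len(nrow(records)), function(i) {
    if (is.na(flday[i])) return(NA_real_)
    gddTo(as.character(records$site[i]), out$snowmelt_day[i], flday[i])
  }, numeric(1))
  ratio <- records$stems_2012 / records$stems_2011
  ratio[!is.na(records$stems_2011) & records$stems_2011 == 0] <- NA_real_
  out$change_in_stem_number <- ratio
  prop <- records$flowering_stems_2012 / records$stems_2012
  prop[!is.na(records$stems_2012) & records$stems_2012 == 0] <- NA_real_
  out$proportion_flowering_stems <- prop
  if (standardize) {
    for (tr in c("leaf_size", "snowmelt_to_leaf_expansion",
                 "gdd_to_leaf_expansion", "gdd_to_flowering",
                 "change_in_stem_number", "proportion_flowering_stems"))
      out[[paste0("z_", tr)]] <- standardizeTraits(out[[tr]])
  }
  out
}
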