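#' Shannon diversity index of daily rainfall
#'
#' Normalized entropy of the daily rainfall shares over a window of n days:
#' \deqn{SDI = -\sum_i P_i \ln(P_i) / \ln(n), \quad P_i = Rd_i / \sum Rd}
#' Days with zero rain contribute 0 to the sum. SDI = 1 means perfectly even
#' rainfall across all days; SDI = 0 means all rain fell on a single day.
#'
#' @param rain_mm Numeric vector of daily rainfall, mm, non-negative.
#' @return SDI in \[0, 1\]; `NA` if total rainfall is zero (undefined).
#' @export
shannon_diversity <- function(rain_mm) {
  stopifnot(is.numeric(rain_mm))
  if (any(rain_mm < 0, na.rm = TRUE)) stop("rainfall must be non-negative")
  n <- length(rain_mm)
  if (n < 2) stop("need at least 2 days")
  total <- sum(rain_mm)
  if (total == 0) return(NA_real_)
  p <- rain_mm / total
  p <- p[p > 0]
  # + 0 normalizes the signed zero of the single-day case
  -sum(p * log(p)) / log(n) + 0
}

#' Growing degree-days above a 5 degree C base
#'
#' Sum of daily mean temperatures on days whose mean is at or above the base
#' temperature (the temperature itself is accumulated, not the excess over
#' the base).
#'
#' @param tmean_c Numeric vector of daily mean temperatures, degrees C.
#' @param base Base temperature, degrees C (default 5).
#' @return Degree-days (>= 0).
#' @export
growing_degree_days <- function(tmean_c, base = 5) {
  stopifnot(is.numeric(tmean_c))
  sum(tmean_c[!is.na(tmean_c) & tmean_c >= base])
}

season_indices <- function(rain, tmean) {
  list(PPT = sum(rain),
       SDI = shannon_diversity(rain),
       T = mean(tmean),
       GDD = growing_degree_days(tmean))
}

#' Weather indices over the growing window, averaged across past seasons
#'
#' For each of the `n_seasons` seasons preceding the study year, restricts the
#' daily series to the planting-to-harvest calendar window (both ends
#' included, shifted back by 1..n_seasons years) and computes the cumulative
#' precipitation PPT, the Shannon rainfall diversity index SDI, the mean
#' temperature T and the growing degree-days GDD; the reported index is the
#' arithmetic mean across seasons. A season with zero total rainfall has an
#' undefined SDI and is skipped for that index with a warning.
#'
#' @param series Data frame with columns `date` (Date or ISO-8601 character),
#'   `rain_mm` and `tmean_c`, for one site.
#' @param window Length-2 vector (planting date, harvest date) of the study
#'   season; the same month-day window is applied to each historical year.
#' @param n_seasons Number of historical seasons to average (default 5).
#' @return List with `PPT`, `SDI`, `T`, `GDD`, `window`, `seasons_averaged`.
#' @export
weather_indices <- function(series, window, n_seasons = 5) {
  stopifnot(all(c("date", "rain_mm", "tmean_c") %in% names(series)),
            length(window) == 2, n_seasons >= 1)
  dates <- as.Date(series$date)
  window <- as.Date(window)
  if (window[2] <= window[1]) stop("harvest must follow planting")
  per_season <- vector("list", n_seasons)
  for (s in seq_len(n_seasons)) {
    w <- shift_years(window, -s)
    keep <- dates >= w[1] & dates <= w[2]
    if (!any(keep)) {
      stop("no weather data for season window ", w[1], " to ", w[2])
    }
    per_season[[s]] <- season_indices(series$rain_mm[keep],
                                      series$tmean_c[keep])
  }
  sdis <- vapply(per_season, `[[`, numeric(1), "SDI")
  if (anyNA(sdis)) {
    warning(sum(is.na(sdis)), " season(s) with zero rainfall skipped for SDI")
  }
  list(PPT = mean(vapply(per_season, `[[`, numeric(1), "PPT")),
       SDI = mean(sdis, na.rm = TRUE),
       T = mean(vapply(per_season, `[[`, numeric(1), "T")),
       GDD = mean(vapply(per_season, `[[`, numeric(1), "GDD")),
       window = window,
       seasons_averaged = n_seasons)
}

# shift a Date vector by whole years keeping month-day (growing windows are
# May-September, so Feb 29 never arises)
shift_years <- function(d, k) {
  lt <- as.POSIXlt(d)
  lt$year <- lt$year + k
  as.Date(lt)
}
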