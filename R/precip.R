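# Reduction of daily precipitation to the two model predictors:
# P_Annual, the calendar-year total, and P_MAM,ext, the total precipitation
# on March-May days strictly exceeding a fixed baseline percentile
# (95th percentile of 1981-2010 in-season daily values by default).
# Thresholds are frozen from the baseline and reused for all years,
# independently per watershed and climate model.

check_precip_series <- function(series) {
  need <- c("date", "pr_mm")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    rn_invalid_input(paste0("precip series missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  if (any(series$pr_mm < 0) || any(!is.finite(series$pr_mm))) {
    rn_invalid_input("daily precipitation must be finite and >= 0")
  }
  invisible(series)
}

series_year <- function(series) as.integer(format(series$date, "%Y"))
series_month <- function(series) as.integer(format(series$date, "%m"))

#' Annual precipitation total
#'
#' Sums daily precipitation over one calendar year of a single
#' watershed-model series.
#'
#' @param series Data frame with columns `date` (Date) and `pr_mm` (>= 0),
#'   one watershed-model series.
#' @param year Calendar year; all its days must be present.
#' @return P_Annual in mm.
#' @export
annual_total <- function(series, year) {
  check_precip_series(series)
  yr <- series_year(series)
  sel <- yr == year
  ndays <- sum(sel)
  expected <- as.integer(as.Date(sprintf("%d-12-31", year)) -
                           as.Date(sprintf("%d-01-01", year))) + 1L
  if (ndays != expected) {
    rn_missing_input(sprintf("year %d has %d of %d days", year, ndays, expected))
  }
  sum(series$pr_mm[sel])
}

#' Extreme-precipitation threshold from a fixed baseline
#'
#' Computes the given percentile (linear interpolation between order
#' statistics) of all in-season daily values across the baseline years of
#' one watershed-model series. Zero days are included in the percentile
#' population unless `wet_day_only = TRUE`.
#'
#' @inheritParams annual_total
#' @param baseline Integer years of the baseline window (default 1981:2010);
#'   all in-season days of every baseline year must be present.
#' @param season Integer months defining the season (default March-May).
#' @param percentile Probability in `[0, 1]` (default 0.95).
#' @param wet_day_only If `TRUE`, restrict the percentile population to
#'   days with positive precipitation.
#' @return An object of class `extreme_threshold`: list with `threshold`
#'   (mm), `baseline`, `season`, `percentile`.
#' @export
#' @examples
#' s <- data.frame(date = seq(as.Date("1981-01-01"), as.Date("2010-12-31"), 1))
#' s$pr_mm <- 5
#' extreme_threshold(s)$threshold
extreme_threshold <- function(series, baseline = 1981:2010, season = 3:5,
                              percentile = 0.95, wet_day_only = FALSE) {
  check_precip_series(series)
  yr <- series_year(series)
  mo <- series_month(series)
  sel <- yr %in% baseline & mo %in% season
  covered <- unique(yr[sel])
  if (!all(baseline %in% covered)) {
    rn_insufficient_baseline(sprintf(
      "baseline years %s not covered by the series",
      paste(setdiff(baseline, covered), collapse = ", ")))
  }
  vals <- series$pr_mm[sel]
  if (wet_day_only) vals <- vals[vals > 0]
  if (length(vals) == 0L) {
    rn_insufficient_baseline("no baseline values to take a percentile of")
  }
  thr <- unname(quantile(vals, probs = percentile, type = 7))
  structure(list(threshold = thr, baseline = range(baseline),
                 season = season, percentile = percentile),
            class = "extreme_threshold")
}

#' Extreme springtime precipitation total
#'
#' Total precipitation on in-season days strictly exceeding the baseline
#' threshold, for one calendar year of one watershed-model series.
#'
#' @inheritParams annual_total
#' @param threshold An [extreme_threshold()] object, or a single number
#'   interpreted as the threshold in mm.
#' @return P_MAM,ext in mm.
#' @export
extreme_mam_total <- function(series, threshold, year) {
  check_precip_series(series)
  if (inherits(threshold, "extreme_threshold")) {
    season <- threshold$season
    thr <- threshold$threshold
  } else {
    season <- 3:5
    thr <- threshold
  }
  yr <- series_year(series)
  mo <- series_month(series)
  sel <- yr == year & mo %in% season
  if (!any(sel)) {
    rn_missing_input(sprintf("no in-season days for year %d", year))
  }
  vals <- series$pr_mm[sel]
  sum(vals[vals > thr])
}

#' Reduce daily precipitation to model features
#'
#' Batch computation of P_Annual and P_MAM,ext for every watershed, climate
#' model and year in a long-format daily table. Extreme thresholds are
#' computed independently per (watershed, model) from the baseline window
#' and reused for all years.
#'
#' @param precip Long data frame: `watershed_id`, `model_id`, optionally
#'   `scenario_id`, `date`, `pr_mm`.
#' @param years Years for which to emit features (default: all full years
#'   present).
#' @param baseline_precip Optional long data frame of the same shape
#'   supplying the baseline window (defaults to `precip` itself; used when
#'   future-scenario series must be thresholded on the historical baseline).
#' @inheritParams extreme_threshold
#' @return Tibble `watershed_id`, `model_id` (and `scenario_id` if present),
#'   `year`, `p_annual_mm`, `p_mam_ext_mm`.
#' @export
precip_features <- function(precip, years = NULL, baseline_precip = NULL,
                            baseline = 1981:2010, season = 3:5,
                            percentile = 0.95, wet_day_only = FALSE) {
  check_precip_series(precip)
  bp <- baseline_precip %||% precip
  check_precip_series(bp)

  keys <- intersect(c("watershed_id", "model_id", "scenario_id"), names(precip))
  grp <- setdiff(keys, "scenario_id")

  bp_yr <- series_year(bp)
  bp_mo <- series_month(bp)
  bsel <- bp_yr %in% baseline & bp_mo %in% season
  bvals <- bp[bsel, , drop = FALSE]
  if (wet_day_only) bvals <- bvals[bvals$pr_mm > 0, , drop = FALSE]
  if (nrow(bvals) == 0L) {
    rn_insufficient_baseline("baseline window not covered by the series")
  }
  thresholds <- bvals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(threshold = unname(quantile(.data$pr_mm, percentile,
                                                 type = 7)),
                     .groups = "drop")

  p <- precip
  p$year <- series_year(p)
  p$month <- series_month(p)
  if (!is.null(years)) p <- p[p$year %in% years, , drop = FALSE]

  ann <- p |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year")))) |>
    dplyr::summarise(p_annual_mm = sum(.data$pr_mm), .groups = "drop")

  ext <- p[p$month %in% season, , drop = FALSE] |>
    dplyr::left_join(thresholds, by = grp) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year")))) |>
    dplyr::summarise(
      p_mam_ext_mm = sum(.data$pr_mm[.data$pr_mm > .data$threshold]),
      .groups = "drop")

  out <- dplyr::left_join(ann, ext, by = c(keys, "year"))
  out$p_mam_ext_mm[is.na(out$p_mam_ext_mm)] <- 0
  out
}
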