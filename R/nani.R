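# Net anthropogenic nitrogen input (NANI) accounting.
#
# NANI = fertilizer + agricultural fixation + atmospheric deposition
#        + net food/feed import - nonfood crop export,
# all in kg N km^-2 y^-1 of watershed area. Food/feed import is a net term
# and may be negative (net export); nonfood crop export leaves the watershed
# and is subtracted.

#' Assemble NANI from its five components
#'
#' @param fertilizer,fixation,deposition Non-negative components,
#'   kg N km^-2 y^-1. Vectors are recycled by ordinary R rules.
#' @param food_feed_import Signed net food and feed import (negative = net
#'   export), kg N km^-2 y^-1.
#' @param nonfood_crop_export Non-negative nonfood crop export (subtracted),
#'   kg N km^-2 y^-1.
#' @return NANI in kg N km^-2 y^-1 (may be negative).
#' @export
#' @examples
#' assemble_nani(7200, 4500, 1400, -3000, 78)
assemble_nani <- function(fertilizer, fixation, deposition,
                          food_feed_import, nonfood_crop_export) {
  comp <- list(fertilizer = fertilizer, fixation = fixation,
               deposition = deposition, food_feed_import = food_feed_import,
               nonfood_crop_export = nonfood_crop_export)
  for (nm in names(comp)) {
    if (any(!is.finite(comp[[nm]]))) {
      rn_invalid_input(paste0("non-finite values in NANI component `", nm, "`"))
    }
  }
  for (nm in c("fertilizer", "fixation", "deposition", "nonfood_crop_export")) {
    if (any(comp[[nm]] < 0)) {
      rn_invalid_input(paste0("NANI component `", nm, "` must be >= 0"))
    }
  }
  fertilizer + fixation + deposition + food_feed_import - nonfood_crop_export
}

#' Area-weighted fertilizer usage from crop states
#'
#' Sums, over the five crop types, the crop's area fraction of the watershed
#' times its fertilizer application rate, yielding fertilizer input per unit
#' watershed area.
#'
#' @param crops Data frame with columns `crop_type`, `area_fraction` (of the
#'   watershed, in `[0, 1]`) and `rate_kg_km2_yr` (per km^2 of that crop),
#'   plus optional grouping columns (`watershed_id`, `year`).
#' @return If grouping columns are present, a tibble of per-group fertilizer
#'   usage (`fertilizer_kg_km2_yr`); otherwise a single number.
#' @export
#' @examples
#' fertilizer_usage(data.frame(crop_type = c("c3_annual", "c4_annual"),
#'                             area_fraction = c(0.2, 0.3),
#'                             rate_kg_km2_yr = c(5000, 10000)))
fertilizer_usage <- function(crops) {
  need <- c("crop_type", "area_fraction", "rate_kg_km2_yr")
  miss <- setdiff(need, names(crops))
  if (length(miss)) {
    rn_invalid_input(paste0("crop table missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  if (any(crops$area_fraction < 0 | crops$area_fraction > 1) ||
      any(crops$rate_kg_km2_yr < 0)) {
    rn_invalid_input("crop area fractions must be in [0,1] and rates >= 0")
  }
  keys <- intersect(c("watershed_id", "year"), names(crops))
  if (length(keys) == 0L) {
    return(sum(crops$area_fraction * crops$rate_kg_km2_yr))
  }
  crops |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      fertilizer_kg_km2_yr = sum(.data$area_fraction * .data$rate_kg_km2_yr),
      .groups = "drop")
}

#' Rescale fertilizer series to regional reference totals
#'
#' Computes one multiplicative factor per HUC2 region, the ratio of the
#' reference 1987-2012 total to the input series' 1987-2012 total, and
#' applies it to all years of the series (including future years). After
#' scaling, each region's total over the reference window matches its
#' reference exactly. Regions with zero input and zero reference total get
#' factor 1.
#'
#' @param series Data frame `watershed_id`, `year`, `value_kg_km2_yr` (or a
#'   `value` column), fertilizer input per unit area.
#' @param watersheds Data frame `watershed_id`, `huc2`, `area_km2` mapping
#'   watersheds to regions.
#' @param reference Data frame `huc2`, `total_kg`: reference totals (kg N
#'   summed over the window years and member watersheds).
#' @param window Integer years of the matching window, default 1987:2012.
#' @return `series` with `value_kg_km2_yr` rescaled; the per-region factors
#'   are attached as attribute `"factors"`.
#' @export
scale_fertilizer_to_reference <- function(series, watersheds, reference,
                                          window = 1987:2012) {
  vcol <- if ("value_kg_km2_yr" %in% names(series)) "value_kg_km2_yr" else "value"
  if (!vcol %in% names(series)) {
    rn_invalid_input("series must carry `value_kg_km2_yr` (or `value`)")
  }
  s <- dplyr::left_join(series, watersheds[c("watershed_id", "huc2", "area_km2")],
                        by = "watershed_id")
  if (any(is.na(s$huc2))) {
    rn_invalid_input("every watershed in `series` must map to one HUC2")
  }
  totals <- s |>
    dplyr::filter(.data$year %in% window) |>
    dplyr::group_by(.data$huc2) |>
    dplyr::summarise(input_total = sum(.data[[vcol]] * .data$area_km2),
                     .groups = "drop") |>
    dplyr::left_join(reference, by = "huc2")
  if (any(is.na(totals$total_kg))) {
    rn_invalid_input("reference totals missing for some HUC2 regions")
  }
  bad <- totals$input_total == 0 & totals$total_kg != 0
  if (any(bad)) {
    rn_unscalable(paste0("cannot scale HUC2 region(s) with zero input total: ",
                         paste(totals$huc2[bad], collapse = ", ")))
  }
  totals$factor <- ifelse(totals$input_total == 0 & totals$total_kg == 0,
                          1, totals$total_kg / totals$input_total)
  out <- dplyr::left_join(s, totals[c("huc2", "factor")], by = "huc2")
  out[[vcol]] <- out[[vcol]] * out$factor
  out <- out[names(series)]
  attr(out, "factors") <- totals[c("huc2", "factor")]
  out
}

#' Nitrogen fixation from nitrogen-fixing crop area
#'
#' @param c3_nfix_area Area of C3 nitrogen-fixing crops, km^2 (vectorized).
#' @param rate Fixation rate, kg N km^-2 y^-1; the default is the rate
#'   calibrated so continental fixation matches 6.9 Tg N in 2007.
#' @return Fixation in kg N y^-1.
#' @export
fixation_from_area <- function(c3_nfix_area, rate = 14300) {
  if (any(c3_nfix_area < 0) || any(rate < 0)) {
    rn_invalid_input("fixation area and rate must be >= 0")
  }
  c3_nfix_area * rate
}

#' Calibrate the fixation rate to a national total
#'
#' Finds the constant per-area fixation rate such that applying it to the
#' given nitrogen-fixing crop areas reproduces the target national total
#' exactly (rate = target / total area).
#'
#' @param c3_nfix_area Vector of nitrogen-fixing crop areas (km^2), e.g. per
#'   watershed for the calibration year.
#' @param target_total Target total fixation, kg N y^-1 (e.g. 6.9e9 for the
#'   2007 continental estimate).
#' @return The calibrated rate in kg N km^-2 y^-1.
#' @export
calibrate_fixation_rate <- function(c3_nfix_area, target_total) {
  total_area <- sum(c3_nfix_area)
  if (!is.finite(total_area) || total_area <= 0) {
    rn_invalid_input(
      "calibration impossible: total nitrogen-fixing crop area is zero")
  }
  target_total / total_area
}

#' Fit the regional food/feed-import regression
#'
#' Per HUC2 region, ordinary least squares of historical net food and feed
#' import on historical fertilizer input and agricultural nitrogen fixation
#' (all as per-area intensities, kg N km^-2 y^-1), with an intercept. The
#' fitted relationships are assumed stationary and reused to predict future
#' import from scenario fertilizer and fixation.
#'
#' @param history Data frame `huc2`, `year`, `import_kg_km2_yr`,
#'   `fertilizer_kg_km2_yr`, `fixation_kg_km2_yr`, one row per region and
#'   census year (at least 4 census years per region).
#' @return An object of class `import_regression`: tibble of per-region
#'   `intercept`, `slope_fertilizer`, `slope_fixation`.
#' @export
fit_import_regression <- function(history) {
  need <- c("huc2", "year", "import_kg_km2_yr", "fertilizer_kg_km2_yr",
            "fixation_kg_km2_yr")
  miss <- setdiff(need, names(history))
  if (length(miss)) {
    rn_invalid_input(paste0("import history missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  fit_one <- function(d) {
    if (nrow(d) < 4L) {
      rn_invalid_input(sprintf(
        "HUC2 %s has %d census records; need >= 4", d$huc2[1], nrow(d)))
    }
    fit <- lm(import_kg_km2_yr ~ fertilizer_kg_km2_yr + fixation_kg_km2_yr,
              data = d)
    if (fit$rank < 3L || any(is.na(coef(fit)))) {
      rn_degenerate_design(paste0(
        "collinear fertilizer/fixation history in HUC2 ", d$huc2[1]))
    }
    tibble::tibble(huc2 = d$huc2[1],
                   intercept = unname(coef(fit)[1]),
                   slope_fertilizer = unname(coef(fit)[2]),
                   slope_fixation = unname(coef(fit)[3]))
  }
  coefs <- history |>
    dplyr::group_by(.data$huc2) |>
    dplyr::group_split() |>
    lapply(fit_one) |>
    dplyr::bind_rows()
  structure(list(coefficients = coefs), class = "import_regression")
}

#' @export
print.import_regression <- function(x, ...) {
  cat("Per-HUC2 food/feed import regression (import ~ fertilizer + fixation)\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Predict net food/feed import from the regional regression
#'
#' @param object An [fit_import_regression()] fit.
#' @param huc2 Region ids (vector).
#' @param fertilizer,fixation Fertilizer and fixation intensities,
#'   kg N km^-2 y^-1, matching `huc2`.
#' @return Predicted net import, kg N km^-2 y^-1 (signed; may be negative).
#' @export
predict_import <- function(object, huc2, fertilizer, fixation) {
  stopifnot(inherits(object, "import_regression"))
  idx <- match(huc2, object$coefficients$huc2)
  if (any(is.na(idx))) {
    rn_missing_input(paste0("no import regression for HUC2 ",
                            huc2[which(is.na(idx))[1]]))
  }
  co <- object$coefficients[idx, ]
  co$intercept + co$slope_fertilizer * fertilizer +
    co$slope_fixation * fixation
}

#' Scale a modelled deposition series to a reference
#'
#' Computes, per watershed, the ratio of mean reference deposition to mean
#' modelled deposition over an overlap window, and multiplies the modelled
#' series (typically its future years) by that factor. A zero/zero overlap
#' gives factor 1; zero modelled mean against nonzero reference is an error.
#'
#' @param model Data frame `watershed_id`, `year`, `dep_kg_km2_yr`: the
#'   modelled series to be adjusted (must cover the overlap years).
#' @param reference Data frame with the same columns covering the overlap.
#' @param overlap Integer years of the overlap window (default 2002:2006).
#' @return `model` with `dep_kg_km2_yr` rescaled; per-watershed factors
#'   attached as attribute `"factors"`.
#' @export
scale_deposition <- function(model, reference, overlap = 2002:2006) {
  mean_over <- function(d, label) {
    d2 <- dplyr::filter(d, .data$year %in% overlap)
    cnt <- dplyr::count(d2, .data$watershed_id)
    if (nrow(d2) == 0L || any(cnt$n < length(overlap))) {
      rn_invalid_input(paste0(label, " series does not cover the overlap years"))
    }
    dplyr::summarise(dplyr::group_by(d2, .data$watershed_id),
                     m = mean(.data$dep_kg_km2_yr), .groups = "drop")
  }
  mm <- mean_over(model, "model")
  mr <- mean_over(reference, "reference")
  f <- dplyr::inner_join(mm, mr, by = "watershed_id",
                         suffix = c("_model", "_ref"))
  bad <- f$m_model == 0 & f$m_ref != 0
  if (any(bad)) {
    rn_unscalable(paste0("zero modelled deposition with nonzero reference in ",
                         paste(f$watershed_id[bad], collapse = ", ")))
  }
  f$factor <- ifelse(f$m_model == 0 & f$m_ref == 0, 1, f$m_ref / f$m_model)
  out <- model |>
    dplyr::left_join(f[c("watershed_id", "factor")], by = "watershed_id") |>
    dplyr::mutate(dep_kg_km2_yr = .data$dep_kg_km2_yr * .data$factor) |>
    dplyr::select(dplyr::all_of(names(model)))
  attr(out, "factors") <- f[c("watershed_id", "factor")]
  out
}

#' Interpolate census-year values to an annual series
#'
#' Piecewise-linear interpolation between adjacent census years; years
#' before the first census year are filled by extrapolating the OLS linear
#' trend fitted to all census points. Years after the last census year are
#' not extrapolated here (see [hold_constant_after()]).
#'
#' @param census Data frame `year`, `value` at census years (>= 2 points).
#' @param years Integer target years, each at or before the last census year.
#' @param floor_zero If `TRUE`, clamp the result at zero (used for
#'   fixation, which cannot be negative; imports stay unrestricted).
#' @return Tibble `year`, `value` over `years`.
#' @export
#' @examples
#' interpolate_census(data.frame(year = c(1987, 1992), value = c(100, 110)),
#'                    1989)
interpolate_census <- function(census, years, floor_zero = FALSE) {
  if (nrow(census) < 2L) rn_invalid_input("need >= 2 census points")
  census <- dplyr::arrange(census, .data$year)
  if (any(years > max(census$year))) {
    rn_invalid_input("target years beyond the last census year; use hold_constant_after()")
  }
  inside <- years >= min(census$year)
  value <- numeric(length(years))
  if (any(inside)) {
    value[inside] <- stats::approx(census$year, census$value,
                                   xout = years[inside])$y
  }
  if (any(!inside)) {
    trend <- lm(value ~ year, data = census)
    value[!inside] <- predict(trend, data.frame(year = years[!inside]))
  }
  if (floor_zero) value <- pmax(value, 0)
  tibble::tibble(year = years, value = value)
}

#' Hold a series constant beyond an anchor year
#'
#' Values after (`direction = "forward"`) or before (`direction =
#' "backward"`) the anchor year are replaced by the anchor-year value; used
#' for nonfood crop export after 2007 and for deposition before 1979.
#'
#' @param series Data frame `year`, `value`.
#' @param anchor_year Year whose value is propagated; must be present.
#' @param years Target years to fill (default: the series' own years).
#' @param direction `"forward"` or `"backward"`.
#' @return Tibble `year`, `value` over the union of `series$year` and
#'   `years`, with out-of-anchor years filled.
#' @export
hold_constant_after <- function(series, anchor_year, years = NULL,
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!anchor_year %in% series$year) {
    rn_invalid_input(sprintf("anchor year %s missing from series", anchor_year))
  }
  anchor_value <- series$value[match(anchor_year, series$year)]
  all_years <- sort(union(series$year, years %||% series$year))
  value <- series$value[match(all_years, series$year)]
  beyond <- if (direction == "forward") all_years > anchor_year
            else all_years < anchor_year
  value[beyond] <- anchor_value
  if (anyNA(value)) {
    rn_missing_input("series has gaps on the non-held side of the anchor")
  }
  tibble::tibble(year = all_years, value = value)
}
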