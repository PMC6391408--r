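# Scenario engine: orchestrates TN-flux estimation for historical and
# future periods across scenario configurations — land-management-only runs
# (historical precipitation), combined land-management + precipitation runs
# (paired RCP), and single-factor decomposition runs.
#
# Convention for "historical level" of a flagged driver in a future-period
# year: year-offset mapping, future_start + k <-> hist_start + k, which
# preserves interannual variability within the 30-year windows. The same
# mapping carries historical precipitation (and deposition) into
# land-management-only future runs.

#' Pair an SSP scenario with its CMIP5 precipitation pathway
#'
#' Fixed pairing table: each land-use/land-management scenario is combined
#' with the most similar available concentration pathway (SSP4-3.4 with
#' RCP2.6; SSP3-7.0, a high-vulnerability high-forcing storyline, with
#' RCP8.5).
#'
#' @param ssp Scenario id, e.g. `"SSP1-2.6"`.
#' @return The paired RCP id, e.g. `"RCP2.6"`.
#' @export
#' @examples
#' pair_rcp("SSP4-3.4")
pair_rcp <- function(ssp) {
  table <- c("SSP1-2.6" = "RCP2.6", "SSP2-4.5" = "RCP4.5",
             "SSP4-6.0" = "RCP6.0", "SSP5-8.5" = "RCP8.5",
             "SSP4-3.4" = "RCP2.6", "SSP3-7.0" = "RCP8.5")
  if (length(ssp) != 1L || !ssp %in% names(table)) {
    rn_config_error(paste0("unknown SSP scenario id `", paste(ssp), "`"))
  }
  unname(table[[ssp]])
}

#' Specify a scenario run
#'
#' A scenario specification names the SSP, the precipitation mode
#' (historical ensemble vs. the paired RCP pathway), the three factor flags
#' controlling whether cropland, developed land and fertilizer application
#' rates follow the future trajectory or stay at historical levels, and the
#' NANI source (driver-derived "luh2" accounting vs. the observation-mode
#' component record, the latter only meaningful with all-historical flags).
#'
#' @param ssp Scenario id (one of the six known SSP-RCP combinations).
#' @param precipitation `"historical"` or `"paired-rcp"`.
#' @param cropland,developed,fertilizer_rate `"future"` or `"historical"`.
#' @param nani_source `"luh2"` (driver accounting) or `"observed"`.
#' @return A list of class `tn_scenario` (with the paired `rcp` filled in).
#' @export
scenario_spec <- function(ssp,
                          precipitation = c("historical", "paired-rcp"),
                          cropland = c("future", "historical"),
                          developed = c("future", "historical"),
                          fertilizer_rate = c("future", "historical"),
                          nani_source = c("luh2", "observed")) {
  structure(list(
    ssp = ssp,
    rcp = pair_rcp(ssp),
    precipitation = match.arg(precipitation),
    cropland = match.arg(cropland),
    developed = match.arg(developed),
    fertilizer_rate = match.arg(fertilizer_rate),
    nani_source = match.arg(nani_source)
  ), class = "tn_scenario")
}

#' @export
print.tn_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s (precipitation: %s, paired %s)\n", x$ssp,
              x$precipitation, x$rcp))
  cat(sprintf("  factors - cropland: %s, developed: %s, fertilizer rate: %s; NANI: %s\n",
              x$cropland, x$developed, x$fertilizer_rate, x$nani_source))
  invisible(x)
}

#' Canonical 30-year analysis periods
#'
#' @return Tibble `label`, `start`, `end` for the historical (1976-2005),
#'   middle-of-the-century (2031-2060) and end-of-the-century (2071-2100)
#'   periods.
#' @export
canonical_periods <- function() {
  tibble::tibble(label = c("historical", "mid-century", "end-of-century"),
                 start = c(1976L, 2031L, 2071L),
                 end = c(2005L, 2060L, 2100L))
}

world_years <- function(world) {
  hist <- world$hist_years %||% world$config$years_historical
  fut <- world$future_years %||% world$config$years_future
  if (is.null(hist) || is.null(fut)) {
    rn_config_error("world must define historical and future year ranges")
  }
  list(hist = hist, fut = fut)
}

map_hist_year <- function(year, yrs) {
  m <- ifelse(year <= max(yrs$hist), year,
              min(yrs$hist) + (year - min(yrs$fut)))
  bad <- m < min(yrs$hist) | m > max(yrs$hist)
  if (any(bad)) {
    rn_missing_input(sprintf(
      "year %d has no historical counterpart under the year-offset mapping",
      year[bad][1]))
  }
  m
}

slice_year <- function(tbl, year, what) {
  out <- tbl[tbl$year == year, , drop = FALSE]
  if (nrow(out) == 0L) {
    rn_missing_input(sprintf("no %s records for year %d", what, year))
  }
  out
}

# Driver-derived (scenario-mode) NANI for one evaluation year.
luh2_nani_year <- function(spec, world, y, yrs) {
  lu_src <- function(flag) {
    if (flag == "future" && y > max(yrs$hist)) {
      list(tbl = world$landuse[[spec$ssp]], year = y)
    } else {
      list(tbl = world$landuse$historical,
           year = if (y <= max(yrs$hist)) y else map_hist_year(y, yrs))
    }
  }
  crop_src <- lu_src(spec$cropland)
  dev_src <- lu_src(spec$developed)
  rate_src <- lu_src(spec$fertilizer_rate)

  areas <- slice_year(crop_src$tbl$crops, crop_src$year, "crop-area")
  rates <- slice_year(rate_src$tbl$crops, rate_src$year, "fertilizer-rate")
  crops <- dplyr::inner_join(
    areas[c("watershed_id", "crop_type", "area_fraction")],
    rates[c("watershed_id", "crop_type", "rate_kg_km2_yr")],
    by = c("watershed_id", "crop_type"))
  fert <- crops |>
    dplyr::group_by(.data$watershed_id) |>
    dplyr::summarise(fertilizer = sum(.data$area_fraction * .data$rate_kg_km2_yr),
                     .groups = "drop")
  fix <- crops |>
    dplyr::filter(.data$crop_type == "c3_nfix") |>
    dplyr::transmute(.data$watershed_id,
                     fixation = .data$area_fraction *
                       (world$fixation_rate %||% world$config$fixation_rate %||% 14300))

  d <- dplyr::left_join(world$watersheds[c("watershed_id", "huc2")], fert,
                        by = "watershed_id") |>
    dplyr::left_join(fix, by = "watershed_id")
  if (anyNA(d$fertilizer) || anyNA(d$fixation)) {
    rn_missing_input(sprintf(
      "crop states missing for watershed %s in year %d",
      d$watershed_id[which(is.na(d$fertilizer) | is.na(d$fixation))[1]], y))
  }
  if (!is.null(world$fertilizer_factors)) {
    d <- dplyr::left_join(d, world$fertilizer_factors, by = "huc2")
    d$fertilizer <- d$fertilizer * d$factor
    d$factor <- NULL
  }
  d$food_feed_import <- predict_import(world$import_model, d$huc2,
                                       d$fertilizer, d$fixation)

  dep_year <- if (spec$precipitation == "paired-rcp" && y > max(yrs$hist)) {
    list(tbl = world$deposition[[rcp_key(spec$rcp)]], year = y)
  } else {
    list(tbl = world$deposition$historical,
         year = if (y <= max(yrs$hist)) y else map_hist_year(y, yrs))
  }
  if (is.null(dep_year$tbl)) {
    rn_missing_input(paste0("no deposition pathway for ", spec$rcp))
  }
  dep <- slice_year(dep_year$tbl, dep_year$year, "deposition")
  d <- dplyr::left_join(d, dep[c("watershed_id", "dep_kg_km2_yr")],
                        by = "watershed_id")

  nf_anchor <- world$nonfood_anchor %||% 2007
  nf_year <- min(if (y <= max(yrs$hist)) y else nf_anchor, nf_anchor)
  nf_year <- max(nf_year, min(world$nonfood$year))
  nf <- slice_year(world$nonfood, nf_year, "nonfood-export")
  d <- dplyr::left_join(d, nf[c("watershed_id", "value_kg_km2_yr")],
                        by = "watershed_id")
  if (anyNA(d$dep_kg_km2_yr) || anyNA(d$value_kg_km2_yr)) {
    rn_missing_input(sprintf(
      "deposition or nonfood-export missing for watershed %s",
      d$watershed_id[which(is.na(d$dep_kg_km2_yr) | is.na(d$value_kg_km2_yr))[1]]))
  }
  # negative driver-derived fertilizer/fixation cannot occur by construction,
  # but clamp defensively (imports stay signed)
  d$fertilizer <- pmax(d$fertilizer, 0)
  d$fixation <- pmax(d$fixation, 0)
  tibble::tibble(
    watershed_id = d$watershed_id,
    nani = assemble_nani(d$fertilizer, d$fixation, d$dep_kg_km2_yr,
                         d$food_feed_import, d$value_kg_km2_yr))
}

#' Project TN flux for a scenario configuration
#'
#' For every requested year, watershed and climate model, builds the
#' predictor record — NANI (driver accounting or observed components,
#' honouring the factor flags), developed + cropland percent cover, and the
#' precipitation features of the configured mode — and applies the TN
#' loading model.
#'
#' Future-period years draw flagged-historical drivers from the historical
#' record via the year-offset mapping (see module header); consequently an
#' all-historical configuration evaluated over the future period reproduces
#' the historical baseline values exactly.
#'
#' @param spec A [scenario_spec()].
#' @param world A `tn_world` from [generate_world()], or any list providing
#'   the same fields (`watersheds`, `landuse`, `precip_features`,
#'   `deposition`, `nonfood`, `import_model`, and year ranges via `config`
#'   or `hist_years`/`future_years`).
#' @param years Years to evaluate (default: historical + future periods).
#' @param coefficients [tn_coefficients()] to apply.
#' @return Tibble `watershed_id`, `model_id`, `year`, `flux_kg_km2_yr` with
#'   the scenario spec attached as attribute `"spec"`.
#' @export
run_projection <- function(spec, world, years = NULL,
                           coefficients = tn_coefficients()) {
  stopifnot(inherits(spec, "tn_scenario"))
  yrs <- world_years(world)
  years <- years %||% c(yrs$hist, yrs$fut)

  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    is_hist <- y <= max(yrs$hist)

    lu_year <- function(flag) {
      if (flag == "future" && !is_hist) {
        list(tbl = world$landuse[[spec$ssp]]$landuse, year = y)
      } else {
        list(tbl = world$landuse$historical$landuse,
             year = if (is_hist) y else map_hist_year(y, yrs))
      }
    }
    crop_lu <- lu_year(spec$cropland)
    dev_lu <- lu_year(spec$developed)
    crop_frac <- slice_year(crop_lu$tbl, crop_lu$year, "land-use")
    dev_frac <- slice_year(dev_lu$tbl, dev_lu$year, "land-use")
    lu <- dplyr::inner_join(
      crop_frac[c("watershed_id", "cropland")],
      dev_frac[c("watershed_id", "developed")],
      by = "watershed_id")
    lu$lu_dc <- 100 * (lu$cropland + lu$developed)

    if (spec$nani_source == "observed") {
      ny <- if (is_hist) y else map_hist_year(y, yrs)
      comp <- slice_year(world$components, ny, "NANI-component")
      nani <- comp[c("watershed_id", "nani")]
    } else {
      nani <- luh2_nani_year(spec, world, y, yrs)
    }

    if (spec$precipitation == "paired-rcp" && !is_hist) {
      feats <- world$precip_features[[rcp_key(spec$rcp)]]
      if (is.null(feats)) {
        rn_missing_input(paste0("no precipitation features for ", spec$rcp))
      }
      feats <- slice_year(feats, y, "precipitation-feature")
    } else {
      fy <- if (is_hist) y else map_hist_year(y, yrs)
      feats <- slice_year(world$precip_features$historical, fy,
                          "precipitation-feature")
    }

    d <- lu[c("watershed_id", "lu_dc")] |>
      dplyr::inner_join(nani, by = "watershed_id") |>
      dplyr::inner_join(
        feats[c("watershed_id", "model_id", "p_annual_mm", "p_mam_ext_mm")],
        by = "watershed_id")
    if (nrow(d) == 0L) {
      rn_missing_input(sprintf("no complete predictor records for year %d", y))
    }
    out[[i]] <- tibble::tibble(
      watershed_id = d$watershed_id,
      model_id = d$model_id,
      year = y,
      flux_kg_km2_yr = predict_tn_flux(
        data.frame(nani = d$nani, p_annual = d$p_annual_mm,
                   p_mam_ext = d$p_mam_ext_mm, lu_dc = d$lu_dc),
        coefficients))
  }
  field <- dplyr::bind_rows(out)
  attr(field, "spec") <- spec
  field
}

#' Factorial decomposition runs
#'
#' Produces the flux fields needed to attribute future change to its
#' drivers: the historical baseline, the all-future ("combined") run, and
#' the three single-factor runs — future cropland only (with its embedded
#' NANI changes), future developed land only, and future fertilizer
#' application rates only. Precipitation is kept at historical levels
#' (required of `spec`), and NANI is driver-derived for both periods so the
#' two periods are accounted identically.
#'
#' @param spec A [scenario_spec()] with `precipitation = "historical"`.
#' @param world As in [run_projection()].
#' @param years_hist,years_fut Historical and future evaluation years
#'   (defaults: the world's periods).
#' @param coefficients [tn_coefficients()] to apply.
#' @return Named list of flux fields: `historical` (historical period),
#'   `baseline` (future period, all factors historical — the delta
#'   reference), `combined`, `cropland`, `developed`, `fertilizer_rate`.
#' @export
decomposition_runs <- function(spec, world, years_hist = NULL,
                               years_fut = NULL,
                               coefficients = tn_coefficients()) {
  stopifnot(inherits(spec, "tn_scenario"))
  if (spec$precipitation != "historical") {
    rn_config_error("decomposition requires precipitation = 'historical'")
  }
  yrs <- world_years(world)
  years_hist <- years_hist %||% yrs$hist
  years_fut <- years_fut %||% yrs$fut

  flag_sets <- list(
    combined = c(cropland = "future", developed = "future",
                 fertilizer_rate = "future"),
    cropland = c(cropland = "future", developed = "historical",
                 fertilizer_rate = "historical"),
    developed = c(cropland = "historical", developed = "future",
                  fertilizer_rate = "historical"),
    fertilizer_rate = c(cropland = "historical", developed = "historical",
                        fertilizer_rate = "future"))

  base <- scenario_spec(spec$ssp, precipitation = "historical",
                        cropland = "historical", developed = "historical",
                        fertilizer_rate = "historical", nani_source = "luh2")
  # `historical` is the historical-period run (the percent-change anchor);
  # `baseline` is the same all-historical configuration evaluated over the
  # future period, the common reference against which single-factor deltas
  # are defined
  out <- list(historical = run_projection(base, world, years_hist,
                                          coefficients),
              baseline = run_projection(base, world, years_fut,
                                        coefficients))
  for (nm in names(flag_sets)) {
    f <- flag_sets[[nm]]
    s <- scenario_spec(spec$ssp, precipitation = "historical",
                       cropland = f[["cropland"]],
                       developed = f[["developed"]],
                       fertilizer_rate = f[["fertilizer_rate"]],
                       nani_source = "luh2")
    out[[nm]] <- run_projection(s, world, years_fut, coefficients)
  }
  out
}

#' Shrink a scenario's future drivers toward historical levels
#'
#' Replaces, for every future-period year, the scenario's land-use fractions
#' and crop states by `historical + epsilon * (future - historical)` (with
#' the historical counterpart taken at the year-offset-mapped year). Used to
#' examine the linear limit of the factorial decomposition, where
#' single-factor contributions become additive.
#'
#' @param world A `tn_world` (or compatible list).
#' @param ssp Scenario id whose future drivers are blended.
#' @param epsilon Blend weight in `[0, 1]`; 0 collapses the future onto the
#'   historical record, 1 leaves the scenario unchanged.
#' @return A modified copy of `world`.
#' @export
blend_drivers <- function(world, ssp, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  yrs <- world_years(world)
  sc <- world$landuse[[ssp]]
  if (is.null(sc)) rn_config_error(paste0("world has no scenario `", ssp, "`"))
  hist <- world$landuse$historical

  blend_tbl <- function(fut_tbl, hist_tbl, keys, cols) {
    fut_years <- intersect(unique(fut_tbl$year), yrs$fut)
    rows <- fut_tbl$year %in% fut_years
    f <- fut_tbl[rows, , drop = FALSE]
    f$.hist_year <- map_hist_year(f$year, yrs)
    h <- hist_tbl
    names(h)[names(h) == "year"] <- ".hist_year"
    j <- dplyr::left_join(f, h, by = c(keys, ".hist_year"),
                          suffix = c("", ".hist"))
    for (cl in cols) {
      hv <- j[[paste0(cl, ".hist")]]
      if (anyNA(hv)) rn_missing_input("historical counterpart missing in blend")
      j[[cl]] <- hv + epsilon * (j[[cl]] - hv)
    }
    fut_tbl[rows, cols] <- j[cols]
    fut_tbl
  }

  sc$landuse <- blend_tbl(sc$landuse, hist$landuse, "watershed_id",
                          lu_categories())
  sc$crops <- blend_tbl(sc$crops, hist$crops,
                        c("watershed_id", "crop_type"),
                        c("area_fraction", "rate_kg_km2_yr"))
  world$landuse[[ssp]] <- sc
  world
}

#' 30-year period mean of a flux field
#'
#' @param field Flux field from [run_projection()].
#' @param period A row of [canonical_periods()], a `list(start =, end =)`,
#'   or a numeric `c(start, end)`.
#' @return Tibble `watershed_id`, `model_id`, `mean_flux_kg_km2_yr`.
#' @export
period_mean <- function(field, period) {
  if (is.numeric(period) && length(period) == 2L) {
    period <- list(start = period[1], end = period[2])
  }
  years <- period$start:period$end
  sub <- field[field$year %in% years, , drop = FALSE]
  cnt <- dplyr::count(sub, .data$watershed_id, .data$model_id)
  if (nrow(cnt) == 0L || any(cnt$n != length(years))) {
    rn_missing_input(sprintf(
      "flux field does not cover every year of %d-%d for every watershed-model",
      period$start, period$end))
  }
  sub |>
    dplyr::group_by(.data$watershed_id, .data$model_id) |>
    dplyr::summarise(mean_flux_kg_km2_yr = mean(.data$flux_kg_km2_yr),
                     .groups = "drop")
}
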