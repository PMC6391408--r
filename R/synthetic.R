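# Seeded synthetic worlds with the statistical structure the analysis
# assumes: watershed networks with HUC2 regions, Bernoulli-Gamma daily
# precipitation per climate model with scenario trend factors, smooth
# land-use trajectories continuous at the 2015 historical/future junction,
# crop states with fertilizer rates, and NANI components whose continental
# mean shares reproduce the historical budget (fertilizer ~ +72%, fixation
# ~ +45%, deposition ~ +14%, food/feed import ~ -30%, nonfood crop export
# ~ +0.78% of NANI).

ssp_ids <- function() {
  c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP4-3.4", "SSP4-6.0", "SSP5-8.5")
}

rcp_key <- function(rcp) tolower(gsub("[-.]", "", rcp))

# deterministic sub-seed per generator stage (and optional scenario),
# kept well below 2^31
seed_for <- function(cfg, tag, scenario = "") {
  h <- sum(utf8ToInt(paste0(tag, "/", scenario))) %% 9973L
  (abs(cfg$seed) %% 199999L) * 10007L + h
}

#' Configuration of a synthetic world
#'
#' Collects every tunable of the synthetic-world generators: domain size,
#' ensemble sizes per climate pathway, year ranges, the generating TN-model
#' coefficients, precipitation-process parameters, per-scenario land-use and
#' fertilizer-rate trajectories, and the NANI component share targets.
#'
#' The default world is deliberately small (50 watersheds, 5 HUC2 regions,
#' 7 climate models per pathway) so that full pipelines run in seconds;
#' `preset = "paper"` switches to the full-scale domain (2105 watersheds,
#' ensembles of 21/16/20/12/21 models for the historical and RCP2.6/4.5/
#' 6.0/8.5 pathways).
#'
#' @param n_watersheds,n_huc2 Domain size.
#' @param n_models Named integer vector of ensemble sizes for `historical`,
#'   `rcp26`, `rcp45`, `rcp60`, `rcp85`.
#' @param years_historical,years_baseline,years_future Canonical 30-year
#'   historical period, percentile baseline window, and future period.
#' @param seed Integer master seed; every generator derives its own stream.
#' @param coefficients Generating [tn_coefficients()].
#' @param r_squared_target Population R^2 of synthetic calibration data used
#'   to set the ln-scale noise SD when `noise_sd` is `NULL`.
#' @param n_calibration Number of synthetic catchment-year records.
#' @param wet_day_prob Range of per-watershed wet-day probabilities.
#' @param gamma_shape Gamma shape of wet-day amounts.
#' @param mean_annual_precip Range (mm) of per-watershed expected annual
#'   precipitation.
#' @param model_jitter_sd SD of the lognormal per-climate-model jitter on
#'   the precipitation scale parameter.
#' @param precip_trends Named list of multiplicative trend factors applied
#'   to the wet-day scale parameter in future years, per RCP pathway.
#' @param landuse_deltas Named list (per SSP scenario) of
#'   `c(cropland = ..., developed = ...)` 2015-to-2100 fraction changes.
#' @param fert_rate_factors Named list (per SSP scenario) of 2100/2015
#'   fertilizer application rate multipliers.
#' @param dep_factors Named list (per RCP) of end-of-century deposition
#'   multipliers relative to historical.
#' @param nani_shares Target continental mean component shares of NANI.
#' @param mean_cropland Mean historical cropland fraction.
#' @param fixation_rate Fixation rate applied to nitrogen-fixing crop area,
#'   kg N km^-2 y^-1.
#' @param census_years Agricultural census years used for observation-mode
#'   NANI inputs.
#' @param preset `"default"` (small fast world) or `"paper"` (full-scale
#'   domain and ensemble sizes).
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_watersheds = 50,
                         n_huc2 = 5,
                         n_models = c(historical = 7, rcp26 = 7, rcp45 = 7,
                                      rcp60 = 7, rcp85 = 7),
                         years_historical = 1976:2005,
                         years_baseline = 1981:2010,
                         years_future = 2071:2100,
                         seed = 1,
                         coefficients = tn_coefficients(),
                         r_squared_target = 0.67,
                         n_calibration = 280,
                         wet_day_prob = c(0.20, 0.45),
                         gamma_shape = 0.8,
                         mean_annual_precip = c(600, 1400),
                         model_jitter_sd = 0.06,
                         precip_trends = list(rcp26 = 1.02, rcp45 = 1.05,
                                              rcp60 = 1.07, rcp85 = 1.12),
                         landuse_deltas = list(
                           "SSP1-2.6" = c(cropland = 0.04, developed = 0.01),
                           "SSP2-4.5" = c(cropland = 0.00, developed = 0.01),
                           "SSP3-7.0" = c(cropland = 0.08, developed = 0.02),
                           "SSP4-3.4" = c(cropland = 0.10, developed = 0.01),
                           "SSP4-6.0" = c(cropland = 0.07, developed = 0.02),
                           "SSP5-8.5" = c(cropland = -0.03, developed = 0.03)),
                         fert_rate_factors = list(
                           "SSP1-2.6" = 1.10, "SSP2-4.5" = 0.95,
                           "SSP3-7.0" = 1.25, "SSP4-3.4" = 1.30,
                           "SSP4-6.0" = 1.20, "SSP5-8.5" = 0.85),
                         dep_factors = list(rcp26 = 0.7, rcp45 = 0.8,
                                            rcp60 = 0.85, rcp85 = 0.9),
                         nani_shares = c(fertilizer = 0.72, fixation = 0.45,
                                         deposition = 0.14,
                                         food_feed_import = -0.30,
                                         nonfood_crop_export = 0.0078),
                         mean_cropland = 0.25,
                         fixation_rate = 14300,
                         census_years = c(1987, 1992, 1997, 2002, 2007, 2012),
                         preset = c("default", "paper")) {
  preset <- match.arg(preset)
  cfg <- list(
    n_watersheds = n_watersheds, n_huc2 = n_huc2, n_models = n_models,
    years_historical = years_historical, years_baseline = years_baseline,
    years_future = years_future, seed = as.integer(seed),
    coefficients = coefficients, r_squared_target = r_squared_target,
    n_calibration = n_calibration, wet_day_prob = wet_day_prob,
    gamma_shape = gamma_shape, mean_annual_precip = mean_annual_precip,
    model_jitter_sd = model_jitter_sd, precip_trends = precip_trends,
    landuse_deltas = landuse_deltas, fert_rate_factors = fert_rate_factors,
    dep_factors = dep_factors, nani_shares = nani_shares,
    mean_cropland = mean_cropland, fixation_rate = fixation_rate,
    census_years = census_years
  )
  if (preset == "paper") {
    cfg$n_watersheds <- 2105
    cfg$n_huc2 <- 18
    cfg$n_models <- c(historical = 21, rcp26 = 16, rcp45 = 20,
                      rcp60 = 12, rcp85 = 21)
  }
  if (cfg$n_watersheds < 1 || cfg$n_huc2 < 1 || any(cfg$n_models < 1)) {
    rn_config_error("world_config counts must be positive")
  }
  structure(cfg, class = "world_config")
}

#' Generate the watershed table of a synthetic world
#'
#' Watersheds receive log-normal areas, a cyclic HUC2 assignment, and two
#' disjoint region memberships emulating the Mississippi-Atchafalaya-like
#' interior basin and a Northeast-like coastal region; CONUS is the union of
#' all watersheds.
#'
#' @param cfg A [world_config()].
#' @return Tibble `watershed_id`, `huc2`, `area_km2`, `in_marb`,
#'   `in_northeast`.
#' @export
generate_watersheds <- function(cfg) {
  set.seed(seed_for(cfg, "watersheds"))
  n <- cfg$n_watersheds
  huc2 <- sprintf("H%02d", rep_len(seq_len(cfg$n_huc2), n))
  area <- stats::rlnorm(n, meanlog = log(3500), sdlog = 0.5)
  marb_huc2 <- sprintf("H%02d", seq_len(max(1L, floor(cfg$n_huc2 * 0.4))))
  ne_huc2 <- sprintf("H%02d", cfg$n_huc2)
  tibble::tibble(
    watershed_id = sprintf("W%04d", seq_len(n)),
    huc2 = huc2,
    area_km2 = area,
    in_marb = huc2 %in% marb_huc2,
    in_northeast = huc2 %in% ne_huc2
  )
}

#' Region definitions from a watershed table
#'
#' @param watersheds Output of [generate_watersheds()].
#' @return Tibble `region_id`, `watershed_id` with CONUS (all watersheds),
#'   MARB and Northeast rows.
#' @export
regions_from_watersheds <- function(watersheds) {
  dplyr::bind_rows(
    tibble::tibble(region_id = "CONUS", watershed_id = watersheds$watershed_id),
    tibble::tibble(region_id = "MARB",
                   watershed_id = watersheds$watershed_id[watersheds$in_marb]),
    tibble::tibble(region_id = "Northeast",
                   watershed_id = watersheds$watershed_id[watersheds$in_northeast])
  )
}

# Per-watershed precipitation process parameters; shared across scenarios so
# future-minus-historical contrasts reflect trend factors only.
precip_params <- function(cfg, watersheds) {
  set.seed(seed_for(cfg, "precip_params"))
  n <- nrow(watersheds)
  p_wet <- runif(n, cfg$wet_day_prob[1], cfg$wet_day_prob[2])
  target_annual <- runif(n, cfg$mean_annual_precip[1], cfg$mean_annual_precip[2])
  # mean annual = 365.25 * p_wet * shape * scale
  scale <- target_annual / (365.25 * p_wet * cfg$gamma_shape)
  tibble::tibble(watershed_id = watersheds$watershed_id,
                 p_wet = p_wet, gamma_scale = scale)
}

#' Generate daily precipitation for one scenario
#'
#' Occurrence-amount (Bernoulli-Gamma) daily precipitation per watershed and
#' climate model. Watershed climatologies are shared across scenarios; each
#' climate model carries a lognormal jitter on the scale parameter; future
#' pathways multiply the wet-day scale by the configured trend factor.
#'
#' @param cfg A [world_config()].
#' @param watersheds Output of [generate_watersheds()].
#' @param scenario `"historical"` or an RCP key (`"rcp26"`, `"rcp45"`,
#'   `"rcp60"`, `"rcp85"`).
#' @param years Integer calendar years to generate (defaults: the historical
#'   + baseline window, or the future period).
#' @return Long tibble `watershed_id`, `model_id`, `scenario_id`, `date`,
#'   `pr_mm`.
#' @export
generate_daily_precip <- function(cfg, watersheds, scenario = "historical",
                                  years = NULL) {
  known <- c("historical", names(cfg$precip_trends))
  if (!scenario %in% known) {
    rn_config_error(paste0("unknown precipitation scenario `", scenario, "`"))
  }
  if (is.null(years)) {
    years <- if (scenario == "historical") {
      min(cfg$years_historical):max(cfg$years_baseline)
    } else {
      cfg$years_future
    }
  }
  trend <- if (scenario == "historical") 1 else cfg$precip_trends[[scenario]]
  n_mod <- if (scenario == "historical") cfg$n_models[["historical"]]
           else cfg$n_models[[scenario]]
  # climate models are shared GCM identities across pathways: an RCP
  # ensemble is a subset of the historical ensemble, so per-model pairing
  # of historical and future runs is well defined
  model_ids <- sprintf("m%02d", seq_len(n_mod))

  pars <- precip_params(cfg, watersheds)
  n_max <- max(cfg$n_models)
  set.seed(seed_for(cfg, "precip_jitter"))
  jitter <- matrix(exp(rnorm(nrow(pars) * n_max, 0, cfg$model_jitter_sd)),
                   nrow(pars), n_max)

  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dyear <- as.integer(format(dates, "%Y"))
  keep <- dyear %in% years
  dates <- dates[keep]
  nd <- length(dates)

  set.seed(seed_for(cfg, "precip_draws", scenario))
  blocks <- vector("list", nrow(pars) * n_mod)
  k <- 0L
  for (m in seq_len(n_mod)) {
    for (w in seq_len(nrow(pars))) {
      k <- k + 1L
      wet <- runif(nd) < pars$p_wet[w]
      amt <- numeric(nd)
      nw <- sum(wet)
      if (nw > 0) {
        amt[wet] <- rgamma(nw, shape = cfg$gamma_shape,
                           scale = pars$gamma_scale[w] * jitter[w, m] * trend)
      }
      blocks[[k]] <- tibble::tibble(
        watershed_id = pars$watershed_id[w],
        model_id = model_ids[m],
        scenario_id = scenario,
        date = dates,
        pr_mm = amt)
    }
  }
  dplyr::bind_rows(blocks)
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate land-use trajectories and crop states for one scenario
#'
#' Six-category land-use fractions per watershed-year, constructed as linear
#' paths through each watershed's 2015 composition so that historical and
#' future segments are continuous at the 2015 junction. Future cropland and
#' developed changes follow the scenario's configured 2100 deltas (with small
#' per-watershed jitter), compensated from forest/grassland/pasture in
#' proportion to available area. Crop states split the cropland fraction
#' across the five crop types with per-watershed weights; fertilizer
#' application rates ramp from a 1976 level to the scenario's 2100 factor.
#'
#' @param cfg A [world_config()].
#' @param watersheds Output of [generate_watersheds()].
#' @param scenario One of the SSP scenario ids, or `"historical"` for the
#'   historical segment only (1976-2015).
#' @return List with `landuse` (tibble `watershed_id`, `year`, one fraction
#'   column per category) and `crops` (tibble `watershed_id`, `year`,
#'   `crop_type`, `area_fraction`, `rate_kg_km2_yr`).
#' @export
generate_landuse <- function(cfg, watersheds, scenario = "historical") {
  if (!scenario %in% c("historical", ssp_ids())) {
    rn_config_error(paste0("unknown land-use scenario `", scenario, "`"))
  }
  n <- nrow(watersheds)
  cats <- lu_categories()

  # 2015 composition and historical drift: shared across scenarios
  set.seed(seed_for(cfg, "landuse_base"))
  alpha <- c(cropland = 8 * cfg$mean_cropland / (1 - cfg$mean_cropland) * 0.75,
             developed = 0.8, pasture = 1.5, forest = 3, grassland = 1.5,
             wetland = 0.4)
  comp2015 <- rdirichlet1(n, alpha)
  colnames(comp2015) <- cats
  hist_drift <- cbind(cropland = rnorm(n, 0.01, 0.01),
                      developed = rnorm(n, 0.008, 0.004))

  # nitrogen-fixing crop weight calibrated so fixation ~ (45/72) * fertilizer
  crop_w <- rdirichlet1(n, c(c3_annual = 6, c4_annual = 5, c3_perennial = 1,
                             c4_perennial = 1, c3_nfix = 3))
  colnames(crop_w) <- crop_types()
  base_rates <- c(c3_annual = 9000, c4_annual = 11000, c3_perennial = 5000,
                  c4_perennial = 6000, c3_nfix = 500)
  rate_jitter <- matrix(exp(rnorm(n * 5, 0, 0.08)), n, 5)
  rates0 <- sweep(rate_jitter, 2, base_rates, "*")
  colnames(rates0) <- crop_types()
  # calibrate the nitrogen-fixing crop weight so the continental
  # fixation/fertilizer ratio matches the target share ratio, accounting for
  # the historical fertilizer-rate ramp and area weighting
  ratio_target <- cfg$nani_shares[["fixation"]] / cfg$nani_shares[["fertilizer"]]
  wa <- watersheds$area_km2 / sum(watersheds$area_km2)
  yh <- cfg$years_historical
  ramp_mean <- mean(0.85 + 0.15 * (yh - min(yh)) / (2015 - min(yh)))
  w0 <- crop_w[, "c3_nfix"]
  other0 <- crop_w[, setdiff(crop_types(), "c3_nfix"), drop = FALSE]
  fert_other <- rowSums(other0 * rates0[, colnames(other0)])
  r_nfix <- rates0[, "c3_nfix"]
  ratio_at <- function(s) {
    wn <- pmin(s * w0, 0.8)
    fert <- ramp_mean * ((1 - wn) / (1 - w0) * fert_other + wn * r_nfix)
    sum(wa * wn * cfg$fixation_rate) / sum(wa * fert) - ratio_target
  }
  s <- stats::uniroot(ratio_at, c(1e-6, 50), tol = 1e-10)$root
  w_nfix <- pmin(s * w0, 0.8)
  other <- other0 * (1 - w_nfix) / rowSums(other0)
  crop_w <- cbind(other, c3_nfix = w_nfix)[, crop_types()]

  hist_years <- min(cfg$years_historical):2015
  if (scenario == "historical") {
    years <- hist_years
    delta <- NULL
  } else {
    years <- min(cfg$years_historical):max(cfg$years_future)
    set.seed(seed_for(cfg, "landuse_future", scenario))
    d <- cfg$landuse_deltas[[scenario]]
    # per-watershed spread proportional to the scenario's target, so a
    # stable archetype is exactly stable
    delta_crop <- rnorm(n, d[["cropland"]], 0.05 * abs(d[["cropland"]]))
    delta_dev <- rnorm(n, d[["developed"]], 0.05 * abs(d[["developed"]]))
    donors <- comp2015[, c("pasture", "forest", "grassland"), drop = FALSE]
    donor_tot <- rowSums(donors)
    need <- delta_crop + delta_dev
    # keep donor categories and targets within [0, 1]
    cap <- pmin(1, ifelse(need > 0, 0.9 * donor_tot / pmax(need, 1e-12), 1))
    delta_crop <- delta_crop * cap
    delta_dev <- delta_dev * cap
    need <- delta_crop + delta_dev
    delta <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
    delta[, "cropland"] <- delta_crop
    delta[, "developed"] <- delta_dev
    delta[, c("pasture", "forest", "grassland")] <-
      -donors / pmax(donor_tot, 1e-12) * need
  }

  frac_at <- function(year) {
    if (year <= 2015) {
      w <- (2015 - year) / (2015 - min(hist_years))
      out <- comp2015
      out[, "cropland"] <- out[, "cropland"] - w * hist_drift[, "cropland"]
      out[, "developed"] <- out[, "developed"] - w * hist_drift[, "developed"]
      out[, "forest"] <- out[, "forest"] +
        w * (hist_drift[, "cropland"] + hist_drift[, "developed"])
      pmax(out, 0) / rowSums(pmax(out, 0))
    } else {
      w <- (year - 2015) / (max(cfg$years_future) - 2015)
      comp2015 + w * delta
    }
  }

  lu_rows <- lapply(years, function(y) {
    f <- frac_at(y)
    tibble::tibble(watershed_id = watersheds$watershed_id, year = y,
                   cropland = f[, "cropland"], developed = f[, "developed"],
                   pasture = f[, "pasture"], forest = f[, "forest"],
                   grassland = f[, "grassland"], wetland = f[, "wetland"])
  })
  landuse <- dplyr::bind_rows(lu_rows)

  rate_factor_at <- function(year) {
    if (year <= 2015) {
      0.85 + 0.15 * (year - min(hist_years)) / (2015 - min(hist_years))
    } else {
      ff <- cfg$fert_rate_factors[[scenario]]
      1 + (ff - 1) * (year - 2015) / (max(cfg$years_future) - 2015)
    }
  }

  crop_rows <- lapply(years, function(y) {
    f <- frac_at(y)
    rf <- rate_factor_at(y)
    tibble::tibble(
      watershed_id = rep(watersheds$watershed_id, times = 5),
      year = y,
      crop_type = rep(crop_types(), each = n),
      area_fraction = as.vector(sweep(crop_w, 1, f[, "cropland"], "*")),
      rate_kg_km2_yr = as.vector(rates0) * rf)
  })
  crops <- dplyr::bind_rows(crop_rows)

  list(landuse = landuse, crops = crops)
}

#' Generate observation-mode NANI components and census tables
#'
#' Builds the five NANI components per watershed-year for the historical
#' record on top of the historical crop states, so that observation-mode and
#' scenario-mode NANI agree up to observational jitter: fertilizer is the
#' area-weighted crop application rate, fixation the nitrogen-fixing crop
#' area times the fixation rate, deposition is levelled so its continental
#' share matches the configured target, net food/feed import follows a known
#' per-HUC2 linear rule in fertilizer and fixation (the recoverable ground
#' truth for the import regression), and nonfood crop export is a small
#' positive term. Census-year subsamples provide the observation-mode inputs
#' for interpolation and regression fitting.
#'
#' @param cfg A [world_config()].
#' @param watersheds Output of [generate_watersheds()].
#' @param crops Historical crop table from [generate_landuse()].
#' @param jitter_sd Lognormal observational jitter on components (0 gives
#'   noiseless tables, e.g. for exact regression recovery tests).
#' @return List with `components` (tibble `watershed_id`, `year`, the five
#'   components and `nani`, kg N km^-2 y^-1), `import_history` (per-HUC2
#'   census tibble for [fit_import_regression()]), `reference_fertilizer`
#'   (per-HUC2 `total_kg` over the 1987-2012 window) and `truth` (the
#'   generating import-rule coefficients and share targets).
#' @export
generate_nani_world <- function(cfg, watersheds, crops, jitter_sd = 0.05) {
  years <- sort(unique(crops$year))
  fert <- fertilizer_usage(crops)
  nfix <- crops |>
    dplyr::filter(.data$crop_type == "c3_nfix") |>
    dplyr::mutate(fixation = .data$area_fraction * cfg$fixation_rate) |>
    dplyr::select("watershed_id", "year", "fixation")
  comp <- dplyr::left_join(fert, nfix, by = c("watershed_id", "year")) |>
    dplyr::rename(fertilizer = "fertilizer_kg_km2_yr") |>
    dplyr::left_join(watersheds[c("watershed_id", "huc2", "area_km2")],
                     by = "watershed_id")

  set.seed(seed_for(cfg, "nani"))
  w_area <- watersheds$area_km2 / sum(watersheds$area_km2)
  mean_fert <- sum(dplyr::filter(comp, .data$year %in% cfg$years_historical) |>
                     dplyr::group_by(.data$watershed_id) |>
                     dplyr::summarise(m = mean(.data$fertilizer),
                                      .groups = "drop") |>
                     dplyr::pull(.data$m) * w_area)
  sh <- cfg$nani_shares
  mean_nani <- mean_fert / sh[["fertilizer"]]

  # deposition: per-watershed level with spatial spread, continental mean
  # hitting the target share; small interannual jitter added below
  dep_level <- mean_nani * sh[["deposition"]] *
    exp(rnorm(nrow(watersheds), 0, 0.25))
  dep_level <- dep_level * (mean_nani * sh[["deposition"]]) /
    sum(dep_level * w_area)
  dep_tbl <- tibble::tibble(watershed_id = watersheds$watershed_id,
                            dep_level = dep_level)

  # import rule: import = a_huc2 + bf * fertilizer + bx * fixation
  huc2s <- sort(unique(watersheds$huc2))
  bf <- -0.25 + rnorm(length(huc2s), 0, 0.02)
  bx <- -0.25 + rnorm(length(huc2s), 0, 0.02)
  mean_fix <- sum(dplyr::filter(comp, .data$year %in% cfg$years_historical) |>
                    dplyr::group_by(.data$watershed_id) |>
                    dplyr::summarise(m = mean(.data$fixation),
                                     .groups = "drop") |>
                    dplyr::pull(.data$m) * w_area)
  a <- mean_nani * sh[["food_feed_import"]] -
    mean(bf) * mean_fert - mean(bx) * mean_fix + rnorm(length(huc2s), 0, 10)
  import_rule <- tibble::tibble(huc2 = huc2s, intercept = a,
                                slope_fertilizer = bf, slope_fixation = bx)

  nonfood_level <- mean_nani * sh[["nonfood_crop_export"]] *
    exp(rnorm(nrow(watersheds), 0, 0.2))
  nonfood_tbl <- tibble::tibble(watershed_id = watersheds$watershed_id,
                                nonfood_level = nonfood_level)

  jit <- function(k) exp(rnorm(k, 0, jitter_sd))
  comp <- comp |>
    dplyr::left_join(dep_tbl, by = "watershed_id") |>
    dplyr::left_join(nonfood_tbl, by = "watershed_id") |>
    dplyr::left_join(import_rule, by = "huc2")
  nr <- nrow(comp)
  comp <- comp |>
    dplyr::mutate(
      fertilizer = .data$fertilizer * jit(nr),
      fixation = .data$fixation * jit(nr),
      deposition = .data$dep_level * jit(nr),
      food_feed_import = .data$intercept +
        .data$slope_fertilizer * .data$fertilizer +
        .data$slope_fixation * .data$fixation,
      nonfood_crop_export = .data$nonfood_level * jit(nr),
      nani = assemble_nani(.data$fertilizer, .data$fixation, .data$deposition,
                           .data$food_feed_import, .data$nonfood_crop_export))

  components <- comp[c("watershed_id", "year", "fertilizer", "fixation",
                       "deposition", "food_feed_import",
                       "nonfood_crop_export", "nani")]

  census <- comp |>
    dplyr::filter(.data$year %in% cfg$census_years) |>
    dplyr::group_by(.data$huc2, .data$year) |>
    dplyr::summarise(
      import_kg_km2_yr = sum(.data$food_feed_import * .data$area_km2) /
        sum(.data$area_km2),
      fertilizer_kg_km2_yr = sum(.data$fertilizer * .data$area_km2) /
        sum(.data$area_km2),
      fixation_kg_km2_yr = sum(.data$fixation * .data$area_km2) /
        sum(.data$area_km2),
      .groups = "drop")

  ref_fert <- comp |>
    dplyr::filter(.data$year %in% 1987:2012) |>
    dplyr::group_by(.data$huc2) |>
    dplyr::summarise(total_kg = sum(.data$fertilizer * .data$area_km2),
                     .groups = "drop")

  list(components = components,
       import_history = census,
       reference_fertilizer = ref_fert,
       truth = list(import_rule = import_rule, shares = sh,
                    mean_nani = mean_nani))
}

#' Generate a synthetic calibration dataset
#'
#' Draws catchment-year predictor records over realistic ranges and
#' constructs the observed TN flux as the generating log-linear model plus
#' ln-scale Gaussian noise. When `noise_sd` is `NULL` it is set from the
#' sample signal variance so the population R^2 equals
#' `cfg$r_squared_target`.
#'
#' @param cfg A [world_config()].
#' @param n Number of catchment-year records (default `cfg$n_calibration`).
#' @param noise_sd ln-scale noise SD; `NULL` to derive from the R^2 target,
#'   0 for noiseless data.
#' @param seed Optional seed overriding the config-derived stream (used for
#'   replicate draws).
#' @return List with `data` (calibration tibble in the canonical CSV schema)
#'   and `truth` (generating coefficients, noise SD, land-use subset).
#' @export
generate_calibration_dataset <- function(cfg, n = cfg$n_calibration,
                                         noise_sd = NULL, seed = NULL) {
  set.seed(seed %||% seed_for(cfg, "calibration"))
  nani <- stats::rlnorm(n, log(4000), 0.7) - 300
  p_annual <- runif(n, 600, 1600)
  p_mam_ext <- p_annual * stats::rbeta(n, 2, 12)
  lu <- rdirichlet1(n, c(cropland = 2, developed = 0.8, pasture = 1.5,
                         forest = 3, grassland = 1.5, wetland = 0.4)) * 100
  colnames(lu) <- lu_categories()
  lu_dc <- lu[, "cropland"] + lu[, "developed"]
  lp <- predict_ln_tn(
    data.frame(nani = nani, p_annual = p_annual, p_mam_ext = p_mam_ext,
               lu_dc = lu_dc),
    cfg$coefficients)
  if (is.null(noise_sd)) {
    r2 <- cfg$r_squared_target
    noise_sd <- stats::sd(lp) * sqrt((1 - r2) / r2)
  }
  y <- lp + rnorm(n, 0, noise_sd)
  data <- tibble::tibble(
    catchment_id = sprintf("C%04d", seq_len(n)),
    year = rep_len(2001:2012, n),
    tn_flux_kg_km2_yr = exp(y),
    nani_kg_km2_yr = nani,
    p_annual_mm = p_annual,
    p_mam_ext_mm = p_mam_ext)
  for (cat in lu_categories()) data[[lu_col(cat)]] <- lu[, cat]
  list(data = data,
       truth = list(coefficients = cfg$coefficients, noise_sd = noise_sd,
                    lu_subset = c("cropland", "developed")))
}

#' Generate a complete synthetic world
#'
#' Bundles watersheds, regions, land-use and crop trajectories (historical
#' plus the requested SSP scenarios), daily precipitation (historical plus
#' the RCP pathways paired to the requested scenarios), reduced
#' precipitation features, observation-mode NANI components, the import
#' regression history, reference fertilizer totals, and deposition pathways
#' into the input structure consumed by [run_projection()].
#'
#' @param cfg A [world_config()].
#' @param scenarios SSP scenario ids to include (default: all six).
#' @param precip_years_historical,precip_years_future Years of daily
#'   precipitation to generate (defaults: historical period + baseline
#'   window, and the future period).
#' @return A list of class `tn_world`; see [scenario_inputs()] for the
#'   projection-facing fields.
#' @export
generate_world <- function(cfg, scenarios = ssp_ids(),
                           precip_years_historical = NULL,
                           precip_years_future = NULL) {
  bad <- setdiff(scenarios, ssp_ids())
  if (length(bad)) {
    rn_config_error(paste0("unknown scenario id(s): ", paste(bad, collapse = ", ")))
  }
  watersheds <- generate_watersheds(cfg)
  regions <- regions_from_watersheds(watersheds)

  lu <- list(historical = generate_landuse(cfg, watersheds, "historical"))
  for (s in scenarios) lu[[s]] <- generate_landuse(cfg, watersheds, s)

  hist_years <- precip_years_historical %||%
    (min(cfg$years_historical):max(cfg$years_baseline))
  fut_years <- precip_years_future %||% cfg$years_future
  precip <- list(historical = generate_daily_precip(cfg, watersheds,
                                                    "historical", hist_years))
  rcps <- unique(vapply(scenarios, function(s) rcp_key(pair_rcp(s)), ""))
  for (r in rcps) {
    precip[[r]] <- generate_daily_precip(cfg, watersheds, r, fut_years)
  }

  features <- list(
    historical = precip_features(precip$historical,
                                 baseline = cfg$years_baseline))
  for (r in rcps) {
    features[[r]] <- precip_features(
      precip[[r]], baseline_precip = precip$historical,
      baseline = cfg$years_baseline)
  }

  nani <- generate_nani_world(cfg, watersheds, lu$historical$crops)

  # deposition pathways: observation-mode deposition historically, ramping
  # to the configured RCP factor by 2100
  dep_hist <- nani$components[c("watershed_id", "year")]
  dep_hist$dep_kg_km2_yr <- nani$components$deposition
  deposition <- list(historical = dep_hist)
  dep2015 <- dep_hist |>
    dplyr::filter(.data$year == max(.data$year)) |>
    dplyr::select("watershed_id", dep0 = "dep_kg_km2_yr")
  y0 <- max(dep_hist$year)
  for (r in rcps) {
    f100 <- cfg$dep_factors[[r]]
    rows <- lapply(fut_years, function(y) {
      w <- (y - y0) / (max(cfg$years_future) - y0)
      tibble::tibble(watershed_id = dep2015$watershed_id, year = y,
                     dep_kg_km2_yr = dep2015$dep0 * (1 + (f100 - 1) * w))
    })
    deposition[[r]] <- dplyr::bind_rows(rows)
  }

  nonfood <- nani$components[c("watershed_id", "year")]
  nonfood$value_kg_km2_yr <- nani$components$nonfood_crop_export

  import_model <- fit_import_regression(nani$import_history)

  structure(list(
    config = cfg,
    watersheds = watersheds,
    regions = regions,
    landuse = lu,
    precip = precip,
    precip_features = features,
    components = nani$components,
    import_history = nani$import_history,
    import_model = import_model,
    reference_fertilizer = nani$reference_fertilizer,
    deposition = deposition,
    nonfood = nonfood,
    truth = nani$truth
  ), class = "tn_world")
}

#' @export
print.tn_world <- function(x, ...) {
  cat(sprintf("Synthetic TN world: %d watersheds, %d HUC2 regions, seed %d\n",
              nrow(x$watersheds), length(unique(x$watersheds$huc2)),
              x$config$seed))
  cat("  scenarios:", paste(setdiff(names(x$landuse), "historical"),
                            collapse = ", "), "\n")
  cat("  precipitation pathways:", paste(names(x$precip), collapse = ", "), "\n")
  invisible(x)
}
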