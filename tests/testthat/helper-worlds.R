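# Hand-built minimal worlds for scenario-engine tests, with closed-form
# expected fluxes computable by direct arithmetic.

# One watershed, constant drivers; future scenario optionally changes
# cropland/developed fractions and fertilizer rates.
tiny_world <- function(crop = 0.15, dev = 0.10,
                       fut_crop = crop, fut_dev = dev, fut_rate_mult = 1,
                       p_annual = 1000, p_mam = 100,
                       fut_p_annual = p_annual, fut_p_mam = p_mam,
                       dep = 300, nonfood = 10,
                       n_models = 1,
                       hist_years = 2001:2003, fut_years = 2091:2093,
                       ssp = "SSP4-3.4") {
  ws <- tibble::tibble(watershed_id = "W1", huc2 = "H01", area_km2 = 10,
                       in_marb = TRUE, in_northeast = FALSE)
  cats <- c("cropland", "developed", "pasture", "forest", "grassland",
            "wetland")
  lu_row <- function(cr, dv, years) {
    rest <- (1 - cr - dv) / 4
    tibble::tibble(watershed_id = "W1", year = years, cropland = cr,
                   developed = dv, pasture = rest, forest = rest,
                   grassland = rest, wetland = rest)
  }
  # crop states: one fertilized annual crop + the nitrogen-fixing crop
  crops_row <- function(cr, rate_mult, years) {
    dplyr::bind_rows(lapply(years, function(y) {
      tibble::tibble(
        watershed_id = "W1", year = y,
        crop_type = c("c3_annual", "c4_annual", "c3_perennial",
                      "c4_perennial", "c3_nfix"),
        area_fraction = cr * c(0.6, 0, 0, 0, 0.4),
        rate_kg_km2_yr = c(10000 * rate_mult, 0, 0, 0, 0))
    }))
  }
  models <- sprintf("m%02d", seq_len(n_models))
  feats <- function(years, pa, pm) {
    tidyr::expand_grid(watershed_id = "W1", model_id = models,
                       year = years) |>
      dplyr::mutate(p_annual_mm = pa, p_mam_ext_mm = pm)
  }
  dep_tbl <- function(years) {
    tibble::tibble(watershed_id = "W1", year = years, dep_kg_km2_yr = dep)
  }
  # noiseless import rule: import = 500 - 0.3 F - 0.1 Fx
  hist_imp <- tidyr::expand_grid(huc2 = "H01",
                                 year = c(1987, 1992, 1997, 2002)) |>
    dplyr::mutate(fertilizer_kg_km2_yr = c(800, 900, 1000, 1100),
                  fixation_kg_km2_yr = c(400, 420, 380, 440),
                  import_kg_km2_yr = 500 - 0.3 * fertilizer_kg_km2_yr -
                    0.1 * fixation_kg_km2_yr)
  import_model <- rivertn::fit_import_regression(hist_imp)

  nonfood_tbl <- tibble::tibble(watershed_id = "W1",
                                year = c(hist_years, 2007),
                                value_kg_km2_yr = nonfood)
  nonfood_tbl <- nonfood_tbl[!duplicated(nonfood_tbl$year), ]

  world <- list(
    watersheds = ws,
    regions = tibble::tibble(region_id = c("CONUS", "MARB"),
                             watershed_id = "W1"),
    landuse = list(
      historical = list(landuse = lu_row(crop, dev, hist_years),
                        crops = crops_row(crop, 1, hist_years)),
      list(landuse = lu_row(fut_crop, fut_dev, fut_years),
           crops = crops_row(fut_crop, fut_rate_mult, fut_years))),
    precip_features = list(
      historical = feats(hist_years, p_annual, p_mam),
      rcp26 = feats(fut_years, fut_p_annual, fut_p_mam)),
    deposition = list(historical = dep_tbl(hist_years),
                      rcp26 = dep_tbl(fut_years)),
    nonfood = nonfood_tbl,
    import_model = import_model,
    fixation_rate = 14300,
    hist_years = hist_years,
    future_years = fut_years)
  names(world$landuse)[2] <- ssp
  world
}

# closed-form flux for the tiny world's driver settings (Eq.-style arithmetic)
tiny_expected_flux <- function(crop, dev, rate_mult = 1,
                               p_annual = 1000, p_mam = 100,
                               dep = 300, nonfood = 10,
                               coefficients = rivertn::tn_coefficients()) {
  fert <- crop * 0.6 * 10000 * rate_mult
  fix <- crop * 0.4 * 14300
  imp <- 500 - 0.3 * fert - 0.1 * fix
  nani <- fert + fix + dep + imp - nonfood
  lu_dc <- 100 * (crop + dev)
  lnq <- coefficients[["intercept"]] +
    coefficients[["f_nani"]] * asinh(nani / 2) +
    coefficients[["p_annual"]] * p_annual +
    coefficients[["p_mam_ext"]] * p_mam +
    coefficients[["lu_dc"]] * lu_dc
  exp(lnq)
}

# small generated world shared by io/e2e tests (kept tiny for speed)
small_cfg <- function(seed = 42, ...) {
  args <- list(
    seed = seed, n_watersheds = 12, n_huc2 = 3,
    n_models = c(historical = 3, rcp26 = 3, rcp45 = 3, rcp60 = 3, rcp85 = 3),
    years_historical = 1976:1987, years_baseline = 1980:1987,
    years_future = 2089:2100)
  over <- list(...)
  args[names(over)] <- over
  do.call(rivertn::world_config, args)
}
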