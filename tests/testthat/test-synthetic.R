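test_that("watershed generation is seeded, positive-area and region-disjoint", {
  cfg <- small_cfg()
  a <- generate_watersheds(cfg)
  b <- generate_watersheds(cfg)
  expect_identical(a, b)
  expect_true(all(a$area_km2 > 0))
  expect_false(any(a$in_marb & a$in_northeast))
  regions <- regions_from_watersheds(a)
  expect_setequal(unique(regions$region_id), c("CONUS", "MARB", "Northeast"))
  expect_setequal(regions$watershed_id[regions$region_id == "CONUS"],
                  a$watershed_id)
})

test_that("daily precipitation honours occurrence and scaling parameters", {
  cfg_dry <- small_cfg(wet_day_prob = c(0, 0))
  ws <- generate_watersheds(cfg_dry)[1:3, ]
  dry <- generate_daily_precip(cfg_dry, ws, "historical", years = 1981:1982)
  expect_true(all(dry$pr_mm == 0))

  cfg1 <- small_cfg(mean_annual_precip = c(700, 700))
  cfg2 <- small_cfg(mean_annual_precip = c(1400, 1400))
  ws1 <- generate_watersheds(cfg1)[1:4, ]
  p1 <- generate_daily_precip(cfg1, ws1, "historical", years = 1981:1990)
  p2 <- generate_daily_precip(cfg2, ws1, "historical", years = 1981:1990)
  r <- sum(p2$pr_mm) / sum(p1$pr_mm)
  expect_equal(r, 2, tolerance = 0.05)

  expect_error(generate_daily_precip(cfg1, ws1, "rcp99"),
               class = "rivertn_config_error")
})

test_that("a unit trend factor leaves future precipitation distributionally null", {
  cfg <- small_cfg(seed = 61, precip_trends = list(rcp26 = 1, rcp45 = 1.05,
                                                   rcp60 = 1.07, rcp85 = 1.12))
  ws <- generate_watersheds(cfg)[1:3, ]
  hist <- generate_daily_precip(cfg, ws, "historical", years = 1981:1990)
  fut <- generate_daily_precip(cfg, ws, "rcp26", years = 2091:2100)
  wet_h <- hist$pr_mm[hist$pr_mm > 0]
  wet_f <- fut$pr_mm[fut$pr_mm > 0]
  set.seed(1)
  ks <- suppressWarnings(stats::ks.test(sample(wet_h, 2000),
                                        sample(wet_f, 2000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("land-use trajectories sum to one and join smoothly at 2015", {
  cfg <- small_cfg()
  ws <- generate_watersheds(cfg)
  hist <- generate_landuse(cfg, ws, "historical")
  fut <- generate_landuse(cfg, ws, "SSP4-3.4")
  cats <- c("cropland", "developed", "pasture", "forest", "grassland",
            "wetland")
  frac <- as.matrix(fut$landuse[cats])
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(rowSums(frac), rep(1, nrow(frac)), tolerance = 1e-9)
  h15 <- hist$landuse[hist$landuse$year == 2015, ]
  f15 <- fut$landuse[fut$landuse$year == 2015, ]
  expect_lt(max(abs(as.matrix(h15[cats]) - as.matrix(f15[cats]))), 1e-6)

  # expansion archetype reaches its configured 2100 cropland delta
  f00 <- fut$landuse[fut$landuse$year == 2100, ]
  delta <- mean(f00$cropland - f15$cropland)
  expect_lt(abs(delta - 0.10), 0.005)

  # a zero-delta scenario keeps 2100 equal to 2015
  cfg_flat <- small_cfg(landuse_deltas = list(
    "SSP2-4.5" = c(cropland = 0, developed = 0)))
  flat <- generate_landuse(cfg_flat, generate_watersheds(cfg_flat), "SSP2-4.5")
  s15 <- flat$landuse[flat$landuse$year == 2015, cats]
  s00 <- flat$landuse[flat$landuse$year == 2100, cats]
  expect_lt(max(abs(as.matrix(s15) - as.matrix(s00))), 1e-3)

  # crop areas partition the cropland fraction
  ca <- stats::aggregate(area_fraction ~ watershed_id + year,
                         data = fut$crops, FUN = sum)
  ca <- merge(ca, fut$landuse[c("watershed_id", "year", "cropland")])
  expect_equal(ca$area_fraction, ca$cropland, tolerance = 1e-9)
})

test_that("synthetic NANI reproduces the historical component shares", {
  cfg <- small_cfg(seed = 62, n_watersheds = 30)
  ws <- generate_watersheds(cfg)
  crops <- generate_landuse(cfg, ws, "historical")$crops
  nani <- generate_nani_world(cfg, ws, crops)
  co <- nani$components[nani$components$year %in% cfg$years_historical, ]
  wa <- ws$area_km2[match(co$watershed_id, ws$watershed_id)]
  share <- function(v) sum(co[[v]] * wa) / sum(co$nani * wa)
  # continental mean shares within 3 percentage points of the targets
  expect_lt(abs(share("fertilizer") - 0.72), 0.03)
  expect_lt(abs(share("fixation") - 0.45), 0.03)
  expect_lt(abs(share("deposition") - 0.14), 0.03)
  expect_lt(abs(share("food_feed_import") + 0.30), 0.03)
  expect_lt(abs(share("nonfood_crop_export") - 0.0078), 0.003)
  # the identity NANI = F + Fx + D + I - E holds row-wise
  expect_equal(co$nani,
               co$fertilizer + co$fixation + co$deposition +
                 co$food_feed_import - co$nonfood_crop_export,
               tolerance = 1e-9)
})

test_that("noiseless census tables return the generating import rule", {
  cfg <- small_cfg(seed = 63)
  ws <- generate_watersheds(cfg)
  crops <- generate_landuse(cfg, ws, "historical")$crops
  nani <- generate_nani_world(cfg, ws, crops, jitter_sd = 0)
  fit <- fit_import_regression(nani$import_history)
  truth <- nani$truth$import_rule
  got <- fit$coefficients[order(fit$coefficients$huc2), ]
  expect_equal(got$slope_fertilizer, truth$slope_fertilizer, tolerance = 1e-6)
  expect_equal(got$slope_fixation, truth$slope_fixation, tolerance = 1e-6)
  expect_equal(got$intercept, truth$intercept, tolerance = 1e-4)
})

test_that("calibration data are seeded-deterministic with controllable R^2", {
  cfg <- small_cfg(seed = 64)
  a <- generate_calibration_dataset(cfg)
  b <- generate_calibration_dataset(cfg)
  expect_identical(a$data, b$data)
  r2 <- vapply(1:8, function(i) {
    calibrate_tn_model(
      generate_calibration_dataset(cfg, seed = 400 + i)$data)$r_squared
  }, numeric(1))
  expect_equal(mean(r2), 0.67, tolerance = 0.05)
})

test_that("whole generated worlds are deterministic and internally consistent", {
  cfg <- small_cfg(seed = 65, n_watersheds = 6,
                   n_models = c(historical = 2, rcp26 = 2, rcp45 = 2,
                                rcp60 = 2, rcp85 = 2))
  w1 <- generate_world(cfg, scenarios = "SSP4-3.4")
  w2 <- generate_world(cfg, scenarios = "SSP4-3.4")
  expect_identical(w1$precip_features, w2$precip_features)
  expect_identical(w1$components, w2$components)
  # every watershed-year-model needed downstream is present
  feats <- w1$precip_features$historical
  expect_equal(nrow(feats),
               6 * 2 * length(min(cfg$years_historical):max(cfg$years_baseline)))
  expect_true(all(feats$p_annual_mm >= feats$p_mam_ext_mm))
  expect_true(all(feats$p_mam_ext_mm >= 0))
})
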