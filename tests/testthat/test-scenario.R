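test_that("SSP scenarios pair with the fixed RCP table", {
  expect_identical(pair_rcp("SSP1-2.6"), "RCP2.6")
  expect_identical(pair_rcp("SSP2-4.5"), "RCP4.5")
  expect_identical(pair_rcp("SSP4-6.0"), "RCP6.0")
  expect_identical(pair_rcp("SSP5-8.5"), "RCP8.5")
  expect_identical(pair_rcp("SSP4-3.4"), "RCP2.6")
  expect_identical(pair_rcp("SSP3-7.0"), "RCP8.5")
  expect_error(pair_rcp("SSP9-1.9"), class = "rivertn_config_error")
})

test_that("projection matches closed-form arithmetic on a constant world", {
  w <- tiny_world(crop = 0.15, dev = 0.10, fut_crop = 0.25, fut_dev = 0.10)
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical")
  hist <- run_projection(spec, w, w$hist_years)
  fut <- run_projection(spec, w, w$future_years)
  expect_equal(unique(hist$flux_kg_km2_yr),
               tiny_expected_flux(0.15, 0.10), tolerance = 1e-12)
  expect_equal(unique(fut$flux_kg_km2_yr),
               tiny_expected_flux(0.25, 0.10), tolerance = 1e-12)
  expect_setequal(names(fut),
                  c("watershed_id", "model_id", "year", "flux_kg_km2_yr"))
  expect_true(all(fut$flux_kg_km2_yr > 0))
})

test_that("an all-historical configuration reproduces the historical baseline", {
  w <- tiny_world(fut_crop = 0.3, fut_rate_mult = 1.5)
  id_spec <- scenario_spec("SSP4-3.4", precipitation = "historical",
                           cropland = "historical", developed = "historical",
                           fertilizer_rate = "historical")
  hist <- run_projection(id_spec, w, w$hist_years)
  fut <- run_projection(id_spec, w, w$future_years)
  expect_equal(fut$flux_kg_km2_yr, hist$flux_kg_km2_yr, tolerance = 1e-12)
})

test_that("doubling developed+cropland cover multiplies flux by exp(b4*25)", {
  # same NANI in both runs: land-use change enters only via LU_D,C
  w25 <- tiny_world(crop = 0.15, dev = 0.10, fut_crop = 0.15, fut_dev = 0.35)
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical",
                        cropland = "historical", developed = "future",
                        fertilizer_rate = "historical")
  hist <- run_projection(spec, w25, w25$hist_years)
  fut <- run_projection(spec, w25, w25$future_years)
  ratio <- unique(fut$flux_kg_km2_yr) / unique(hist$flux_kg_km2_yr)
  expect_equal(ratio, exp(0.0213 * 25), tolerance = 1e-12)
  expect_equal(ratio, 1.703, tolerance = 1e-3)
})

test_that("projection is deterministic and per-model-identical for identical precip", {
  w <- tiny_world(n_models = 2, fut_crop = 0.3)
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical")
  a <- run_projection(spec, w)
  b <- run_projection(spec, w)
  expect_identical(a, b)
  wide <- tidyr::pivot_wider(a, names_from = "model_id",
                             values_from = "flux_kg_km2_yr")
  expect_identical(wide$m01, wide$m02)
})

test_that("a pure LU_D,C increase never decreases flux", {
  w <- tiny_world(crop = 0.15, dev = 0.10, fut_crop = 0.15, fut_dev = 0.22)
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical",
                        cropland = "historical", developed = "future",
                        fertilizer_rate = "historical")
  hist <- run_projection(spec, w, w$hist_years)
  fut <- run_projection(spec, w, w$future_years)
  expect_true(all(fut$flux_kg_km2_yr >= hist$flux_kg_km2_yr))
})

test_that("missing inputs are reported with the offending key", {
  w <- tiny_world()
  w$precip_features$historical <-
    w$precip_features$historical[w$precip_features$historical$year != 2002, ]
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical")
  expect_error(run_projection(spec, w, w$hist_years), "2002",
               class = "rivertn_missing_input")
  w2 <- tiny_world()
  w2$precip_features$rcp26 <- NULL
  expect_error(
    run_projection(scenario_spec("SSP4-3.4", precipitation = "paired-rcp"),
                   w2, w2$future_years),
    "RCP2.6", class = "rivertn_missing_input")
})

test_that("decomposition runs flip exactly one factor each", {
  w <- tiny_world(crop = 0.15, dev = 0.10, fut_crop = 0.25, fut_dev = 0.14,
                  fut_rate_mult = 1.4)
  spec <- scenario_spec("SSP4-3.4", precipitation = "historical")
  dec <- decomposition_runs(spec, w)
  expect_named(dec, c("historical", "baseline", "combined", "cropland",
                      "developed", "fertilizer_rate"))
  val <- function(f) unique(f$flux_kg_km2_yr)
  expect_equal(val(dec$combined),
               tiny_expected_flux(0.25, 0.14, 1.4), tolerance = 1e-12)
  expect_equal(val(dec$cropland),
               tiny_expected_flux(0.25, 0.10, 1), tolerance = 1e-12)
  expect_equal(val(dec$developed),
               tiny_expected_flux(0.15, 0.14, 1), tolerance = 1e-12)
  expect_equal(val(dec$fertilizer_rate),
               tiny_expected_flux(0.15, 0.10, 1.4), tolerance = 1e-12)
  expect_equal(val(dec$baseline), tiny_expected_flux(0.15, 0.10, 1),
               tolerance = 1e-12)

  # no factor differs -> all runs coincide
  w0 <- tiny_world(fut_crop = 0.15, fut_dev = 0.10, fut_rate_mult = 1)
  dec0 <- decomposition_runs(spec, w0)
  for (nm in c("combined", "cropland", "developed", "fertilizer_rate")) {
    expect_equal(val(dec0[[nm]]), val(dec0$baseline), tolerance = 1e-12)
  }
  expect_error(
    decomposition_runs(scenario_spec("SSP4-3.4",
                                     precipitation = "paired-rcp"), w),
    class = "rivertn_config_error")
})

test_that("single-factor deltas are non-additive at finite perturbations", {
  w <- tiny_world(crop = 0.15, dev = 0.10, fut_crop = 0.25, fut_dev = 0.14,
                  fut_rate_mult = 1.4)
  dec <- decomposition_runs(
    scenario_spec("SSP4-3.4", precipitation = "historical"), w)
  val <- function(f) unique(f$flux_kg_km2_yr)
  base <- val(dec$baseline)
  d_comb <- val(dec$combined) - base
  d_sum <- (val(dec$cropland) - base) + (val(dec$developed) - base) +
    (val(dec$fertilizer_rate) - base)
  # brute-force interaction from the closed form
  expected_interaction <-
    (tiny_expected_flux(0.25, 0.14, 1.4) - tiny_expected_flux(0.15, 0.10, 1)) -
    ((tiny_expected_flux(0.25, 0.10, 1) - tiny_expected_flux(0.15, 0.10, 1)) +
     (tiny_expected_flux(0.15, 0.14, 1) - tiny_expected_flux(0.15, 0.10, 1)) +
     (tiny_expected_flux(0.15, 0.10, 1.4) - tiny_expected_flux(0.15, 0.10, 1)))
  expect_equal(d_comb - d_sum, expected_interaction, tolerance = 1e-10)
  expect_gt(abs(d_comb - d_sum), 1e-6)
})

test_that("period means average 30 annual values per watershed-model", {
  f <- tidyr::expand_grid(watershed_id = "W1", model_id = "m01",
                          year = 1976:2005)
  f$flux_kg_km2_yr <- 100
  expect_equal(period_mean(f, c(1976, 2005))$mean_flux_kg_km2_yr, 100)
  f$flux_kg_km2_yr <- 1:30
  expect_equal(period_mean(f, c(1976, 2005))$mean_flux_kg_km2_yr, 15.5)
  expect_error(period_mean(f[-4, ], c(1976, 2005)),
               class = "rivertn_missing_input")
})
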