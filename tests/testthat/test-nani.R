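test_that("NANI assembly applies the signed five-component sum", {
  expect_identical(assemble_nani(7200, 4500, 1400, -3000, 78), 10022)
  expect_identical(assemble_nani(0, 0, 0, 0, 0), 0)
  expect_identical(assemble_nani(0, 0, 0, -100, 0), -100)
  # linearity / permutation of the additive components
  expect_equal(assemble_nani(10, 20, 30, -5, 2),
               assemble_nani(30, 10, 20, -5, 2))
  expect_equal(assemble_nani(2 * 10, 2 * 20, 2 * 30, 2 * -5, 2 * 2),
               2 * assemble_nani(10, 20, 30, -5, 2))
  expect_error(assemble_nani(-1, 0, 0, 0, 0), class = "rivertn_invalid_input")
  expect_error(assemble_nani(0, 0, NA, 0, 0), class = "rivertn_invalid_input")
})

test_that("fertilizer usage is the area-weighted rate sum", {
  one <- data.frame(crop_type = "c3_annual", area_fraction = 0.5,
                    rate_kg_km2_yr = 10000)
  expect_equal(fertilizer_usage(one), 5000)
  two <- data.frame(crop_type = c("c3_annual", "c4_annual"),
                    area_fraction = c(0.2, 0.3),
                    rate_kg_km2_yr = c(5000, 10000))
  expect_equal(fertilizer_usage(two), 4000)
  zero <- data.frame(crop_type = "c3_annual", area_fraction = 0,
                     rate_kg_km2_yr = 10000)
  expect_equal(fertilizer_usage(zero), 0)
  grp <- data.frame(watershed_id = c("A", "A", "B"), year = 2000,
                    crop_type = c("c3_annual", "c4_annual", "c3_annual"),
                    area_fraction = c(0.2, 0.3, 0.5),
                    rate_kg_km2_yr = c(5000, 10000, 10000))
  out <- fertilizer_usage(grp)
  expect_equal(out$fertilizer_kg_km2_yr, c(4000, 5000))
  expect_error(fertilizer_usage(data.frame(crop_type = "x",
                                           area_fraction = 1.5,
                                           rate_kg_km2_yr = 1)),
               class = "rivertn_invalid_input")
})

test_that("fertilizer rescaling matches reference HUC2 window totals exactly", {
  ws <- data.frame(watershed_id = c("W1", "W2"), huc2 = "H01",
                   area_km2 = c(1, 2))
  series <- tidyr::expand_grid(watershed_id = c("W1", "W2"),
                               year = c(1987:2012, 2050))
  series$value_kg_km2_yr <- ifelse(series$watershed_id == "W1", 1, 0.5)
  series$value_kg_km2_yr[series$year == 2050] <- 18
  # window total = 26 * (1*1 + 0.5*2) = 52; reference chosen for factor 10/9
  ref <- data.frame(huc2 = "H01", total_kg = 52 * 10 / 9)
  out <- scale_fertilizer_to_reference(series, ws, ref)
  expect_equal(attr(out, "factors")$factor, 10 / 9, tolerance = 1e-12)
  expect_equal(out$value_kg_km2_yr[out$year == 2050], c(20, 20),
               tolerance = 1e-12)
  scaled_total <- sum(out$value_kg_km2_yr[out$year %in% 1987:2012] *
                        ifelse(out$watershed_id[out$year %in% 1987:2012] == "W1",
                               1, 2))
  expect_equal(scaled_total, ref$total_kg, tolerance = 1e-9 * ref$total_kg)

  # identity and zero/zero conventions
  ref_id <- data.frame(huc2 = "H01", total_kg = 52)
  out_id <- scale_fertilizer_to_reference(series, ws, ref_id)
  expect_equal(out_id$value_kg_km2_yr, series$value_kg_km2_yr,
               tolerance = 1e-12)
  z <- series
  z$value_kg_km2_yr <- 0
  out_z <- scale_fertilizer_to_reference(z, ws, data.frame(huc2 = "H01",
                                                           total_kg = 0))
  expect_equal(attr(out_z, "factors")$factor, 1)
  expect_error(
    scale_fertilizer_to_reference(z, ws, data.frame(huc2 = "H01",
                                                    total_kg = 5)),
    class = "rivertn_unscalable_region")
})

test_that("fixation rate and area are mutually consistent", {
  expect_equal(fixation_from_area(1), 14300)
  expect_equal(fixation_from_area(0), 0)
  # the printed pair: 6.9 Tg N at 14,300 kg N km^-2 y^-1 implies ~482,518 km^2
  implied_area <- 6.9e9 / 14300
  expect_equal(implied_area, 482517.5, tolerance = 1e-6)
  expect_equal(fixation_from_area(implied_area), 6.9e9, tolerance = 1e-9)

  areas <- implied_area * c(0.4, 0.35, 0.25)
  rate <- calibrate_fixation_rate(areas, 6.9e9)
  expect_equal(rate, 14300, tolerance = 1e-9)
  expect_equal(sum(fixation_from_area(areas, rate)), 6.9e9,
               tolerance = 1e-12)
  expect_equal(calibrate_fixation_rate(1, 5), 5)
  expect_equal(calibrate_fixation_rate(2 * areas, 6.9e9), rate / 2,
               tolerance = 1e-12)
  expect_error(calibrate_fixation_rate(numeric(0), 1),
               class = "rivertn_invalid_input")
  expect_error(calibrate_fixation_rate(c(0, 0), 1),
               class = "rivertn_invalid_input")
})

test_that("import regression recovers a noiseless linear rule", {
  hist <- tidyr::expand_grid(huc2 = c("H01", "H02"),
                             year = c(1987, 1992, 1997, 2002, 2007, 2012))
  set.seed(4)
  hist$fertilizer_kg_km2_yr <- runif(nrow(hist), 500, 2000)
  hist$fixation_kg_km2_yr <- runif(nrow(hist), 200, 900)
  hist$import_kg_km2_yr <- 500 - 0.3 * hist$fertilizer_kg_km2_yr -
    0.1 * hist$fixation_kg_km2_yr
  fit <- fit_import_regression(hist)
  expect_equal(fit$coefficients$intercept, c(500, 500), tolerance = 1e-8)
  expect_equal(fit$coefficients$slope_fertilizer, c(-0.3, -0.3),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$slope_fixation, c(-0.1, -0.1),
               tolerance = 1e-10)
  expect_equal(predict_import(fit, "H01", 1000, 500), 150, tolerance = 1e-8)

  flat <- hist
  flat$fertilizer_kg_km2_yr <- 1000
  expect_error(fit_import_regression(flat),
               class = "rivertn_degenerate_design")
  expect_error(fit_import_regression(hist[hist$year < 2000, ]),
               class = "rivertn_invalid_input")
  expect_error(predict_import(fit, "H99", 1, 1),
               class = "rivertn_missing_input")
})

test_that("deposition scaling uses the overlap-mean ratio per watershed", {
  model <- data.frame(watershed_id = "W1", year = c(2002:2006, 2050),
                      dep_kg_km2_yr = c(rep(8, 5), 6))
  ref <- data.frame(watershed_id = "W1", year = 2002:2006,
                    dep_kg_km2_yr = 10)
  out <- scale_deposition(model, ref)
  expect_equal(attr(out, "factors")$factor, 1.25)
  expect_equal(out$dep_kg_km2_yr[out$year == 2050], 7.5)

  same <- scale_deposition(ref, ref)
  expect_equal(same$dep_kg_km2_yr, ref$dep_kg_km2_yr)

  zz_m <- data.frame(watershed_id = "W1", year = c(2002:2006, 2050),
                     dep_kg_km2_yr = c(rep(0, 5), 6))
  zz_r <- data.frame(watershed_id = "W1", year = 2002:2006, dep_kg_km2_yr = 0)
  out_z <- scale_deposition(zz_m, zz_r)
  expect_equal(out_z$dep_kg_km2_yr[out_z$year == 2050], 6)
  expect_error(scale_deposition(zz_m, ref), class = "rivertn_unscalable_region")
  expect_error(scale_deposition(model[model$year > 2003, ], ref),
               class = "rivertn_invalid_input")
})

test_that("census interpolation is piecewise linear with trend extrapolation", {
  two <- data.frame(year = c(1987, 1992), value = c(100, 110))
  expect_equal(interpolate_census(two, 1989)$value, 104)
  const <- data.frame(year = c(1987, 1992, 1997), value = 55)
  expect_equal(interpolate_census(const, 1987:1997)$value, rep(55, 11))
  line <- data.frame(year = c(1987, 1992, 1997, 2002, 2007, 2012))
  line$value <- 2 * (line$year - 1987) + 100
  expect_equal(interpolate_census(line, 1980)$value, 86, tolerance = 1e-9)
  expect_equal(interpolate_census(line, c(1980, 1990, 2012))$value,
               c(86, 106, 150), tolerance = 1e-9)
  neg <- data.frame(year = c(1987, 1992), value = c(5, 50))
  expect_equal(interpolate_census(neg, 1980)$value, 5 - 9 * 7)
  expect_equal(interpolate_census(neg, 1980, floor_zero = TRUE)$value, 0)
  expect_error(interpolate_census(two, 2000), class = "rivertn_invalid_input")
  expect_error(interpolate_census(two[1, , drop = FALSE], 1990),
               class = "rivertn_invalid_input")
})

test_that("hold-constant propagation works forward and backward", {
  s <- data.frame(year = 2000:2007, value = c(70:76, 78))
  out <- hold_constant_after(s, 2007, years = c(2050, 2095))
  expect_equal(out$value[out$year == 2095], 78)
  expect_equal(out$value[out$year == 2003], 73)
  dep <- data.frame(year = 1979:1985, value = c(10, 11:16))
  back <- hold_constant_after(dep, 1979, years = 1976:1978,
                              direction = "backward")
  expect_equal(back$value[back$year %in% 1976:1978], rep(10, 3))
  expect_error(hold_constant_after(s, 2010), class = "rivertn_invalid_input")
})
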