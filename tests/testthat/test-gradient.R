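# gradient simulator: mass-to-S scaling, calibration, banding, TMT noise,
# mixture generation

test_that("s_from_mass follows the 2/3 power law and matches the 2.8S anchor", {
  for (k in c(0.001, 0.00297, 0.1)) {
    expect_equal(s_from_mass(58, k) / s_from_mass(29, k), 2^(2 / 3))
  }
  # oracle: hand evaluation of 0.00297 * 29000^(2/3) = 2.8006...
  expect_equal(s_from_mass(29, k = 0.00297), 0.00297 * 29000^(2 / 3))
  expect_equal(s_from_mass(29), 2.8, tolerance = 1e-3)
  expect_true(all(diff(s_from_mass(seq(10, 500, by = 5))) > 0))
  expect_error(s_from_mass(0), "positive")
  expect_error(s_from_mass(-5), "positive")
  expect_error(s_from_mass(29, k = 0), "positive")
  # inverse round-trip
  expect_equal(mass_from_s(s_from_mass(123.4)), 123.4)
})

test_that("calibrate_gradient fits the linear S-to-position map", {
  # two-point fit is exact: slope (10.1-4.0)/(8.9-2.8) = 1, intercept 1.2
  cal <- calibrate_gradient(data.frame(s_value = c(2.8, 8.9),
                                       peak_position = c(4.0, 10.1)))
  expect_equal(cal$slope, 1.0)
  expect_equal(cal$intercept, 1.2)
  expect_equal(position_from_s(3.0, cal), 4.2)
  # least squares on the 4 colinear default standards recovers the line
  cal4 <- calibrate_gradient(default_standards())
  expect_equal(cal4$slope, 0.82)
  expect_equal(cal4$intercept, 2.2)
  expect_error(calibrate_gradient(data.frame(s_value = 3, peak_position = 5)),
               "calibration failure")
  expect_error(calibrate_gradient(data.frame(s_value = c(3, 3),
                                             peak_position = c(5, 6))),
               "calibration failure")
  # negative slope (smaller S deeper) is a physical impossibility
  expect_error(calibrate_gradient(data.frame(s_value = c(2, 8),
                                             peak_position = c(9, 3))),
               "slope")
})

test_that("band profiles conserve mass and sediment monotonically", {
  g <- default_gradient
  for (s in c(2.2, 4.5, 6.5, 9.0, 13.0)) {
    b <- band_profile(s, 37.5, g, default_cal)
    expect_length(b, g$n_fractions)
    expect_true(all(b >= 0))
    expect_equal(sum(b), 37.5, tolerance = 1e-9)
  }
  # a species mapping exactly onto fraction 7 peaks there
  s7 <- (7 - default_cal$intercept) / default_cal$slope
  expect_equal(peak_fraction(band_profile(s7, 1, g, default_cal)), 7L)
  # peak fraction is nondecreasing in S over a brute-force grid
  grid <- seq(1.5, 14, by = 0.1)
  peaks <- vapply(grid, function(s)
    peak_fraction(band_profile(s, 1, g, default_cal)), integer(1))
  expect_true(all(diff(peaks) >= 0))
  # band centred far off the gradient pellets at the end
  b <- band_profile(50, 5, g, default_cal)
  expect_equal(sum(b), 5)
  expect_equal(peak_fraction(b), g$n_fractions)
})

test_that("calibration round-trips through simulated standard bands", {
  g <- default_gradient
  placed <- vapply(default_standards()$s_value, function(s)
    profile_centroid(band_profile(s, 1, g, default_cal)), numeric(1))
  cal2 <- calibrate_gradient(data.frame(
    s_value = default_standards()$s_value, peak_position = placed))
  expect_equal(cal2$slope, default_cal$slope, tolerance = 1e-3)
  expect_equal(cal2$intercept, default_cal$intercept, tolerance = 1e-3)
})

test_that("gradient_spec validates its invariants", {
  expect_error(gradient_spec(n_fractions = 1), ">= 2")
  expect_error(gradient_spec(ms_fractions = 10:14), "1..n_fractions")
  expect_error(gradient_spec(assayed_fractions = 0:4), "1..n_fractions")
  expect_error(gradient_spec(band_sigma = 0), "band_sigma")
})

test_that("simulate_tmt implements seeded multiplicative log-normal noise", {
  truth <- truth_profiles(peak_pool(), default_gradient, default_cal,
                          fractions = 5:10)
  # cv = 0 returns the truth
  expect_equal(unclass(simulate_tmt(truth, cv = 0, 2, seed = 1)[[1]]),
               unclass(truth), ignore_attr = TRUE)
  # determinism: same seed, identical matrices; replicates differ
  r1 <- simulate_tmt(truth, cv = 0.1, 2, seed = 99)
  r2 <- simulate_tmt(truth, cv = 0.1, 2, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(unclass(r1[[1]]), unclass(r1[[2]])))
  # law of large numbers: mean over 10000 replicates within 1% per cell
  # (multiplicative log-normal noise has mean exp(sigma^2/2) ~ 1.005 at
  # cv = 0.1, inside the 1% band; the median is 1 exactly)
  many <- simulate_tmt(truth, cv = 0.1, 10000, seed = 7)
  arr <- simplify2array(lapply(many, unclass))
  expect_equal(apply(arr, 1:2, mean) / unclass(truth),
               matrix(1, nrow(truth), ncol(truth)), tolerance = 0.01,
               ignore_attr = TRUE)
  ratios <- apply(arr, 3, function(m) m / unclass(truth))
  expect_equal(stats::median(ratios), 1, tolerance = 0.01)
  expect_error(simulate_tmt(truth, cv = 0.1, 0, seed = 1), "positive")
})

test_that("generate_mixture is reproducible and respects its contract", {
  solo <- generate_mixture(n_decoys = 0, seed = 5)
  expect_equal(nrow(solo), 1L)
  expect_true(solo$is_active)
  expect_equal(solo$s_value, 6.5)
  expect_identical(generate_mixture(n_decoys = 50, seed = 11),
                   generate_mixture(n_decoys = 50, seed = 11))
  # study-scale mixture: ~3000 species, observed matrix nonnegative
  pool <- generate_mixture(n_decoys = 2999, mass_range = c(20, 300),
                           seed = 2)
  expect_equal(nrow(pool), 3000L)
  expect_equal(sum(pool$is_active), 1L)
  m <- truth_profiles(pool, default_gradient, default_cal, fractions = 5:10)
  expect_true(all(unclass(m) >= 0))
  expect_equal(nrow(m), 3000L)
  expect_error(generate_mixture(n_decoys = -1), ">= 0")
})

test_that("species pools merge oligomeric states under one MS id", {
  pool <- species_pool(id = c("X", "X:XY"),
                       mass_kda = c(60, 140),
                       abundance = c(50, 50),
                       is_active = c(TRUE, FALSE),
                       pool_of = c(NA, "X"))
  m <- truth_profiles(pool, default_gradient, default_cal)
  expect_equal(nrow(m), 1L)
  expect_equal(rownames(m), "X")
  # pooled signal is the sum of the two bands
  b1 <- band_profile(pool$s_value[1], 50, default_gradient, default_cal)
  b2 <- band_profile(pool$s_value[2], 50, default_gradient, default_cal)
  expect_equal(unname(unclass(m)[1, ]), b1 + b2)
  expect_error(species_pool("a", mass_kda = 10, abundance = -1), ">= 0")
  expect_error(species_pool(c("a", "a"), c(10, 20), c(1, 1)), "unique")
})
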