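# reconstitution assay model: capture ratio, flipping statistic, Poisson
# occupancy, activity profiles and in-silico depletion

test_that("capture_ratio is the pellet share in percent", {
  expect_equal(capture_ratio(0, 1000), 0)
  expect_equal(capture_ratio(500, 500), 50)
  expect_equal(capture_ratio(750, 250), 75)
  expect_error(capture_ratio(0, 0), "undefined")
  expect_error(capture_ratio(-1, 10), ">= 0")
})

test_that("flipping_percent implements the normalized triplet statistic", {
  expect_equal(flipping_percent(50, 50, 100), 0)      # R_conA = R_buffer
  expect_equal(flipping_percent(50, 100, 100), 100)   # R_conA = R_conA_TX
  expect_equal(flipping_percent(50, 75, 100), 50)     # hand arithmetic
  # accepts raw counts too
  expect_equal(flipping_percent(list(P = 500, S = 500),
                                list(P = 750, S = 250),
                                list(P = 1000, S = 0)), 50)
  # invariance under uniform rescaling of all counts (ratio statistic)
  set.seed(1)
  for (i in 1:20) {
    P <- runif(3, 100, 1000)
    S <- runif(3, 100, 1000)
    base <- flipping_percent(list(P = P[1], S = S[1]),
                             list(P = P[2], S = S[2]),
                             list(P = P[3], S = S[3]))
    k <- runif(1, 0.1, 10)
    scaled <- flipping_percent(list(P = k * P[1], S = k * S[1]),
                               list(P = k * P[2], S = k * S[2]),
                               list(P = k * P[3], S = k * S[3]))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  expect_error(flipping_percent(50, 75, 50), "window collapse")
})

test_that("expected_capture follows Poisson occupancy end points", {
  expect_identical(expected_capture(0), 50)
  expect_equal(expected_capture(20), 100, tolerance = 1e-6)
  # occupied-vesicle fraction 0.4 <=> lambda = ln(5/3) => 70% capture
  expect_equal(expected_capture(log(5 / 3)), 70)
  expect_equal(lambda_for_capture(70), log(5 / 3))
  # monotone nondecreasing and bounded in [100*f_out, 100]
  lam <- seq(0, 10, by = 0.05)
  for (f_out in c(0.3, 0.5, 0.7)) {
    v <- expected_capture(lam, f_out)
    expect_true(all(diff(v) > 0))
    expect_true(all(v >= 100 * f_out - 1e-12 & v <= 100 + 1e-12))
    expect_equal(v[1], 100 * f_out)
  }
  expect_error(expected_capture(-0.1), ">= 0")
})

test_that("flipping of an ideal triplet equals the occupied-vesicle fraction", {
  # analytic cross-check between the two parameterizations at f_out = 0.5
  for (lam in c(0.05, log(5 / 3), 1, 3, 8)) {
    tri <- triplet_for_lambda(lam)
    expect_equal(flipping_percent(tri$buffer, tri$conA, tri$conA_TX),
                 100 * (1 - exp(-lam)), tolerance = 1e-12)
    expect_equal(expected_flipping(lam), 100 * (1 - exp(-lam)))
  }
})

test_that("activity_profile maps amounts through the occupancy model", {
  p <- recon_params(occupancy_scale = 2)
  # no active protein anywhere: flat 50% capture / 0% flipping
  flat <- activity_profile(rep(0, 7), fractions = 5:11, params = p)
  expect_true(all(flat$value == 50))
  flat2 <- activity_profile(rep(0, 7), fractions = 5:11, params = p,
                            readout = "flipping")
  expect_true(all(flat2$value == 0))
  # single-site support peaks at that site
  amt <- c(0, 0, 5, 0, 0, 0, 0)
  act <- activity_profile(amt, fractions = 5:11, params = p)
  expect_equal(act$fraction[which.max(act$value)], 7L)
  # 70% design rule: peak calibrated to 70, everything else below
  amounts <- band_profile(6.5, 100, default_gradient, default_cal)[5:11]
  cp <- calibrate_occupancy(amounts, recon_params(), target_capture = 70)
  act70 <- activity_profile(amounts, fractions = 5:11, params = cp)
  expect_equal(max(act70$value), 70)
  expect_true(all(act70$value[-which.max(act70$value)] < 70))
  # duplicate noisy measurements are seeded and averaged per fraction
  dup <- activity_profile(amounts, fractions = 5:11, params = cp,
                          n_measurements = 2, noise_cv = 0.05, seed = 3)
  dup2 <- activity_profile(amounts, fractions = 5:11, params = cp,
                           n_measurements = 2, noise_cv = 0.05, seed = 3)
  expect_identical(dup, dup2)
  expect_equal(nrow(dup), 14L)
  avg <- average_activity(dup)
  expect_equal(nrow(avg), 7L)
  expect_equal(avg$value[1],
               mean(dup$value[dup$fraction == 5]))
})

test_that("depletion scales the Poisson mean by the surviving active share", {
  pool <- species_pool(
    id = c("a1", "a2", "a3", "d1", "d2"),
    mass_kda = c(100, 100, 100, 50, 80),
    abundance = c(10, 10, 10, 500, 470),
    is_active = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  grid <- seq(25, 125, by = 25)
  p <- recon_params(occupancy_scale = 1)
  # removing an inactive species leaves the curves identical
  d0 <- depletion_readout(pool, "d1", grid, p)
  expect_equal(d0$flipping_depleted, d0$flipping_mock)
  # removing the sole active species kills the readout at every ratio
  solo <- species_pool(c("act", "d"), c(100, 50), c(10, 990),
                       is_active = c(TRUE, FALSE))
  dd <- depletion_readout(solo, "act", grid, p)
  expect_true(all(dd$flipping_depleted == 0))
  expect_true(all(dd$flipping_mock > 0))
  # three equal active species, remove one: lambda x 2/3 exactly, and the
  # readout ratio tends to 2/3 in the small-lambda regime
  d1 <- depletion_readout(pool, "a1", grid, recon_params(occupancy_scale = 1e-4))
  expect_equal(d1$flipping_depleted / d1$flipping_mock,
               rep(2 / 3, length(grid)), tolerance = 1e-3)
  # at saturation the apparent drop is smaller than one-third (the assay's
  # poor sensitivity to < 2-fold changes)
  dsat <- depletion_readout(pool, "a1", grid, recon_params(occupancy_scale = 50))
  expect_true(all(dsat$flipping_depleted / dsat$flipping_mock > 2 / 3))
  # relative readout drop is bounded by the removed active share q
  set.seed(4)
  for (i in 1:20) {
    q <- runif(1)
    lam <- runif(1, 0.01, 5)
    drop <- 1 - (1 - exp(-(1 - q) * lam)) / (1 - exp(-lam))
    expect_lte(drop, q + 1e-12)
  }
  expect_error(depletion_readout(pool, "nope", grid, p), "unknown ids")
  expect_error(depletion_readout(pool, "a1", numeric(0), p), "nonempty")
})
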