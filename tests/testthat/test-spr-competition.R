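test_that("calibration fit recovers a noiseless hyperbola and validates input", {
  cc <- serial_dilution(50, 6)
  series <- data.frame(conc_nM = cc,
                       response_RU = hyperbolic_response(120, 40, cc))
  model <- fit_calibration(series)
  expect_equal(model$rmax, 120, tolerance = 1e-6)
  expect_equal(model$k_half, 40, tolerance = 1e-6)
  expect_equal(model$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_calibration(series[1:2, ]), "insufficient calibration")
  zero <- transform(series, response_RU = 0)
  expect_error(fit_calibration(zero), "all-zero")
})

test_that("calibration inversion is the exact algebraic inverse", {
  model <- structure(list(rmax = 120, k_half = 40), class = "hyperbolic_model")
  expect_equal(invert_calibration(model, 0), 0)
  expect_equal(invert_calibration(model, 60), 40)             # half-saturation
  expect_equal(invert_calibration(model, 0.8 * 120), 160)     # K*R/(Rmax-R)
  # inversion composed with the forward response is the identity
  cc <- seq(0, 400, by = 7)
  expect_equal(invert_calibration(model, hyperbolic_response(120, 40, cc)), cc)
  expect_error(invert_calibration(model, 120), "outside calibration range")
  expect_error(invert_calibration(model, -1), ">= 0")
})

test_that("competition fit recovers the true K_D exactly on noiseless data", {
  for (kd in c(25, 220, 1500)) {
    fx <- make_noiseless_competition(kd)
    fit <- fit_kd_competition(fx$experiment, fx$calibration)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_identical(fit$model, "single_site")
  }
})

test_that("competition fit rejects series without a competition signal", {
  fx <- make_noiseless_competition(220)
  flat <- fx$experiment
  flat$points$response_RU <- hyperbolic_response(120, 40, 25)  # all free
  expect_error(fit_kd_competition(flat, fx$calibration), "no competition signal")
  short <- fx$experiment
  short$points <- short$points[1:4, ]
  expect_error(fit_kd_competition(short, fx$calibration), "insufficient")
})

test_that("seeded 2%-noise experiments recover K_D within 10%", {
  # each constant is the mean of three independent seeded experiments, the
  # replication at which such constants are reported
  for (kd in c(220, 74.7)) {
    top <- if (kd < 100) 80000 else 10000
    kds <- vapply(1:3, function(i) {
      sim <- gen_competition_dataset(kd,
        titrant_series = serial_dilution(top, 11),
        noise = noise_spec(sigma = 0.02, seed = 200 + i))
      cal <- fit_calibration(sim$calibration)
      fit_kd_competition(sim$experiment, cal)$kd
    }, 0)
    expect_lt(abs(mean(kds) - kd) / kd, 0.10)
  }
})

test_that("apparent fit tags results and matches the independent-sites oracle", {
  fx <- make_noiseless_competition(350)
  fit <- fit_kd_apparent(fx$experiment, fx$calibration)
  expect_identical(fit$model, "apparent")
  expect_equal(fit$kd, 350, tolerance = 1e-6)

  # one ligand vs a titrant carrying three independent sites (K = 220, 1500,
  # 620 nM): the apparent constant approaches the harmonic combination
  kds <- c(220, 1500, 620)
  harmonic <- 1 / sum(1 / kds)
  tit <- serial_dilution(10000, 11)
  free <- vapply(tit, function(p) {
    unname(solve_multi_ligand_equilibrium(
      c(syn = 25), c(s1 = p, s2 = p, s3 = p),
      matrix(kds, 1, 3))$free)
  }, 0)
  model <- structure(list(rmax = 120, k_half = 40), class = "hyperbolic_model")
  expt <- list(analyte_total_nM = 25,
               points = data.frame(
                 titrant_nM = tit,
                 response_RU = hyperbolic_response(120, 40, free)))
  fit3 <- fit_kd_apparent(expt, model)
  expect_equal(fit3$kd, harmonic, tolerance = 0.05)
})

test_that("direct equilibrium SPR fit recovers K_D and flags degenerate input", {
  cc <- serial_dilution(75, 5)
  curve <- data.frame(conc_nM = cc, response_RU = hyperbolic_response(60, 9, cc))
  fit <- fit_kd_direct_spr(curve)
  expect_equal(fit$kd, 9, tolerance = 1e-6)
  expect_equal(fit$rmax, 60, tolerance = 1e-6)
  flat <- transform(curve, response_RU = 30)
  expect_error(fit_kd_direct_spr(flat), "no saturation")
})

test_that("avidity index compares measured to independent-site predictions", {
  kds <- c(220, 1500, 620)
  harmonic <- 1 / sum(1 / kds)
  expect_equal(avidity_index(kds, harmonic), 1.0)
  expect_equal(avidity_index(kds, 74.7), harmonic / 74.7)  # ~1.96
  expect_gt(avidity_index(kds, 74.7), 1.9)
  expect_equal(avidity_index(500, 500), 1.0)
})

test_that("truncation leaves clean data untouched and drops plateau points", {
  # noiseless, artifact-free: nothing to exclude
  fx <- make_noiseless_competition(220)
  fit <- fit_kd_competition(fx$experiment, fx$calibration,
                            truncate_high_titrant = TRUE)
  expect_identical(fit$excluded_high_titrant, 0L)
  expect_equal(fit$kd, 220, tolerance = 1e-6)

  # plateau artifact raises the top-titrant free analyte and is truncated
  sim <- gen_competition_dataset(220, noise = noise_spec(sigma = 0.02, seed = 3),
                                 artifact = plateau_artifact())
  cal <- fit_calibration(sim$calibration)
  free_top <- invert_calibration(cal, sim$experiment$points$response_RU[
    which.max(sim$experiment$points$titrant_nM)])
  clean <- gen_competition_dataset(220, noise = noise_spec(sigma = 0.02, seed = 3))
  free_top_clean <- invert_calibration(cal, clean$experiment$points$response_RU[
    which.max(clean$experiment$points$titrant_nM)])
  expect_gt(free_top, free_top_clean)

  ftrunc <- fit_kd_competition(sim$experiment, cal, truncate_high_titrant = TRUE)
  expect_gt(ftrunc$excluded_high_titrant, 0)
  ffull <- fit_kd_competition(sim$experiment, cal, truncate_high_titrant = FALSE)
  expect_lt(abs(ftrunc$kd - ffull$kd) / ftrunc$kd, 0.05)
})

test_that("end-to-end recovery holds across the affinity range at 2% noise", {
  for (kd in c(10, 100, 1000, 5000)) {
    top <- max(10000, 50 * kd)
    kds <- vapply(1:3, function(i) {
      sim <- gen_competition_dataset(kd,
        titrant_series = serial_dilution(top, 11),
        noise = noise_spec(sigma = 0.02, seed = 1000 * i + kd))
      cal <- fit_calibration(sim$calibration)
      fit_kd_competition(sim$experiment, cal)$kd
    }, 0)
    expect_lt(abs(mean(kds) - kd) / kd, 0.10, label = sprintf("kd=%g", kd))
  }
})
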