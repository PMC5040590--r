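test_that("saturation fit recovers noiseless constants and shares the hyperbolic core", {
  cc <- serial_dilution(500, 9)[-1]
  series <- data.frame(conc_nM = cc,
                       intensity_AU = hyperbolic_response(1000, 31, cc))
  fit <- fit_kd_saturation(series)
  expect_equal(fit$kd, 31, tolerance = 1e-6)
  expect_equal(fit$rmax, 1000, tolerance = 1e-6)

  # identical input through the direct-SPR entry point gives the same fit
  curve <- data.frame(conc_nM = cc, response_RU = series$intensity_AU)
  fit_spr <- fit_kd_direct_spr(curve)
  expect_equal(fit$kd, fit_spr$kd)
  expect_equal(fit$rmax, fit_spr$rmax)
})

test_that("seeded 3%-noise bead series recovers K_D within 15%", {
  for (kd in c(31, 210)) {
    sim <- gen_saturation_dataset(kd, bmax = 1000,
                                  noise = noise_spec(sigma = 0.03, seed = 17))
    fit <- fit_kd_saturation(sim$series)
    expect_lt(abs(fit$kd - kd) / kd, 0.15)
  }
})

test_that("saturation fit warns when the series never bends over", {
  cc <- seq(1, 50, length.out = 8)
  lin <- data.frame(conc_nM = cc,
                    intensity_AU = hyperbolic_response(5e4, 5000, cc))
  expect_warning(fit <- fit_kd_saturation(lin), "unidentifiable")
  expect_true(fit$details$lower_bound)
})

test_that("depletion check warns when resin capacity rivals K_D", {
  cc <- serial_dilution(500, 9)[-1]
  series <- data.frame(conc_nM = cc,
                       intensity_AU = hyperbolic_response(1000, 31, cc))
  expect_warning(fit_kd_saturation(series, resin_capacity_nM = 100), "depletion")
  expect_silent(fit_kd_saturation(series, resin_capacity_nM = 0.5))
})

test_that("resin comparison reproduces the hand-computed two-group t-test", {
  a <- c(10, 12, 11, 13); b <- c(6, 7, 5, 6)
  cmp <- compare_resin_binding(list(control = a, treated = b),
                               baseline = "control")
  # closed-form pooled t-test
  sp2 <- (var(a) * 3 + var(b) * 3) / 6
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), 6)
  row <- cmp$contrasts[cmp$contrasts$condition == "treated", ]
  expect_equal(row$statistic, t_hand, tolerance = 1e-12)
  expect_equal(row$p_value, p_hand, tolerance = 1e-12)
  expect_equal(row$percent_of_control, 100 * mean(b) / mean(a))
})

test_that("identical groups yield a null ANOVA", {
  set.seed(5)
  base <- rnorm(4, 100, 5)
  cmp <- compare_resin_binding(list(control = base, other = base))
  expect_lt(cmp$f, 1e-20)
  expect_true(all(cmp$contrasts$p_value > 0.99))
})

test_that("Tukey correction is never more liberal than Fisher's LSD", {
  set.seed(8)
  conds <- list(control = rnorm(4, 100, 8), a = rnorm(4, 85, 8),
                b = rnorm(4, 95, 8), c = rnorm(4, 60, 8))
  lsd <- compare_resin_binding(conds, correction = "fisher_lsd")
  tuk <- compare_resin_binding(conds, correction = "tukey")
  expect_true(all(lsd$contrasts$p_value <=
                  tuk$contrasts$p_value + 1e-12))
  # cross-check Tukey p-values against stats::TukeyHSD
  df <- data.frame(condition = rep(names(conds), lengths(conds)),
                   intensity_AU = unlist(conds))
  hsd <- TukeyHSD(aov(intensity_AU ~ condition, data = df))$condition
  for (g in c("a", "b", "c")) {
    pair <- intersect(rownames(hsd), paste0(c(g, "control"), "-",
                                            c("control", g)))
    expect_equal(tuk$contrasts$p_value[tuk$contrasts$condition == g],
                 unname(hsd[pair, "p adj"]), tolerance = 1e-8)
  }
})

test_that("a 50% reduction with 4 replicates is flagged at p < 0.01", {
  set.seed(21)
  cmp <- compare_resin_binding(
    list(control = rnorm(4, 100, 8), phospho = rnorm(4, 50, 8)))
  expect_lt(cmp$contrasts$p_value[cmp$contrasts$condition == "phospho"], 0.01)
})

test_that("resin comparison enforces its preconditions", {
  expect_error(compare_resin_binding(list(control = c(1, 2))), "at least 2")
  expect_error(compare_resin_binding(list(control = c(1, 2), x = 3)),
               ">= 2 replicates")
  expect_error(compare_resin_binding(list(a = c(1, 2), b = c(3, 4)),
                                     baseline = "control"), "baseline")
  expect_error(compare_resin_binding(list(control = c(5, 5), x = c(5, 5))),
               "zero variance")
})

test_that("phosphate stoichiometry is the counts/activity/protein quotient", {
  expect_equal(phospho_stoichiometry(0, 375, 10), 0)
  expect_equal(phospho_stoichiometry(3750, 375, 2), 5)
  expect_equal(phospho_stoichiometry(375, 375, 1), 1)
  expect_error(phospho_stoichiometry(100, 375, 0), "> 0")
  expect_error(phospho_stoichiometry(-1, 375, 1), ">= 0")
})
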