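make_lane <- function(genotype, target, target_bg, psd95, psd95_bg,
                      lane = 1, blot = "b1") {
  data.frame(blot_id = blot, lane_id = paste0(genotype, lane),
             genotype = genotype, load_ug = 5,
             target_AU = target, target_bg_AU = target_bg,
             psd95_AU = psd95, psd95_bg_AU = psd95_bg)
}

test_that("lane ratios are background-corrected quotients with invalid flags", {
  lanes <- rbind(make_lane("WT", 110, 10, 1100, 100),
                 make_lane("WT", 50, 50, 1100, 100, lane = 2),
                 make_lane("HET", 80, 10, 90, 100, lane = 1))
  out <- lane_ratios(lanes)
  expect_equal(out$ratio[1], 0.10)
  expect_equal(out$ratio[2], 0)          # background equals density: zero
  expect_true(is.na(out$ratio[3]) && !out$valid[3])  # net PSD-95 <= 0
  # randomized lanes against direct recomputation
  set.seed(9)
  rl <- do.call(rbind, lapply(1:20, function(i)
    make_lane("WT", runif(1, 50, 200), runif(1, 0, 40),
              runif(1, 500, 2000), runif(1, 0, 300), lane = i)))
  rr <- lane_ratios(rl)
  expect_equal(rr$ratio, (rl$target_AU - rl$target_bg_AU) /
                 (rl$psd95_AU - rl$psd95_bg_AU))
  expect_error(lane_ratios(rl[setdiff(names(rl), "psd95_AU")]),
               "missing column")
})

test_that("outlier screen excludes at most one extreme value per pass", {
  expect_length(exclude_outliers(rep(1, 5))$excluded, 0)
  scr <- exclude_outliers(c(1, 1, 1, 1, 10), k = 2)
  expect_equal(scr$excluded, 10)
  expect_equal(scr$retained, rep(1, 4))
  # SE mode is strictly more aggressive (spread shrinks by sqrt(n))
  vals <- c(1.0, 1.1, 0.95, 1.05, 1.18)
  sd_scr <- exclude_outliers(vals, mode = "sd")
  se_scr <- exclude_outliers(vals, mode = "se")
  expect_length(sd_scr$excluded, 0)
  expect_equal(se_scr$excluded, 1.18)
  expect_error(exclude_outliers(c(1, 2)), "n >= 3")
})

test_that("group comparison matches the closed-form pooled t", {
  cmp <- compare_groups(c(1, 2, 3), c(2, 3, 4), variant = "pooled",
                        tail = "het_greater")
  expect_equal(cmp$t, -sqrt(1.5), tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_one_tailed, pt(-sqrt(1.5), 4), tolerance = 1e-12)
  expect_equal(cmp$cohens_d, 1)               # |1| / pooled sd 1
  expect_equal(cmp$percent_change, 50)
})

test_that("group comparison agrees with stats::t.test in every variant", {
  set.seed(14)
  x <- rnorm(11, 0.234, 0.04); y <- rnorm(11, 0.179, 0.017)
  for (variant in c("welch", "pooled", "paired")) {
    cmp <- compare_groups(x, y, variant = variant, tail = "wt_greater")
    tt <- t.test(x, y, alternative = "greater",
                 var.equal = (variant == "pooled"),
                 paired = (variant == "paired"))
    expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(cmp$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(cmp$p_one_tailed, tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give p = 0.5, d = 0 and 0% change", {
  cmp <- compare_groups(c(1, 1, 1), c(1, 1, 1), variant = "welch")
  expect_equal(cmp$percent_change, 0)
  expect_equal(cmp$cohens_d, 0)
  expect_equal(cmp$p_one_tailed, 0.5)
})

test_that("Welch df never exceeds pooled df; p agrees under equal variance", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(8, 1, 0.2); y <- rnorm(8, 0.9, 0.2)
    w <- compare_groups(x, y, variant = "welch")
    p <- compare_groups(x, y, variant = "pooled")
    expect_lte(w$df, p$df + 1e-9)
    expect_equal(w$p_one_tailed, p$p_one_tailed, tolerance = 0.05)
  }
})

test_that("Cohen's d is invariant to common rescaling", {
  set.seed(2)
  x <- rnorm(10, 5, 1); y <- rnorm(10, 4, 1)
  d1 <- compare_groups(x, y)$cohens_d
  d2 <- compare_groups(x * 37, y * 37)$cohens_d
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("percent change rounds halves away from zero", {
  expect_equal(round_half_away(-23.504), -24)
  expect_equal(round_half_away(c(-23.5, 23.5, 11.4, -0.5)), c(-24, 24, 11, -1))
  cmp <- compare_groups(rep(c(0.234, 0.235), 6)[1:11],
                        rep(c(0.179, 0.180), 6)[1:11])
  expect_equal(cmp$percent_change_int,
               round_half_away(100 * (cmp$mean_het - cmp$mean_wt) / cmp$mean_wt))
})

test_that("comparison preconditions are enforced", {
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
  expect_error(compare_groups(c(1, 2, 3), c(1, 2), variant = "paired"),
               "equal group sizes")
  expect_error(compare_groups(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("lane-table pipeline wires ratios, screening and comparison together", {
  lt <- gen_lane_table(effects = c(synGAP = -24), base_ratios = c(synGAP = 0.234),
                       cv = 0.10, n_per_group = 11, seed = 99)
  cmp <- compare_psd_composition(lt[lt$protein == "synGAP", ],
                                 variant = "welch", tail = "wt_greater",
                                 protein = "synGAP")
  expect_lt(cmp$p_one_tailed, 0.05)
  expect_lt(cmp$percent_change, -10)
  expect_identical(cmp$protein, "synGAP")
})
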