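#' Per-lane target-to-PSD-95 density ratios
#'
#' Computes, for every immunoblot lane, the background-corrected ratio of
#' the target protein's integrated density to that of PSD-95 in the same
#' lane: `(target - target_bg) / (psd95 - psd95_bg)`. Within-lane
#' normalization to the scaffold removes loading differences between lanes.
#'
#' @param lanes Data frame with columns `blot_id`, `lane_id`, `genotype`,
#'   `target_AU`, `target_bg_AU`, `psd95_AU`, `psd95_bg_AU` (a `load_ug`
#'   column is carried through if present).
#' @return The input with `ratio` and logical `valid` columns added; lanes
#'   whose net PSD-95 density is not positive are flagged invalid (`ratio`
#'   `NA`) rather than dropped.
#' @export
lane_ratios <- function(lanes) {
  need <- c("blot_id", "lane_id", "genotype",
            "target_AU", "target_bg_AU", "psd95_AU", "psd95_bg_AU")
  missing_cols <- setdiff(need, names(lanes))
  if (length(missing_cols))
    stop("lanes table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- c("target_AU", "target_bg_AU", "psd95_AU", "psd95_bg_AU")
  if (any(vapply(lanes[num], function(x) any(x < 0), TRUE)))
    stop("densities and backgrounds must be >= 0")
  net_target <- pmax(lanes$target_AU - lanes$target_bg_AU, 0)
  net_psd95 <- lanes$psd95_AU - lanes$psd95_bg_AU
  valid <- net_psd95 > 0
  ratio <- ifelse(valid, net_target / net_psd95, NA_real_)
  out <- lanes
  out$ratio <- ratio
  out$valid <- valid
  out
}

#' Screen a group of ratios for a single outlier
#'
#' Applies the rule used for blot-ratio quality control: a value lying more
#' than `k` group standard deviations from the group mean is an outlier, and
#' at most one value (the most extreme) is excluded per group per pass. An
#' alternate strict mode measures the distance in standard errors of the
#' mean instead of standard deviations; it is far more aggressive and is
#' provided because published phrasings sometimes conflate the two.
#'
#' Only the single most deviant value is ever a candidate, and the spread is
#' computed from the remaining values (leaving the candidate out), so that a
#' gross outlier cannot mask itself by inflating the group's own standard
#' deviation.
#'
#' @param values Numeric vector of per-lane ratios for one group (n >= 3).
#' @param k Multiplier on the spread measure (default 2).
#' @param mode `"sd"` (default) or `"se"`.
#' @return List with `retained`, `excluded` (values), `excluded_idx`
#'   (indices into the input) and `mode`.
#' @examples
#' exclude_outliers(c(1, 1, 1, 1, 10))  # 10 excluded
#' @export
exclude_outliers <- function(values, k = 2, mode = c("sd", "se")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), k > 0)
  if (length(values) < 3) stop("need n >= 3 to screen for outliers")
  dev <- abs(values - mean(values))
  cand <- which.max(dev)       # one exclusion per pass: the most extreme
  spread <- stats::sd(values[-cand])
  if (mode == "se") spread <- spread / sqrt(length(values))
  idx <- integer(0)
  if (dev[cand] > k * spread) idx <- cand
  list(retained = if (length(idx)) values[-idx] else values,
       excluded = values[idx], excluded_idx = idx, mode = mode)
}

#' Two-group comparison of density ratios
#'
#' Compares wild-type and mutant groups of per-lane ratios by a one-tailed
#' t-test (Welch, pooled-variance, or paired), reporting the percent change
#' of the mutant mean relative to wild type and Cohen's d computed with the
#' pooled standard deviation. The tail direction must be declared up front
#' (`"wt_greater"` tests WT > HET, i.e. a predicted decrease;
#' `"het_greater"` the reverse).
#'
#' @param ratios_wt,ratios_het Numeric vectors of per-lane ratios.
#' @param variant `"welch"`, `"pooled"`, or `"paired"` (paired requires
#'   equal-length, order-paired vectors).
#' @param tail `"wt_greater"` or `"het_greater"`.
#' @param protein Optional label carried into the result.
#' @return List of class `group_comparison`: means, standard errors and n
#'   per group, `percent_change` (exact) and `percent_change_int` (rounded
#'   to the nearest integer, halves away from zero), `t`, `df`,
#'   `p_one_tailed`, `cohens_d`, `test_variant` and `tail`.
#' @export
compare_groups <- function(ratios_wt, ratios_het,
                           variant = c("welch", "pooled", "paired"),
                           tail = c("wt_greater", "het_greater"),
                           protein = NA_character_) {
  variant <- match.arg(variant); tail <- match.arg(tail)
  x <- ratios_wt[is.finite(ratios_wt)]; y <- ratios_het[is.finite(ratios_het)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 ratios per group")
  if (variant == "paired" && n1 != n2)
    stop("paired comparison requires equal group sizes with declared pairing")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0 && m1 == m2) {
    tstat <- 0; df <- n1 + n2 - 2
  } else if (v1 == 0 && v2 == 0) {
    stop("zero variance in both groups: t-test undefined")
  } else if (variant == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    tstat <- (m1 - m2) / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {                                 # paired
    d <- x - y
    if (stats::sd(d) == 0 && mean(d) == 0) { tstat <- 0 } else {
      tstat <- mean(d) / (stats::sd(d) / sqrt(n1))
    }
    df <- n1 - 1
  }
  # one-tailed p in the declared direction: wt_greater means evidence is
  # large positive t (x - y > 0)
  p_one <- if (tail == "wt_greater") stats::pt(tstat, df, lower.tail = FALSE)
           else stats::pt(tstat, df, lower.tail = TRUE)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d_cohen <- if (sp > 0) abs(m1 - m2) / sp else 0
  pct <- 100 * (m2 - m1) / m1
  structure(list(protein = protein,
                 mean_wt = m1, se_wt = stats::sd(x) / sqrt(n1), n_wt = n1,
                 mean_het = m2, se_het = stats::sd(y) / sqrt(n2), n_het = n2,
                 percent_change = pct,
                 percent_change_int = round_half_away(pct),
                 t = tstat, df = df, p_one_tailed = p_one,
                 cohens_d = d_cohen, test_variant = variant, tail = tail),
            class = "group_comparison")
}

#' Round to the nearest integer, halves away from zero
#'
#' Commercial rounding as used for reporting percent changes (-23.5 rounds
#' to -24), in contrast to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.na(x$protein)) cat(sprintf("Protein: %s\n", x$protein))
  cat(sprintf("  WT : %.4g +/- %.2g (n = %d)\n", x$mean_wt, x$se_wt, x$n_wt))
  cat(sprintf("  HET: %.4g +/- %.2g (n = %d)\n", x$mean_het, x$se_het, x$n_het))
  cat(sprintf("  change: %+.1f%% (%+d%% rounded)\n",
              x$percent_change, x$percent_change_int))
  cat(sprintf("  %s one-tailed t-test (%s): t = %.3f, df = %.2f, p = %.4g\n",
              x$test_variant, x$tail, x$t, x$df, x$p_one_tailed))
  cat(sprintf("  Cohen's d = %.2f\n", x$cohens_d))
  cat("  note: lanes are technical replicates of one pooled preparation per genotype\n")
  invisible(x)
}

#' Full densitometry comparison from a lane table
#'
#' Convenience pipeline: computes per-lane ratios with [lane_ratios()],
#' optionally screens each genotype group for a single outlier with
#' [exclude_outliers()], and runs [compare_groups()]. No multiple-testing
#' correction across proteins is applied.
#'
#' @param lanes Lane table (see [lane_ratios()]).
#' @param variant,tail Passed to [compare_groups()].
#' @param screen_outliers Apply the one-outlier-per-group screen?
#' @param outlier_mode Passed to [exclude_outliers()].
#' @param protein Optional label.
#' @return A `group_comparison` with an `excluded_lanes` element listing any
#'   excluded lane ids.
#' @export
compare_psd_composition <- function(lanes, variant = "welch",
                                    tail = "wt_greater",
                                    screen_outliers = TRUE,
                                    outlier_mode = "sd",
                                    protein = NA_character_) {
  rt <- lane_ratios(lanes)
  rt <- rt[rt$valid, ]
  split_r <- split(seq_len(nrow(rt)), rt$genotype)
  if (!all(c("WT", "HET") %in% names(split_r)))
    stop("lane table must contain both WT and HET genotypes")
  excluded <- character(0)
  take <- function(geno) {
    idx <- split_r[[geno]]
    vals <- rt$ratio[idx]
    if (screen_outliers && length(vals) >= 3) {
      scr <- exclude_outliers(vals, mode = outlier_mode)
      if (length(scr$excluded_idx)) {
        excluded <<- c(excluded,
                       paste0(rt$blot_id[idx[scr$excluded_idx]], ":",
                              rt$lane_id[idx[scr$excluded_idx]]))
        vals <- scr$retained
      }
    }
    vals
  }
  wt <- take("WT"); het <- take("HET")
  cmp <- compare_groups(wt, het, variant = variant, tail = tail,
                        protein = protein)
  cmp$excluded_lanes <- excluded
  cmp
}
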