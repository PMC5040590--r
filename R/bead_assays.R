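#' Saturation-binding dissociation constant from a bead assay
#'
#' Fits integrated band intensities of protein bound to an affinity resin,
#' measured over a series of input concentrations, to a hyperbola; the
#' half-saturation constant is the \eqn{K_D}. Intensities are fit directly
#' because immunoblot signal is linear over the working range.
#'
#' The assay design keeps the protein far (20-3000-fold) below the resin's
#' ligand capacity, so depletion of free protein by the beads is neglected
#' and the nominal input concentration stands in for the free concentration.
#' If `resin_capacity_nM` is supplied, a warning is emitted whenever the
#' predicted bound fraction of input exceeds 10% at any concentration,
#' flagging that this assumption is strained.
#'
#' @param series Data frame with columns `conc_nM` (input protein) and
#'   `intensity_AU` (bound signal). Replicate rows allowed.
#' @param resin_capacity_nM Optional binding capacity of the resin expressed
#'   as a concentration in the incubation volume (nM); enables the depletion
#'   check.
#' @return An [affinity_fit()] with `model = "hyperbolic"`; `rmax` is the
#'   fitted Bmax (AU). If the concentration series never bends over (no
#'   point above the fitted \eqn{K_D}), the constant is flagged as a lower
#'   bound with a warning.
#' @export
fit_kd_saturation <- function(series, resin_capacity_nM = NULL) {
  stopifnot(is.data.frame(series),
            all(c("conc_nM", "intensity_AU") %in% names(series)))
  if (any(series$intensity_AU < 0)) stop("intensities must be >= 0")
  h <- .fit_hyperbola(series$conc_nM, series$intensity_AU,
                      min_points = 5, what = "saturation")
  lower_bound <- h$k_half > max(series$conc_nM)
  if (lower_bound)
    warning("K_D unidentifiable from this concentration range; lower bound reported")
  if (!is.null(resin_capacity_nM)) {
    # fraction of input captured when resin sites are in excess:
    # bound/total = capacity / (K_D + C + capacity), worst at the lowest C
    frac <- resin_capacity_nM /
      (h$k_half + min(series$conc_nM) + resin_capacity_nM)
    if (frac > 0.10)
      warning(sprintf(
        "depletion assumption strained: up to %.0f%% of input protein predicted bound",
        100 * frac))
  }
  affinity_fit(kd = h$k_half, stderr = h$se_k, r_squared = h$r_squared,
               model = "hyperbolic", n_points = h$n, rmax = h$rmax,
               details = list(lower_bound = lower_bound))
}

#' Compare resin-binding conditions by one-way ANOVA with post-hoc contrasts
#'
#' Analyses replicate bound-protein intensities across treatment conditions
#' (e.g. control vs kinase-phosphorylated vs calmodulin-bound) by ordinary
#' one-way ANOVA, then contrasts every condition against a designated
#' baseline using either uncorrected Fisher's LSD (pairwise t on the pooled
#' ANOVA mean square, two-tailed) or the Tukey studentized-range correction
#' for multiple comparisons. Means are also reported as percent of the
#' baseline mean.
#'
#' @param conditions Data frame with columns `condition` and `intensity_AU`
#'   (one row per replicate), or a named list of numeric replicate vectors.
#' @param baseline Name of the reference condition.
#' @param correction `"fisher_lsd"` (uncorrected pairwise t) or `"tukey"`.
#' @return List of class `resin_comparison` with the ANOVA `f`, `p`, `df`,
#'   and a `contrasts` data frame (condition, n, mean, percent_of_control,
#'   diff, t or q statistic, p_value).
#' @export
compare_resin_binding <- function(conditions, baseline = "control",
                                  correction = c("fisher_lsd", "tukey")) {
  correction <- match.arg(correction)
  if (is.list(conditions) && !is.data.frame(conditions)) {
    conditions <- data.frame(
      condition = rep(names(conditions), lengths(conditions)),
      intensity_AU = unlist(conditions, use.names = FALSE))
  }
  stopifnot(all(c("condition", "intensity_AU") %in% names(conditions)))
  conditions$condition <- as.character(conditions$condition)
  groups <- split(conditions$intensity_AU, conditions$condition)
  if (length(groups) < 2) stop("need at least 2 conditions to compare")
  if (!baseline %in% names(groups))
    stop(sprintf("baseline condition '%s' not present", baseline))
  if (any(lengths(groups) < 2))
    stop("every condition needs >= 2 replicates")
  if (all(vapply(groups, stats::var, 0) == 0) &&
      length(unique(vapply(groups, mean, 0))) == 1)
    stop("zero variance in all groups: nothing to compare")

  av <- stats::aov(intensity_AU ~ condition, data = conditions)
  atab <- summary(av)[[1]]
  mse <- atab["Residuals", "Mean Sq"]
  df_err <- atab["Residuals", "Df"]
  f <- atab["condition", "F value"]
  p_anova <- atab["condition", "Pr(>F)"]

  ns <- lengths(groups); means <- vapply(groups, mean, 0)
  others <- setdiff(names(groups), baseline)
  k <- length(groups)
  rows <- lapply(others, function(g) {
    diffm <- means[[g]] - means[[baseline]]
    sed <- sqrt(mse * (1 / ns[[g]] + 1 / ns[[baseline]]))
    if (correction == "fisher_lsd") {
      tstat <- diffm / sed
      pval <- 2 * stats::pt(-abs(tstat), df_err)
      stat <- tstat
    } else {
      # studentized range statistic; ptukey handles unbalanced pairs via the
      # Tukey-Kramer standard error already folded into sed
      stat <- abs(diffm) / (sed / sqrt(2))
      pval <- stats::ptukey(stat, nmeans = k, df = df_err, lower.tail = FALSE)
    }
    data.frame(condition = g, n = ns[[g]], mean = means[[g]],
               percent_of_control = 100 * means[[g]] / means[[baseline]],
               diff = diffm, statistic = stat, p_value = pval)
  })
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  structure(list(f = f, p = p_anova, df = c(k - 1, df_err), mse = mse,
                 baseline = baseline, baseline_mean = means[[baseline]],
                 correction = correction, contrasts = contrasts),
            class = "resin_comparison")
}

#' @export
print.resin_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  cat(sprintf("Contrasts vs '%s' (%s):\n", x$baseline,
              if (x$correction == "tukey") "Tukey" else "uncorrected Fisher's LSD"))
  print(transform(x$contrasts,
                  mean = signif(mean, 4),
                  percent_of_control = round(percent_of_control, 1),
                  statistic = signif(statistic, 4),
                  p_value = signif(p_value, 3)))
  invisible(x)
}

#' Stoichiometry of phosphate incorporation
#'
#' Converts scintillation counts of radiolabelled protein into mol phosphate
#' incorporated per mol protein:
#' `(counts / specific_activity) / protein_pmol`.
#'
#' @param counts Measured counts (cpm), `>= 0`.
#' @param specific_activity Specific activity of the labelled ATP (cpm/pmol),
#'   `> 0`.
#' @param protein_pmol Amount of protein in the lane (pmol), `> 0`.
#' @return Stoichiometry in mol phosphate per mol protein.
#' @examples
#' phospho_stoichiometry(3750, 375, 2)  # 5 mol/mol
#' @export
phospho_stoichiometry <- function(counts, specific_activity, protein_pmol) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(specific_activity <= 0)) stop("specific_activity must be > 0")
  if (any(protein_pmol <= 0)) stop("protein amount must be > 0")
  (counts / specific_activity) / protein_pmol
}
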