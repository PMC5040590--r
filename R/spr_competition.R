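#' Fit an SPR calibration (standard) curve
#'
#' Fits the maximum resonance responses of an analyte dilution series to the
#' hyperbola \eqn{R = R_{max} C / (K_{1/2} + C)}. The calibration relates the
#' response on a PDZ-domain-coated chip to the free analyte concentration in
#' a sample, and is later inverted to read free concentrations off sample
#' mixtures. Responses are expected reference- and blank-subtracted, so the
#' curve passes through the origin.
#'
#' @param series Data frame with columns `conc_nM` and `response_RU` (one row
#'   per injection; replicates allowed).
#' @return List of class `hyperbolic_model` with `rmax`, `k_half`, standard
#'   errors, `r_squared` and the fitted values.
#' @examples
#' s <- data.frame(conc_nM = c(0, 3.125, 6.25, 12.5, 25, 50))
#' s$response_RU <- hyperbolic_response(120, 40, s$conc_nM)
#' fit_calibration(s)
#' @export
fit_calibration <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("conc_nM", "response_RU") %in% names(series)))
  h <- .fit_hyperbola(series$conc_nM, series$response_RU,
                      min_points = 4, what = "calibration")
  structure(h, class = "hyperbolic_model")
}

#' @export
print.hyperbolic_model <- function(x, ...) {
  cat(sprintf("Hyperbolic calibration: Rmax = %.4g, K_half = %.4g nM (R^2 = %.4f, n = %d)\n",
              x$rmax, x$k_half, x$r_squared, x$n))
  invisible(x)
}

#' Invert a calibration curve: response to free concentration
#'
#' Algebraic inverse of the calibration hyperbola,
#' \eqn{C = K_{1/2} R / (R_{max} - R)}. Used to convert the maximum response
#' of each analyte/titrant mixture into the free analyte concentration that
#' produced it.
#'
#' @param model A `hyperbolic_model` from [fit_calibration()], or any list
#'   with elements `rmax` and `k_half`.
#' @param response Response value(s), must satisfy `0 <= response < rmax`.
#' @return Free concentration(s) in nM.
#' @export
invert_calibration <- function(model, response) {
  rmax <- model$rmax; k <- model$k_half
  stopifnot(is.numeric(response))
  if (any(response < 0)) stop("response must be >= 0")
  if (any(response >= rmax))
    stop("response outside calibration range: at or above Rmax (surface saturated)")
  k * response / (rmax - response)
}

# Infer free-analyte concentrations for a competition series and sanity-check
# the competition signal.
.competition_free <- function(experiment, calibration) {
  stopifnot(is.list(experiment),
            !is.null(experiment$analyte_total_nM),
            is.data.frame(experiment$points),
            all(c("titrant_nM", "response_RU") %in% names(experiment$points)))
  pts <- experiment$points
  if (length(unique(pts$titrant_nM)) < 6)
    stop("insufficient competition points: need >= 6 titrant concentrations including 0")
  if (!any(pts$titrant_nM == 0))
    stop("competition series must include a 0-titrant point")
  free <- invert_calibration(calibration, pts$response_RU)
  ord <- order(pts$titrant_nM)
  med <- tapply(free[ord], pts$titrant_nM[ord], mean)
  if (all(diff(med) >= 0))
    stop("no competition signal: inferred free analyte does not decrease with titrant")
  if (diff(range(free)) < 1e-12 * max(free))
    stop("no competition signal: free analyte constant across titrant series")
  data.frame(titrant_nM = pts$titrant_nM, free_nM = free)
}

# Single-site competition fit on (titrant, free analyte) pairs. When
# truncating, residuals are standardized in response units (the plateau
# artifact is additive on the chip response, while calibration inversion
# amplifies low-titrant noise in concentration units).
.fit_competition_core <- function(titrant, free, analyte_total, model_tag,
                                  truncate_high_titrant = FALSE,
                                  calibration = NULL, responses = NULL) {
  s_tot <- analyte_total
  # K_D start: titrant at half-maximal suppression of free analyte
  half <- (max(free) + min(free)) / 2
  k0 <- titrant[which.min(abs(free - half))]
  if (k0 <= 0) k0 <- stats::median(titrant[titrant > 0])
  do_fit <- function(tt, ff) {
    fit <- minpack.lm::nlsLM(
      ff ~ free_analyte_competition(s_tot, tt, kd),
      start = list(kd = k0),
      lower = c(kd = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
    kd <- unname(stats::coef(fit)[["kd"]])
    se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                   error = function(e) NA_real_)
    fitted_vals <- free_analyte_competition(s_tot, tt, kd)
    list(kd = kd, se = se, fitted = fitted_vals,
         r2 = .r_squared(ff, fitted_vals))
  }
  full <- do_fit(titrant, free)
  excluded <- 0L
  res <- full
  tt <- titrant; ff <- free
  if (truncate_high_titrant) {
    # plateau-above-zero artifact: at the top titrant concentrations the
    # inferred free analyte stalls clearly above the fitted curve; drop the
    # highest-titrant points whose standardized residuals exceed 2
    if (!is.null(calibration) && !is.null(responses)) {
      resid <- responses -
        hyperbolic_response(calibration$rmax, calibration$k_half, full$fitted)
    } else {
      resid <- ff - full$fitted
    }
    scale <- stats::mad(resid)
    if (scale == 0) scale <- stats::sd(resid)
    if (is.finite(scale) && scale > 0) {
      std <- resid / scale
      ord <- order(tt, decreasing = TRUE)
      drop_idx <- integer(0)
      for (i in ord) {          # walk down from the top titrant, stop at the
        if (std[i] > 2) drop_idx <- c(drop_idx, i) else break  # first clean point
      }
      if (length(drop_idx) > 0 && length(tt) - length(drop_idx) >= 6) {
        tt <- tt[-drop_idx]; ff <- ff[-drop_idx]
        res <- do_fit(tt, ff)
        excluded <- length(drop_idx)
      }
    }
  }
  affinity_fit(kd = res$kd, stderr = res$se, r_squared = res$r2,
               model = model_tag, n_points = length(tt),
               excluded_high_titrant = excluded,
               details = list(analyte_total_nM = s_tot,
                              titrant_nM = tt, free_nM = ff,
                              fitted_free_nM = res$fitted,
                              kd_full = full$kd))
}

#' Competition-in-solution dissociation constant
#'
#' Estimates the equilibrium dissociation constant of an analyte/titrant pair
#' from a competition-in-solution SPR experiment: mixtures containing a fixed
#' total analyte and increasing titrant are pre-equilibrated, the free
#' analyte in each mixture is read off the calibration curve, and the free
#' concentrations are fit by nonlinear least squares to the single-site
#' closed form of [free_analyte_competition()], with the analyte total fixed
#' at its known value and \eqn{K_D} the only free parameter.
#'
#' At high titrant the observed free analyte can plateau above zero because
#' soluble titrant associates weakly with the chip surface. With
#' `truncate_high_titrant = TRUE` the highest-titrant points whose
#' standardized residuals exceed 2 are excluded and the fit repeated; the
#' count of exclusions is recorded.
#'
#' @param experiment List with `analyte_total_nM` (scalar) and `points`, a
#'   data frame with columns `titrant_nM` and `response_RU`.
#' @param calibration A `hyperbolic_model` from [fit_calibration()].
#' @param truncate_high_titrant Drop plateau points at the top of the titrant
#'   series (see Details)?
#' @return An [affinity_fit()] with `model = "single_site"`.
#' @export
fit_kd_competition <- function(experiment, calibration,
                               truncate_high_titrant = FALSE) {
  dat <- .competition_free(experiment, calibration)
  .fit_competition_core(dat$titrant_nM, dat$free_nM,
                        experiment$analyte_total_nM, "single_site",
                        truncate_high_titrant, calibration,
                        experiment$points$response_RU)
}

#' Apparent dissociation constant for multi-site titrants
#'
#' Identical computation to [fit_kd_competition()], but tagged as an apparent
#' constant (\eqn{K_{Dapp}}): when the titrant carries two or three binding
#' sites of similar affinity (tandem PDZ constructs), no unique multi-site
#' equation exists, and the best single-site fit serves as a summary of the
#' overall binding behaviour.
#'
#' @inheritParams fit_kd_competition
#' @return An [affinity_fit()] with `model = "apparent"`.
#' @export
fit_kd_apparent <- function(experiment, calibration,
                            truncate_high_titrant = FALSE) {
  dat <- .competition_free(experiment, calibration)
  .fit_competition_core(dat$titrant_nM, dat$free_nM,
                        experiment$analyte_total_nM, "apparent",
                        truncate_high_titrant, calibration,
                        experiment$points$response_RU)
}

#' Conventional equilibrium SPR dissociation constant
#'
#' Fits equilibrium responses measured at a series of analyte concentrations
#' to a hyperbola; the half-saturation constant is the \eqn{K_D}. Appropriate
#' when the analyte can be applied directly to the coated chip (no bulk
#' refractive-index artifact).
#'
#' @param curve Data frame with columns `conc_nM` and `response_RU` (the
#'   equilibrium response for each analyte concentration).
#' @return An [affinity_fit()] with `model = "hyperbolic"`, `kd` the
#'   half-saturation constant and `rmax` reported.
#' @export
fit_kd_direct_spr <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("conc_nM", "response_RU") %in% names(curve)))
  h <- .fit_hyperbola(curve$conc_nM, curve$response_RU,
                      min_points = 5, what = "equilibrium SPR")
  affinity_fit(kd = h$k_half, stderr = h$se_k, r_squared = h$r_squared,
               model = "hyperbolic", n_points = h$n, rmax = h$rmax,
               details = h[c("se_rmax", "conc", "resp", "fitted")])
}

#' Avidity index of a multi-domain construct
#'
#' Ratio of the apparent affinity predicted for independent sites to the
#' measured apparent affinity. For sites with individual constants
#' \eqn{K_i}, independent binding predicts
#' \eqn{K_{pred} = 1 / \sum_i (1/K_i)}; the index is
#' \eqn{K_{pred} / K_{Dapp}}. Values near 1 indicate the construct binds as
#' its sites would independently; values well above 1 indicate avidity —
#' binding tighter than independent sites can explain.
#'
#' @param individual_kds Numeric vector of single-domain \eqn{K_D}s (nM).
#' @param kd_apparent Measured apparent \eqn{K_D} of the multi-domain
#'   construct (nM).
#' @return Dimensionless ratio.
#' @examples
#' avidity_index(c(220, 1500, 620), 74.7)  # ~1.96: substantial avidity
#' @export
avidity_index <- function(individual_kds, kd_apparent) {
  stopifnot(all(individual_kds > 0), kd_apparent > 0)
  (1 / sum(1 / individual_kds)) / kd_apparent
}
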