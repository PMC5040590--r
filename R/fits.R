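## Shared nonlinear least-squares machinery for hyperbolic and competition
## binding fits. All fits go through minpack.lm::nlsLM (Levenberg-Marquardt),
## with data-driven starting values.

#' Construct an affinity-fit result
#'
#' Container for a fitted equilibrium dissociation constant. Created by the
#' fitting functions; not usually called directly.
#'
#' @param kd Fitted dissociation constant (nM).
#' @param stderr Standard error of `kd` from the fit (nM).
#' @param r_squared Coefficient of determination of the fit.
#' @param model Tag: `"single_site"`, `"apparent"`, or `"hyperbolic"`.
#' @param n_points Number of points used in the fit.
#' @param excluded_high_titrant Number of high-titrant points excluded.
#' @param rmax Fitted maximal response, where applicable.
#' @param details List of extra per-fit diagnostics.
#' @return An object of class `affinity_fit`.
#' @export
affinity_fit <- function(kd, stderr = NA_real_, r_squared = NA_real_,
                         model = "single_site", n_points = NA_integer_,
                         excluded_high_titrant = 0L, rmax = NA_real_,
                         details = list()) {
  stopifnot(kd > 0)
  structure(list(kd = kd, stderr = stderr, r_squared = r_squared,
                 model = model, n_points = n_points,
                 excluded_high_titrant = excluded_high_titrant,
                 rmax = rmax, details = details),
            class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  lab <- switch(x$model, apparent = "K_Dapp", "K_D")
  cat(sprintf("Affinity fit (%s model)\n", x$model))
  cat(sprintf("  %s = %.4g +/- %.2g nM\n", lab, x$kd, x$stderr))
  cat(sprintf("  R^2 = %.4f on %d points", x$r_squared, x$n_points))
  if (isTRUE(x$excluded_high_titrant > 0))
    cat(sprintf(" (%d high-titrant points excluded)", x$excluded_high_titrant))
  cat("\n")
  if (is.finite(x$rmax)) cat(sprintf("  Rmax = %.4g\n", x$rmax))
  invisible(x)
}

#' @export
coef.affinity_fit <- function(object, ...) {
  c(kd = object$kd, rmax = object$rmax)
}

# r_squared of observed vs fitted
.r_squared <- function(obs, fitted) {
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  max(0, min(1, 1 - ss_res / ss_tot))
}

# Core hyperbolic fit R = rmax * C / (k + C). Returns list with rmax, k_half,
# their standard errors, r_squared and fitted values.
.fit_hyperbola <- function(conc, resp, min_points, what = "fit") {
  keep <- is.finite(conc) & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  if (length(unique(conc)) < min_points)
    stop(sprintf("insufficient %s points: need >= %d distinct concentrations, got %d",
                 what, min_points, length(unique(conc))))
  if (all(resp == 0)) stop(sprintf("all-zero responses: cannot %s", what))
  if (diff(range(resp)) == 0) stop("no saturation: all responses equal")
  rmax0 <- 1.1 * max(resp)
  half <- max(resp) / 2
  k0 <- conc[which.min(abs(resp - half))]
  if (k0 <= 0) k0 <- stats::median(conc[conc > 0])
  fit <- minpack.lm::nlsLM(
    resp ~ rmax * conc / (k + conc),
    start = list(rmax = rmax0, k = k0),
    lower = c(rmax = .Machine$double.eps, k = .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, k = NA_real_))
  fitted_vals <- cf[["rmax"]] * conc / (cf[["k"]] + conc)
  list(rmax = unname(cf[["rmax"]]), k_half = unname(cf[["k"]]),
       se_rmax = unname(se[["rmax"]]), se_k = unname(se[["k"]]),
       r_squared = .r_squared(resp, fitted_vals),
       n = length(resp), conc = conc, resp = resp, fitted = fitted_vals)
}
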