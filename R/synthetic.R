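## Seeded generators for synthetic SPR, bead-saturation and immunoblot lane
## data with the statistical structure the fitting stages assume. Every
## stochastic generator requires an explicit seed and embeds its ground
## truth in the returned object so recovery tests can check the fits without
## the fitting code ever seeing the truth.

#' Noise specification for synthetic data
#'
#' @param model `"multiplicative_gaussian"` (sigma is a relative scale) or
#'   `"additive_gaussian"` (sigma is absolute, in response units).
#' @param sigma Noise scale, `>= 0`.
#' @param seed Integer seed; mandatory for any stochastic output.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(model = c("multiplicative_gaussian", "additive_gaussian"),
                       sigma = 0.02, seed) {
  model <- match.arg(model)
  stopifnot(sigma >= 0)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory for stochastic generation")
  structure(list(model = model, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate expr with a locally-set RNG seed, restoring global RNG state;
# seed must be forced before the state snapshot (its evaluation may itself
# consume random numbers in the caller)
.with_seed <- function(seed, expr) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.apply_noise <- function(x, noise) {
  if (noise$sigma == 0) return(x)
  eps <- stats::rnorm(length(x), 0, noise$sigma)
  if (noise$model == "multiplicative_gaussian") x * (1 + eps) else x + eps
}

#' Plateau artifact specification
#'
#' Describes the high-titrant response offset caused by weak association of
#' soluble titrant with the chip surface: beyond `onset_titrant_nM`, sample
#' responses gain a constant `magnitude_RU`, so the inferred free analyte
#' plateaus above zero instead of approaching it. The defaults (3 RU from
#' 2 uM titrant) produce a deviation of a few percent of the working
#' response range, consistent with an effect small enough to shift a fitted
#' \eqn{K_D} by under ~5%.
#'
#' @param onset_titrant_nM Titrant concentration at which the offset starts.
#' @param magnitude_RU Constant response offset (RU), `>= 0`.
#' @return A `plateau_artifact` list for [gen_competition_dataset()].
#' @export
plateau_artifact <- function(onset_titrant_nM = 2000, magnitude_RU = 3) {
  stopifnot(onset_titrant_nM >= 0, magnitude_RU >= 0)
  structure(list(onset_titrant_nM = onset_titrant_nM,
                 magnitude_RU = magnitude_RU), class = "plateau_artifact")
}

#' Two-fold serial dilution design
#'
#' Concentration series produced by `n_dilutions` successive two-fold
#' dilutions of `top`, plus a 0-concentration blank.
#'
#' @param top Highest concentration (nM).
#' @param n_dilutions Number of two-fold dilution steps below `top`.
#' @return Sorted numeric vector including 0.
#' @export
serial_dilution <- function(top, n_dilutions) {
  stopifnot(top > 0, n_dilutions >= 1)
  sort(c(0, top / 2^(seq(n_dilutions, 0))))
}

#' Simulate a competition-in-solution SPR experiment
#'
#' Generates the calibration dilution series and the competition titration a
#' competition-in-solution experiment produces: calibration responses are
#' the hyperbolic chip response at each analyte concentration; sample
#' responses are the chip response at the free analyte concentration left by
#' equilibration with each titrant amount (single-site mass action with the
#' configured true \eqn{K_D}). Noise is applied to all responses; an
#' optional plateau artifact adds a constant offset beyond an onset titrant,
#' emulating weak association of soluble titrant with the chip surface.
#'
#' @param truth_kd True dissociation constant (nM).
#' @param analyte_total Fixed analyte total in the mixtures (nM; default 25).
#' @param titrant_series Titrant totals (nM); default 11 two-fold dilutions
#'   from 10 uM plus 0.
#' @param calibration_series Analyte concentrations for the standard curve
#'   (nM); default two-fold dilutions from 50 nM plus 0.
#' @param calibration_truth List with `rmax` and `k_half` of the true chip
#'   response curve.
#' @param noise A [noise_spec()].
#' @param artifact Optional list with `onset_titrant_nM` and `magnitude_RU`.
#' @return List of class `competition_sim` with `calibration` (data frame
#'   `conc_nM`, `response_RU`), `experiment` (list with `analyte_total_nM`
#'   and `points`), and `truth` (metadata; not consumed by fitting code).
#' @export
gen_competition_dataset <- function(truth_kd,
                                    analyte_total = 25,
                                    titrant_series = serial_dilution(10000, 11),
                                    calibration_series = serial_dilution(50, 6),
                                    calibration_truth = list(rmax = 120,
                                                             k_half = 40),
                                    noise = noise_spec(sigma = 0.02, seed = 1),
                                    artifact = NULL) {
  stopifnot(truth_kd > 0, analyte_total > 0)
  rmax <- calibration_truth$rmax; kh <- calibration_truth$k_half
  free <- free_analyte_competition(analyte_total, titrant_series, truth_kd)
  cal_resp <- hyperbolic_response(rmax, kh, calibration_series)
  smp_resp <- hyperbolic_response(rmax, kh, free)
  if (!is.null(artifact)) {
    stopifnot(artifact$magnitude_RU >= 0)
    hit <- titrant_series >= artifact$onset_titrant_nM
    smp_resp[hit] <- smp_resp[hit] + artifact$magnitude_RU
  }
  out <- .with_seed(noise$seed, {
    list(cal = .apply_noise(cal_resp, noise),
         smp = .apply_noise(smp_resp, noise))
  })
  structure(list(
    calibration = data.frame(conc_nM = calibration_series,
                             response_RU = pmax(out$cal, 0)),
    experiment = list(analyte_total_nM = analyte_total,
                      points = data.frame(titrant_nM = titrant_series,
                                          response_RU = pmax(out$smp, 0))),
    truth = list(kd_nM = truth_kd, analyte_total_nM = analyte_total,
                 calibration = calibration_truth, noise = unclass(noise),
                 artifact = artifact)),
    class = "competition_sim")
}

#' Simulate a saturation-binding series
#'
#' Hyperbolic saturation responses (SPR equilibrium RUs or bead-bound
#' intensities) over a concentration design, with configurable noise.
#'
#' @param truth_kd True dissociation constant (nM).
#' @param bmax Maximal response (RU or AU).
#' @param conc_series Concentration design (nM); default two-fold dilutions
#'   of 500 nM down to ~1 nM (the bead design). Use
#'   `serial_dilution(75, 5)` for a direct-SPR design.
#' @param noise A [noise_spec()].
#' @return List of class `saturation_sim` with `series` (data frame
#'   `conc_nM`, `intensity_AU`, `response_RU`) and `truth`.
#' @export
gen_saturation_dataset <- function(truth_kd, bmax = 1000,
                                   conc_series = serial_dilution(500, 9)[-1],
                                   noise = noise_spec(sigma = 0.03, seed = 1)) {
  stopifnot(truth_kd > 0)
  if (bmax <= 0) stop("bmax must be > 0")
  resp <- hyperbolic_response(bmax, truth_kd, conc_series)
  noisy <- .with_seed(noise$seed, .apply_noise(resp, noise))
  noisy <- pmax(noisy, 0)
  structure(list(
    series = data.frame(conc_nM = conc_series, intensity_AU = noisy,
                        response_RU = noisy),
    truth = list(kd_nM = truth_kd, bmax = bmax, noise = unclass(noise))),
    class = "saturation_sim")
}

#' Simulate a two-genotype immunoblot lane table
#'
#' Builds a lane table of the form the densitometry pipeline reads: for each
#' protein, WT lanes scatter around the configured base ratio and HET lanes
#' around `base * (1 + effect/100)`, with multiplicative lognormal-like
#' noise of the given coefficient of variation. Densities are decomposed
#' into target and PSD-95 signals with non-zero backgrounds so that
#' [lane_ratios()] reconstructs the configured ratios in expectation.
#'
#' @param effects Named numeric vector of percent changes (HET vs WT) per
#'   protein.
#' @param base_ratios Named numeric vector of WT mean ratios per protein
#'   (same names as `effects`).
#' @param cv Relative noise on each lane's ratio (coefficient of variation).
#' @param n_per_group Lanes per genotype per protein.
#' @param seed Integer seed.
#' @param load_ug Protein load per lane (carried into the table).
#' @return Data frame with columns `protein`, `blot_id`, `lane_id`,
#'   `genotype`, `load_ug`, `target_AU`, `target_bg_AU`, `psd95_AU`,
#'   `psd95_bg_AU`, plus attribute `truth`.
#' @export
gen_lane_table <- function(effects, base_ratios, cv = 0.15,
                           n_per_group = 6, seed, load_ug = 5) {
  stopifnot(!is.null(names(effects)), !is.null(names(base_ratios)),
            setequal(names(effects), names(base_ratios)),
            all(is.finite(effects)), all(is.finite(base_ratios)),
            cv >= 0, n_per_group >= 1)
  if (missing(seed)) stop("an integer seed is mandatory")
  proteins <- names(effects)
  .with_seed(seed, {
    rows <- lapply(proteins, function(p) {
      means <- c(WT = base_ratios[[p]],
                 HET = base_ratios[[p]] * (1 + effects[[p]] / 100))
      do.call(rbind, lapply(c("WT", "HET"), function(g) {
        ratio <- means[[g]] * (1 + cv * stats::rnorm(n_per_group))
        ratio <- pmax(ratio, 0)
        psd95_net <- 1e5 * (1 + 0.05 * stats::rnorm(n_per_group))
        target_bg <- 500 * stats::runif(n_per_group, 0.5, 1.5)
        psd95_bg <- 2000 * stats::runif(n_per_group, 0.5, 1.5)
        data.frame(protein = p,
                   blot_id = paste0("blot1_", p),
                   lane_id = paste0(g, seq_len(n_per_group)),
                   genotype = g,
                   load_ug = load_ug,
                   target_AU = ratio * psd95_net + target_bg,
                   target_bg_AU = target_bg,
                   psd95_AU = psd95_net + psd95_bg,
                   psd95_bg_AU = psd95_bg)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(effects = effects, base_ratios = base_ratios,
                               cv = cv, n_per_group = n_per_group, seed = seed)
    out
  })
}
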