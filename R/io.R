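## CSV/YAML/JSON plumbing. All interchange is plain text: CSV with explicit
## headers for tabular data, YAML for scenario configuration, JSON for fit
## reports and manifests. Concentrations are serialized in nM; an optional
## `units` column ("nM" or "uM") is honoured at parse time.

.check_columns <- function(df, required, path, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("malformed %s file '%s': missing column(s) %s",
                 what, path, paste(missing_cols, collapse = ", ")))
  invisible(df)
}

.apply_units <- function(df, conc_cols) {
  if ("units" %in% names(df)) {
    fac <- ifelse(df$units %in% c("uM", "µM"), 1000,
                  ifelse(df$units == "nM", 1, NA))
    if (any(is.na(fac))) stop("unrecognized units (expected nM or uM)")
    for (cc in conc_cols) df[[cc]] <- df[[cc]] * fac
    df$units <- NULL
  }
  df
}

#' Read an SPR calibration CSV
#'
#' Expected columns: `conc_nM`, `response_RU` (optional `units`).
#' @param path File path.
#' @return Data frame ready for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("conc_nM", "response_RU"), path, "calibration")
  .apply_units(df, "conc_nM")
}

#' Write an SPR calibration CSV
#' @param series Data frame with `conc_nM`, `response_RU`.
#' @param path File path.
#' @export
write_calibration_csv <- function(series, path) {
  utils::write.csv(series[c("conc_nM", "response_RU")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a competition-series CSV
#'
#' Expected columns: `titrant_nM`, `response_RU`; the fixed analyte total is
#' carried in a metadata header line `# analyte_total_nM: <value>`.
#' @param path File path.
#' @return List with `analyte_total_nM` and `points`, as consumed by
#'   [fit_kd_competition()].
#' @export
read_competition_csv <- function(path) {
  header <- readLines(path, n = 5)
  meta <- grep("^#\\s*analyte_total_nM\\s*:", header, value = TRUE)
  if (!length(meta))
    stop(sprintf("malformed competition file '%s': missing '# analyte_total_nM:' header line",
                 path))
  analyte_total <- as.numeric(sub("^#\\s*analyte_total_nM\\s*:\\s*", "", meta[1]))
  if (!is.finite(analyte_total) || analyte_total <= 0)
    stop("invalid analyte_total_nM in competition file header")
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("titrant_nM", "response_RU"), path, "competition")
  df <- .apply_units(df, "titrant_nM")
  list(analyte_total_nM = analyte_total, points = df)
}

#' Write a competition-series CSV
#' @param experiment List with `analyte_total_nM` and `points`.
#' @param path File path.
#' @export
write_competition_csv <- function(experiment, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# analyte_total_nM: %g", experiment$analyte_total_nM), con)
  utils::write.csv(experiment$points[c("titrant_nM", "response_RU")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a saturation-series CSV (`conc_nM`, `intensity_AU`)
#' @param path File path.
#' @return Data frame for [fit_kd_saturation()].
#' @export
read_saturation_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("conc_nM", "intensity_AU"), path, "saturation")
  .apply_units(df, "conc_nM")
}

#' Write a saturation-series CSV
#' @param series Data frame with `conc_nM`, `intensity_AU`.
#' @param path File path.
#' @export
write_saturation_csv <- function(series, path) {
  utils::write.csv(series[c("conc_nM", "intensity_AU")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a resin-binding CSV (`condition`, `replicate`, `intensity_AU`)
#' @param path File path.
#' @return Data frame for [compare_resin_binding()].
#' @export
read_resin_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("condition", "replicate", "intensity_AU"), path, "resin")
  df
}

#' Read an immunoblot lane-table CSV
#'
#' Expected columns: `blot_id`, `lane_id`, `genotype`, `load_ug`,
#' `target_AU`, `target_bg_AU`, `psd95_AU`, `psd95_bg_AU`.
#' @param path File path.
#' @return Data frame for [lane_ratios()].
#' @export
read_lanes_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("blot_id", "lane_id", "genotype", "load_ug",
                       "target_AU", "target_bg_AU", "psd95_AU", "psd95_bg_AU"),
                 path, "lanes")
  df
}

#' Write an immunoblot lane-table CSV
#' @param lanes Lane data frame.
#' @param path File path.
#' @export
write_lanes_csv <- function(lanes, path) {
  keep <- intersect(c("protein", "blot_id", "lane_id", "genotype", "load_ug",
                      "target_AU", "target_bg_AU", "psd95_AU", "psd95_bg_AU"),
                    names(lanes))
  utils::write.csv(lanes[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a slot-model scenario from YAML
#'
#' Schema: top-level keys `psd95_copies`, `genotype` (`WT`/`HET`),
#' `conditions` (list of flags), `volume_fL`, and `ligands`, a list of maps
#' each with `name`, `copies`, `kd` (map of site name to nM) and optional
#' `modifiers` (map of condition flag to fold-factor or map of site to
#' factor). Validation failures name the offending field.
#'
#' @param path YAML file path.
#' @return A `slot_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ligands) || !length(cfg$ligands))
    stop(sprintf("scenario '%s': 'ligands' list is missing or empty", path))
  ligands <- lapply(seq_along(cfg$ligands), function(i) {
    l <- cfg$ligands[[i]]
    for (fld in c("name", "copies", "kd"))
      if (is.null(l[[fld]]))
        stop(sprintf("scenario '%s': ligands[%d] is missing '%s'", path, i, fld))
    mods <- lapply(l$modifiers %||% list(), function(m)
      if (is.list(m)) unlist(m) else m)
    ligand_spec(l$name, l$copies, unlist(l$kd), mods)
  })
  slot_scenario(ligands,
                psd95_copies = cfg$psd95_copies %||% 300,
                genotype = cfg$genotype %||% "WT",
                conditions = as.character(cfg$conditions %||% character()),
                volume_fL = cfg$volume_fL %||% 0.5,
                haplo_ligand = cfg$haplo_ligand %||% "synGAP")
}

#' Write a slot-model scenario to YAML
#' @param scenario A `slot_scenario`.
#' @param path Output path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  cfg <- list(
    psd95_copies = scenario$psd95_copies,
    genotype = scenario$genotype,
    conditions = as.list(scenario$conditions),
    volume_fL = scenario$volume_fL,
    haplo_ligand = scenario$haplo_ligand,
    ligands = lapply(unname(scenario$ligands), function(l) {
      out <- list(name = l$name, copies = l$copies, kd = as.list(l$kd))
      if (length(l$modifiers)) out$modifiers <- lapply(l$modifiers, as.list)
      out
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an affinity fit as a JSON report
#' @param fit An `affinity_fit`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
fit_report_json <- function(fit, path = NULL) {
  rep <- list(kd_nM = fit$kd, stderr_nM = fit$stderr,
              r_squared = fit$r_squared, model = fit$model,
              n_points = fit$n_points,
              excluded_high_titrant = fit$excluded_high_titrant)
  if (is.finite(fit$rmax)) rep$rmax <- fit$rmax
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
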