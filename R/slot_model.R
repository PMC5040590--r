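## Scenario engine for the PDZ "slot" competition model: occupancy of the
## three PDZ domains of PSD-95 by synGAP-alpha1 and competing synaptic
## proteins under wild-type, phosphorylated, calmodulin-bound, and
## haploinsufficient conditions.

# Avogadro-based copies <-> nM conversion inside a reference volume (fL):
# 1 copy in 1 fL = 1/(6.022e23 * 1e-15) M = 1.6605 nM
.copies_to_nM <- function(copies, volume_fL) 1.66053907e0 * copies / volume_fL

#' Define a ligand of the slot model
#'
#' @param name Ligand name (e.g. `"synGAP"`, `"TARP"`).
#' @param copies Total copies of the ligand per PSD.
#' @param kd Named numeric vector of dissociation constants (nM) keyed by
#'   site-class name; omit a site to encode "does not bind".
#' @param modifiers Named list of condition flags mapping to multiplicative
#'   \eqn{K_D} fold-factors. Each entry is either a single number (applied to
#'   every site the ligand binds) or a named vector of per-site factors.
#' @return A `ligand_spec` list.
#' @export
ligand_spec <- function(name, copies, kd, modifiers = list()) {
  stopifnot(is.character(name), copies >= 0, all(kd > 0),
            !is.null(names(kd)))
  if (length(modifiers) && any(unlist(modifiers) <= 0))
    stop("modifier fold-factors must be > 0")
  structure(list(name = name, copies = copies, kd = kd,
                 modifiers = modifiers), class = "ligand_spec")
}

#' Build a slot-model scenario
#'
#' A scenario bundles the ligands, the PDZ site classes, and the condition
#' flags to be applied before solving the competitive equilibrium. The three
#' site classes (PDZ1, PDZ2, PDZ3) each carry one copy per PSD-95 molecule.
#'
#' Condition flags act through ligand `modifiers`: a flag named in a ligand's
#' modifier list multiplies that ligand's \eqn{K_D}s by the configured
#' fold-factor (weakening binding when the factor exceeds 1). The `HET`
#' genotype halves the total of the `haplo_ligand` (synGAP by default) and
#' changes nothing else.
#'
#' @param ligands List of [ligand_spec()] objects.
#' @param psd95_copies Copies of PSD-95 per PSD (default 300).
#' @param genotype `"WT"` or `"HET"`.
#' @param conditions Character vector of active condition flags (e.g.
#'   `"phospho_camkii"`).
#' @param volume_fL Reference volume of the PSD compartment in femtoliters,
#'   used only to convert copies to concentrations; fractional occupancies
#'   are invariant to it.
#' @param haplo_ligand Name of the ligand halved under `HET`.
#' @return A `slot_scenario` list.
#' @export
slot_scenario <- function(ligands, psd95_copies = 300,
                          genotype = c("WT", "HET"),
                          conditions = character(),
                          volume_fL = 0.5,
                          haplo_ligand = "synGAP") {
  genotype <- match.arg(genotype)
  stopifnot(psd95_copies > 0, volume_fL > 0)
  if (inherits(ligands, "ligand_spec")) ligands <- list(ligands)
  nms <- vapply(ligands, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate ligand names")
  names(ligands) <- nms
  site_names <- c("PDZ1", "PDZ2", "PDZ3")
  bad <- setdiff(unique(unlist(lapply(ligands, function(l) names(l$kd)))),
                 site_names)
  if (length(bad))
    stop("unknown site class(es): ", paste(bad, collapse = ", "),
         " (expected PDZ1, PDZ2, PDZ3)")
  structure(list(ligands = ligands, psd95_copies = psd95_copies,
                 genotype = genotype, conditions = conditions,
                 volume_fL = volume_fL, haplo_ligand = haplo_ligand),
            class = "slot_scenario")
}

#' Default scenario: synGAP-alpha1 competing with synaptic membrane proteins
#'
#' Ships the package's reference parameterization of the slot model.
#' SynGAP-alpha1 binds all three PDZ domains with its measured dissociation
#' constants (220, 1500 and 620 nM for PDZ1, PDZ2 and PDZ3); its copy number
#' defaults to 40% of PSD-95 (the middle of the 30-50% abundance range of
#' the alpha1 isoforms). TARPs and LRRTM2 compete at PDZ1/PDZ2;
#' neuroligin-1 and neuroligin-2 compete at PDZ3. Competitor affinities and
#' copy numbers are illustrative placeholders — they are not measured values
#' and exist so the directional behaviour of the model can be exercised;
#' override them for any quantitative use.
#'
#' Modifier defaults: CaMKII phosphorylation weakens synGAP tenfold at all
#' three sites; PLK2 phosphorylation is shipped at twofold (the underlying
#' measurement is a bound-fraction reduction, so the fold-factor is a free
#' parameter); calmodulin binding weakens the PDZ3 interaction only.
#'
#' @inheritParams slot_scenario
#' @param syngap_copies Copies of synGAP-alpha1 per PSD.
#' @param plk2_fold Fold-factor for the `phospho_plk2` flag.
#' @return A `slot_scenario`.
#' @export
default_scenario <- function(genotype = "WT", conditions = character(),
                             psd95_copies = 300,
                             syngap_copies = 0.4 * psd95_copies,
                             plk2_fold = 2,
                             volume_fL = 0.5) {
  ligands <- list(
    ligand_spec("synGAP", syngap_copies,
                kd = c(PDZ1 = 220, PDZ2 = 1500, PDZ3 = 620),
                modifiers = list(phospho_camkii = 10,
                                 phospho_plk2 = plk2_fold,
                                 cam_bound = c(PDZ3 = 1.33))),
    # competitor parameters below are illustrative placeholders
    ligand_spec("TARP",   150, kd = c(PDZ1 = 1000, PDZ2 = 1000)),
    ligand_spec("LRRTM2",  60, kd = c(PDZ1 = 1500, PDZ2 = 1500)),
    ligand_spec("NLG1",    60, kd = c(PDZ3 = 500)),
    ligand_spec("NLG2",    40, kd = c(PDZ3 = 1000)))
  slot_scenario(ligands, psd95_copies = psd95_copies, genotype = genotype,
                conditions = conditions, volume_fL = volume_fL)
}

# Effective (condition-modified) KD matrix and ligand totals, in nM
.scenario_inputs <- function(sc) {
  site_names <- c("PDZ1", "PDZ2", "PDZ3")
  nl <- length(sc$ligands)
  K <- matrix(Inf, nl, 3, dimnames = list(names(sc$ligands), site_names))
  totals <- numeric(nl); names(totals) <- names(sc$ligands)
  for (l in sc$ligands) {
    K[l$name, names(l$kd)] <- l$kd
    for (cond in sc$conditions) {
      fac <- l$modifiers[[cond]]
      if (is.null(fac)) next
      if (is.null(names(fac))) {
        K[l$name, names(l$kd)] <- K[l$name, names(l$kd)] * fac
      } else {
        K[l$name, names(fac)] <- K[l$name, names(fac)] * fac
      }
    }
    totals[l$name] <- .copies_to_nM(l$copies, sc$volume_fL)
  }
  if (sc$genotype == "HET") {
    if (!sc$haplo_ligand %in% names(totals))
      stop("haplo_ligand not present in scenario")
    totals[sc$haplo_ligand] <- 0.5 * totals[sc$haplo_ligand]
  }
  sites <- rep(.copies_to_nM(sc$psd95_copies, sc$volume_fL), 3)
  names(sites) <- site_names
  list(ligand_totals = totals, site_totals = sites, kd = K)
}

#' Solve a slot-model scenario
#'
#' Applies the scenario's condition flags and genotype, converts copies to
#' concentrations within the reference volume, and solves the multi-ligand
#' mass-action equilibrium. Occupancies are reported both in copies per PSD
#' and as fractions of each site class.
#'
#' @param scenario A `slot_scenario`.
#' @param ... Passed to [solve_multi_ligand_equilibrium()] (`tol`, etc.).
#' @return List of class `slot_solution`: `state` (the raw
#'   `equilibrium_state`), `bound_copies` (ligand x site), `occupancy`
#'   (fractional), `free_copies`, `total_bound_copies` per ligand,
#'   `per_psd95` (bound copies / PSD-95 copies) and the `scenario`.
#' @export
solve_scenario <- function(scenario, ...) {
  stopifnot(inherits(scenario, "slot_scenario"))
  inp <- .scenario_inputs(scenario)
  st <- solve_multi_ligand_equilibrium(inp$ligand_totals, inp$site_totals,
                                       inp$kd, ...)
  nm_per_copy <- .copies_to_nM(1, scenario$volume_fL)
  bound_copies <- st$bound / nm_per_copy
  total_bound <- rowSums(bound_copies)
  structure(list(state = st,
                 bound_copies = bound_copies,
                 occupancy = st$occupancy,
                 free_copies = st$free / nm_per_copy,
                 total_bound_copies = total_bound,
                 per_psd95 = total_bound / scenario$psd95_copies,
                 scenario = scenario),
            class = "slot_solution")
}

#' @export
print.slot_solution <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Slot-model solution [%s%s]\n", sc$genotype,
              if (length(sc$conditions))
                paste0(" + ", paste(sc$conditions, collapse = ", ")) else ""))
  cat("Bound copies per PSD (ligand x site):\n")
  print(round(x$bound_copies, 1))
  cat("Fractional site occupancy:\n")
  print(round(x$occupancy, 3))
  cat("Bound per PSD-95 molecule:",
      paste(sprintf("%s=%.3f", names(x$per_psd95), x$per_psd95),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare two slot-model scenarios
#'
#' Solves both scenarios and reports, per ligand, the change in bound copies
#' (absolute and percent) and in the bound-to-PSD-95 ratio — the same ratio
#' scale on which immunoblot composition measurements are reported.
#'
#' @param a,b `slot_scenario` objects over the same ligand and site universe.
#' @param ... Passed to [solve_scenario()].
#' @return List of class `slot_comparison` with `table` (data frame of
#'   per-ligand changes, b relative to a) and the two solutions.
#' @export
compare_scenarios <- function(a, b, ...) {
  stopifnot(inherits(a, "slot_scenario"), inherits(b, "slot_scenario"))
  if (!identical(sort(names(a$ligands)), sort(names(b$ligands))))
    stop("scenarios have different ligand universes")
  if (a$psd95_copies != b$psd95_copies)
    stop("scenarios have different site universes (PSD-95 copies differ)")
  sol_a <- solve_scenario(a, ...); sol_b <- solve_scenario(b, ...)
  lig <- names(a$ligands)
  ba <- sol_a$total_bound_copies[lig]; bb <- sol_b$total_bound_copies[lig]
  tab <- data.frame(
    ligand = lig,
    bound_a = ba, bound_b = bb,
    delta_copies = bb - ba,
    percent_change = ifelse(ba > 0, 100 * (bb - ba) / ba, NA_real_),
    per_psd95_a = sol_a$per_psd95[lig],
    per_psd95_b = sol_b$per_psd95[lig],
    row.names = NULL)
  structure(list(table = tab, solution_a = sol_a, solution_b = sol_b),
            class = "slot_comparison")
}

#' @export
print.slot_comparison <- function(x, ...) {
  cat("Composition shift (scenario b relative to a):\n")
  tab <- x$table
  tab$percent_change <- round(tab$percent_change, 1)
  tab[c("bound_a", "bound_b", "delta_copies")] <-
    lapply(tab[c("bound_a", "bound_b", "delta_copies")], round, 1)
  tab[c("per_psd95_a", "per_psd95_b")] <-
    lapply(tab[c("per_psd95_a", "per_psd95_b")], round, 3)
  print(tab)
  invisible(x)
}

#' Fraction of PDZ domains a ligand could occupy
#'
#' Back-of-envelope interval for the fraction of all PDZ slots a ligand
#' could fill, assuming one slot per ligand molecule:
#' \deqn{f = \alpha \cdot N_{ligand} / (N_{PSD95} \cdot n_{PDZ})}
#' evaluated over an interval of the isoform fraction \eqn{\alpha}.
#'
#' With 300 PSD-95 molecules (900 PDZ domains), a ligand as abundant as
#' PSD-95 itself of which 30-50% carries the PDZ-binding isoform could fill
#' 10-16.7% of the slots.
#'
#' @param psd95_copies PSD-95 copies per PSD.
#' @param pdz_per_psd95 PDZ domains per PSD-95 molecule (3).
#' @param ligand_total_copies Total copies of the ligand (all isoforms).
#' @param isoform_fraction Length-2 numeric interval in `[0, 1]`: fraction of
#'   the ligand carrying the PDZ-binding isoform.
#' @return Numeric length-2 vector `c(lo, hi)` of occupancy fractions.
#' @examples
#' occupancy_fraction_estimate(300, 3, 300, c(0.3, 0.5))  # 0.100 0.167
#' @export
occupancy_fraction_estimate <- function(psd95_copies, pdz_per_psd95,
                                        ligand_total_copies,
                                        isoform_fraction) {
  stopifnot(psd95_copies > 0, pdz_per_psd95 > 0, ligand_total_copies >= 0,
            length(isoform_fraction) == 2,
            all(isoform_fraction >= 0), all(isoform_fraction <= 1),
            isoform_fraction[1] <= isoform_fraction[2])
  f <- isoform_fraction * ligand_total_copies /
    (psd95_copies * pdz_per_psd95)
  c(lo = f[1], hi = f[2])
}
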