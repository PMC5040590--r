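---
title: "Quantifying competition for the PDZ slots of PSD-95"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying competition for the PDZ slots of PSD-95}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzslots)
```

## The scientific problem

PSD-95, the principal scaffold of the postsynaptic density (PSD), carries
three PDZ domains that act as mutually exclusive docking "slots" for the
C-terminal ligands of several synaptic proteins: TARPs and LRRTMs (which
travel with AMPA receptors) and neuroligins at the membrane, and the
cytosolic Ras/Rap GTPase-activating protein synGAP-α1. An average PSD holds
roughly 300 PSD-95 molecules — 900 slots — and synGAP is nearly as abundant
as PSD-95 itself, with 30–50% of it carrying the PDZ ligand. Because each
slot binds one protein at a time, the composition of the PSD is a problem
of linked, multiple equilibria: it is set jointly by the concentrations of
all the ligands and their affinities for each slot class.

`pdzslots` implements the quantitative toolchain for this problem:

1. **Affinity estimation** from competition-in-solution surface plasmon
   resonance (SPR), conventional equilibrium SPR, and bead-saturation
   assays.
2. **A mass-action slot-competition solver** that turns copy numbers and
   dissociation constants into occupancy predictions under perturbations —
   kinase phosphorylation of synGAP-α1, calmodulin binding, or
   haploinsufficiency (loss of one *Syngap* gene copy).
3. **Densitometry statistics** for immunoblot measurements of PSD
   composition in wild-type versus haploinsufficient tissue.
4. **Seeded synthetic-data generators** so every stage is testable
   end-to-end without instrument data.

## Competition-in-solution affinity estimation

Applying a large, viscous analyte directly to an SPR chip produces bulk
refractive-index artifacts. The competition-in-solution method avoids this:
mixtures containing a fixed analyte total $S$ (25 nM) and increasing
titrant totals $P$ are pre-equilibrated, and the chip (coated with the
titrant protein) is used only to *measure the free analyte* left in each
mixture. For a single binding site with dissociation constant $K_D$, mass
action gives the free analyte in closed form,

$$
S_{\mathrm{free}} \;=\; \frac{S - P - K_D}{2}
 \;+\; \sqrt{\frac{(S + P + K_D)^2}{4} - S\,P},
$$

the positive branch being the only root inside $[0, S]$
(`free_analyte_competition()`). Internally the package evaluates the
algebraically identical rationalized form
$S_\mathrm{free} = 2 K_D S / \left(q + \sqrt{q^2 + 4 K_D S}\right)$ with
$q = P - S + K_D$, which avoids catastrophic cancellation when titrant is
in large excess and $S_\mathrm{free} \ll S$.

The pipeline is:

* `fit_calibration()` — fit the dilution-series responses (0–50 nM analyte,
  two-fold steps plus blank) to the hyperbola $R = R_{max} C/(K_{1/2}+C)$;
* `invert_calibration()` — map each mixture's response back to a free
  concentration, $C = K_{1/2} R / (R_{max} - R)$;
* `fit_kd_competition()` — nonlinear least squares of the free
  concentrations against the closed form above, with $S$ fixed at its known
  value and $K_D$ the only free parameter.

```{r competition-example}
sim <- gen_competition_dataset(220, noise = noise_spec(sigma = 0.02, seed = 7))
cal <- fit_calibration(sim$calibration)
fit_kd_competition(sim$experiment, cal)
```

Least squares is solved by Levenberg–Marquardt (via `minpack.lm`), started
from data-driven values: $K_{D,0}$ at the titrant concentration of
half-maximal suppression of the free analyte, $R_{max,0} = 1.1 \times$ the
maximum response. The objective is unweighted and on the free-analyte scale
(the variables of the closed form), not on the log-titrant axis used only
for plotting. Replicates at a titrant concentration enter as independent
points rather than being pre-averaged, preserving the error structure.
Reference/blank subtraction is assumed already applied to input responses.

### Apparent constants and avidity

Tandem constructs carrying two or three PDZ domains of similar affinity
admit no unique multi-site equation, so the single-site fit serves as a
summary: `fit_kd_apparent()` performs the identical computation and tags
the result $K_{Dapp}$. If the domains acted independently, the apparent
constant would approach the harmonic combination
$K_{pred} = 1/\sum_i (1/K_i)$; `avidity_index()` reports
$K_{pred}/K_{Dapp}$, so values well above 1 diagnose avidity — binding
tighter than independent sites can explain. For the three single-domain
constants 220, 1500 and 620 nM, $K_{pred} \approx 146.5$ nM, so a measured
$K_{Dapp}$ of 74.7 nM corresponds to an index of ≈1.96.

### High-titrant truncation

At high titrant concentrations soluble titrant can associate weakly with
the chip-bound titrant, so the inferred free analyte plateaus above zero.
With `truncate_high_titrant = TRUE`, the fit drops the highest-titrant
points whose standardized residuals exceed 2 and records the count.
Residuals are standardized in *response* units with a robust (MAD) scale:
the artifact is additive on the chip response, whereas calibration
inversion amplifies low-titrant noise on the concentration scale and would
otherwise mask it. On synthetic data with the artifact enabled
(`plateau_artifact()`: +3 RU beyond 2 µM titrant, a deviation of a few
percent of the working response range), truncated and full fits agree to
within ~5% — the artifact is a nuisance, not a driver, of the estimate.

## Saturation fits

`fit_kd_direct_spr()` (equilibrium responses vs analyte concentration) and
`fit_kd_saturation()` (bead-bound intensities vs input concentration) share
the hyperbolic core, so identical inputs give identical fits. The bead
assay neglects ligand depletion, justified when protein input is far
(20–3000-fold) below the resin capacity; passing `resin_capacity_nM`
enables a warning whenever the predicted bound fraction of input exceeds
10%. A series that never bends over (no concentration above the fitted
$K_D$) triggers an identifiability warning and is reported as a lower
bound.

## The multi-ligand slot solver

For ligands $i$ with free concentrations $F_i$ and site classes $j$ with
totals $T_j$, single-occupancy mass action gives

$$
\mathrm{bound}_{ij} = T_j\,\frac{F_i/K_{ij}}{1 + \sum_k F_k/K_{kj}},
\qquad
F_i = L_i - \sum_j \mathrm{bound}_{ij}.
$$

`solve_multi_ligand_equilibrium()` solves for all $F_i$ by a damped
fixed-point iteration on $F_i = L_i / \left(1 + \sum_j T_j/(K_{ij} D_j)\right)$
with $D_j = 1 + \sum_k F_k/K_{kj}$ (damping 0.5, relative tolerance
$10^{-10}$, at most 10,000 iterations), followed by Gauss–Seidel sweeps of
a per-ligand Newton solve of the conservation equation. The Newton polish
is quadratically convergent and keeps the free pools accurate to machine
precision even when they are many orders of magnitude below the totals
(stiff nM-vs-µM affinity ratios), which the damped iteration alone cannot
guarantee. Uniqueness: each update map is monotone decreasing in the
competitor free pools and the system is a contraction on
$\prod_i [0, L_i]$, so the fixed point is unique and independent of
initialization; the one-ligand case agrees with the closed form to
machine precision. "Does not bind" is encoded as an absent (or `Inf`/`NA`)
entry rather than a sentinel number. Non-convergence raises an error
carrying the residual.

## Scenario engine

`slot_scenario()` bundles ligands (copies per PSD, per-site $K_D$s,
condition modifiers), the PSD-95 copy number (default 300, giving three
slot classes of 300 copies each), a genotype flag, and active conditions.
Copies convert to concentrations inside a configurable reference volume
(default 0.5 fL, chosen so that 300 copies ≈ 1 µM — the concentration
scale of a spine-sized compartment). The volume is a free parameter:
absolute occupancies depend on it, but *fractional* occupancies are
invariant to jointly rescaling all concentrations and constants, which is
why model conclusions are stated as fractions and directions of change.

Defaults shipped in `default_scenario()`:

* synGAP-α1: 120 copies (40% of PSD-95, the middle of the 30–50% abundance
  range) binding PDZ1/PDZ2/PDZ3 at 220/1500/620 nM — the measured
  constants.
* Competitors (TARP, LRRTM2, neuroligin-1, neuroligin-2) with the
  established binding topology — TARP/LRRTM2 at PDZ1/2, neuroligins at
  PDZ3 — but **illustrative placeholder** copies and affinities, since
  measured values are not available here. They exist to exercise the
  directional behaviour of the model and must be overridden for
  quantitative use (see `inst/extdata/example_scenario_*.yaml`).
* Modifiers: CaMKII phosphorylation multiplies synGAP's $K_D$ tenfold at
  all three sites (the measured apparent-affinity shift). Calmodulin
  binding applies only to PDZ3, default fold 1.33 (a ~25% affinity
  reduction). PLK2 is shipped at twofold and explicitly user-settable: the
  underlying observation is a ~40% reduction in *bound fraction* on resin,
  and mapping a bound-fraction change to a fold-factor depends on assay
  occupancy, so no single value is defensible.
* `HET` genotype halves the synGAP total and changes nothing else.

```{r scenario-example}
compare_scenarios(default_scenario("WT"), default_scenario("HET"))$table
```

Any intervention that weakens or reduces synGAP (halving its copies, a
phosphorylation fold-factor above 1, deleting its ligand) frees slots, so
every competitor's occupancy rises or stays equal — a directional
prediction that holds for any positive competitor parameters, which is
what makes the placeholder defaults usable for sign-level conclusions.

## Densitometry statistics

Immunoblot lanes are normalized within-lane: `lane_ratios()` computes
(target − background)/(PSD-95 − background), flagging lanes with
non-positive net PSD-95 signal invalid. `exclude_outliers()` screens each
genotype group once: only the single most deviant value is a candidate,
and it is excluded when it lies more than $k = 2$ spread units from the
group mean. The spread is the standard deviation of the *remaining* values
(leave-one-out), since a gross outlier inflates the group's own SD enough
to mask itself; the default SD interpretation is used because the stricter
SE reading (SD/√n) would exclude implausibly many lanes. At most one value
is excluded per group per pass.

`compare_groups()` runs the declared one-tailed test — synGAP is tested
WT > HET, the competitors HET > WT, matching the direction the slot model
predicts — in Welch, pooled-variance, or paired form (Welch–Satterthwaite
degrees of freedom for Welch), and reports Cohen's d on the pooled SD and
the percent change of the HET mean relative to WT. Percent changes are
rounded to the nearest integer with halves away from zero (−23.5 → −24).
No multiple-testing correction is applied across proteins, and the report
notes that lanes are technical replicates of one pooled preparation per
genotype — the statistics quantify measurement precision, not
animal-to-animal variability.

## Synthetic data: what it does and does not emulate

Generators (`gen_competition_dataset()`, `gen_saturation_dataset()`,
`gen_lane_table()`) produce data with the structure each stage assumes:
hyperbolic chip responses, single-site competition with a known true
$K_D$, and two-genotype lane tables whose expected ratios differ by a
configured effect. Noise defaults are multiplicative Gaussian — σ = 2% of
response for SPR, 3% for bead intensities, lane coefficients of variation
set per use — chosen as plausible instrument scales and explicitly
configurable. Every stochastic generator requires a seed, is bytewise
reproducible given one, restores the caller's RNG state, and embeds its
ground truth in metadata consumed only by tests, never by fitting code.

Simulated designs follow the published assays: two-fold dilution series
with blanks (calibration 0–50 nM; titrant to 10 µM, or 80 µM for the
three-domain construct; bead 1–500 nM; direct SPR 0–75 nM), 25 nM fixed
analyte, and the replication at which constants were reported (2–4
experiments averaged, triplicate injections for direct SPR). What passing
recovery tests demonstrate is that the estimation pipeline is unbiased and
precise *under the assumed error model*; real sensorgrams add kinetic
transients, drift, regeneration artifacts and bulk refractive-index
effects that are not modeled (only their equilibrium-plateau consequence,
the high-titrant plateau artifact, is). Lane tables use a single
coefficient of variation per protein, not the heteroscedastic blot-to-blot
structure of real immunoblots.

## Numerical and design choices

* Concentrations are nM everywhere internally; µM columns are converted at
  the I/O boundary (`units` column).
* The physical (+) root of the competition quadratic is asserted to lie in
  $[0, S]$; a negative discriminant is treated as an internal fault, not
  user error, since it is algebraically impossible for valid inputs.
* Hyperbolic and competition fits run Levenberg–Marquardt to tight
  (`1e-14`) convergence so that noiseless round trips recover truth to
  relative $10^{-6}$ or better.
* Problem sizes in the shipped tests — 13-point titrations, $10^4$-draw
  oracle grids, $10^3$-draw property suites — keep the full suite under a
  minute while giving the property tests real coverage.
* Degenerate inputs fail loudly and specifically: no competition signal,
  response at/above $R_{max}$, insufficient points, zero variance in all
  groups, pairing mismatches, unknown site classes, non-convergence.

## Known limitations

* Equilibrium only: no association/dissociation kinetics, dwell times, or
  time-resolved sensorgram modeling.
* Avidity is diagnosed (index above 1), not modeled mechanistically; the
  apparent constant may be used as a coarse single-ligand
  parameterization of a multivalent construct and is flagged as such.
* The slot model has no spatial structure: slots within and across PSD-95
  molecules are equivalent, and trans-synaptic interactions (neurexin
  binding of LRRTMs/neuroligins) are outside scope.
* Competitor copy numbers and affinities are placeholders; quantitative
  occupancy numbers from the default scenario should not be quoted, only
  fractions and directions.
* Two cells of the published affinity table (the phosphorylated and
  phosphomimetic three-domain constructs) conflict with the fold-changes
  stated in the accompanying text; the package therefore never hard-codes
  them — phosphorylation enters only through user-settable fold-factors.
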