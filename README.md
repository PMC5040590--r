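# pdzslots

Quantitative analysis of competition among synaptic proteins for the three
PDZ-domain "slots" of PSD-95, the principal scaffold of the postsynaptic
density (PSD).

Each PDZ domain of PSD-95 binds one protein at a time, so PSD composition
is a problem of linked, multiple equilibria among the proteins that carry
PDZ ligands: synGAP-α1, TARPs, LRRTMs and neuroligins. `pdzslots` is for
researchers who need to (i) estimate equilibrium dissociation constants
from SPR and bead-binding assays, (ii) predict how PSD composition shifts
when synGAP-α1 is phosphorylated, calmodulin-bound, or reduced by
haploinsufficiency, and (iii) test composition differences measured by
immunoblot densitometry.

## What it computes

**Competition-in-solution K_D.** Mixtures of a fixed analyte total *S*
(25 nM) and increasing titrant totals *P* are pre-equilibrated; the chip
measures only the remaining free analyte. For a single site,

    S_free = (S − P − K_D)/2 + sqrt((S + P + K_D)²/4 − S·P)

and K_D is fit by nonlinear least squares to free concentrations read off
a hyperbolic calibration curve (R = Rmax·C/(K½ + C), inverted as
C = K½·R/(Rmax − R)). Multi-domain titrants get an apparent constant
K_Dapp from the same fit; the avidity index
(1/Σ 1/K_i)/K_Dapp diagnoses tighter-than-independent binding.

**Saturation fits.** Conventional equilibrium SPR and bead-saturation
series share one hyperbolic core; K_D is the half-saturation constant.

**Slot competition model.** For ligands *i* and site classes *j*,

    bound_ij = T_j · (F_i/K_ij) / (1 + Σ_k F_k/K_kj),   F_i = L_i − Σ_j bound_ij

solved by damped fixed point with per-ligand Newton polish. Scenarios map
copies per PSD (300 PSD-95 → 900 slots) to concentrations in a reference
volume and apply condition flags: CaMKII phosphorylation (K_D ×10), CaM
binding (PDZ3 only), HET genotype (synGAP ×0.5).

**Densitometry statistics.** Per-lane target:PSD-95 ratios, a
one-outlier-per-group screen, one-tailed Welch/pooled/paired t-tests,
Cohen's d, and integer percent changes (halves away from zero).

## Worked example

Simulate a competition-in-solution experiment with a true K_D of 220 nM
(2% response noise), fit the calibration curve, and recover the constant:

```r
library(pdzslots)
sim <- gen_competition_dataset(220, noise = noise_spec(sigma = 0.02, seed = 7))
cal <- fit_calibration(sim$calibration)
cal
#> Hyperbolic calibration: Rmax = 121, K_half = 40.62 nM (R^2 = 0.9998, n = 8)
fit_kd_competition(sim$experiment, cal)
#> Affinity fit (single_site model)
#>   K_D = 244.4 +/- 19 nM
#>   R^2 = 0.9925 on 13 points
```

The fitted 244 ± 19 nM brackets the simulation truth of 220 nM — a single
13-mixture titration at 2% noise carries roughly ±10% uncertainty, which
is why constants are reported as means over independent experiments.

Compare wild-type and haploinsufficient (synGAP halved) scenarios under
the default slot topology:

```r
compare_scenarios(default_scenario("WT"), default_scenario("HET"))
#> Composition shift (scenario b relative to a):
#>   ligand bound_a bound_b delta_copies percent_change per_psd95_a per_psd95_b
#> 1 synGAP    98.2    49.9        -48.3          -49.2       0.327       0.166
#> 2   TARP    86.7    89.4          2.7            3.1       0.289       0.298
#> 3 LRRTM2    28.6    29.7          1.1            3.8       0.095       0.099
#> 4   NLG1    35.7    36.5          0.8            2.1       0.119       0.122
#> 5   NLG2    17.0    17.5          0.5            3.1       0.057       0.058
```

Bound synGAP copies fall by ~49% while every competitor gains slots — the
directional signature of haploinsufficiency. Competitor magnitudes depend
on placeholder affinities (see the vignette) and should be read as signs,
not measurements.

```r
avidity_index(c(220, 1500, 620), 74.7)
#> [1] 1.961441
```

The three-domain construct binds ~2× tighter than its individual domains
predict — a substantial avidity effect.

## Layout

- `R/` — equilibrium math, SPR competition fits, bead assays, slot-model
  scenarios, densitometry statistics, synthetic generators, CSV/YAML/JSON
  I/O, pipeline runner (`run_pipeline()`).
- `vignettes/slot-competition-model.Rmd` — the model, its assumptions,
  parameter defaults, and numerical choices.
- `inst/extdata/` — example scenario configurations (competitor values are
  labeled placeholders).
- `tests/testthat/` — unit, property and end-to-end recovery suites.
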