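---
title: "Methods: carbonate dosing and CRISPRi screen fitness in co2screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbonate dosing and CRISPRi screen fitness in co2screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2screen)
```

`co2screen` implements the quantitative core of a genome-wide CRISPRi
fitness screen of a cyanobacterium grown under very high CO2 at stable pH:
the carbonate-chemistry model used to design the growth media, and the
pooled-screen statistics used to turn sgRNA count trajectories into
per-gene fitness calls. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology left room.

## The carbonate dosing model

Bubbling a freshwater medium with a high-CO2 gas mixture acidifies it
unless alkalinity is supplied. The dosing model answers: *how much NaHCO3
must be added so that the medium equilibrates at pH 7.5 under a given CO2
partial pressure?*

At equilibrium with a gas phase at partial pressure $p_{CO_2}$ (atm),

$$[\mathrm{CO_2}] = K_H \, p_{CO_2}, \qquad
  [\mathrm{HCO_3^-}] = [\mathrm{CO_2}]\,10^{\,\mathrm{pH} - pK_{a1}}, \qquad
  [\mathrm{CO_3^{2-}}] = [\mathrm{HCO_3^-}]\,10^{\,\mathrm{pH} - pK_{a2}}.$$

The carbonate alkalinity $CA = [\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}]$
is exactly the alkalinity that one mole of NaHCO3 per mole supplies, so the
required dose equals the CA predicted at the target pH
(`nahco3_dose()`). Total inorganic carbon is
$TIC = [\mathrm{CO_2}] + [\mathrm{HCO_3^-}] + [\mathrm{CO_3^{2-}}]$.

Parameters (all in `carbonate_params()`):

* `kh` — CO2 solubility, mol L$^{-1}$ atm$^{-1}$. Default: the Weiss
  (1974) volumetric solubility evaluated at 303.15 K and practical salinity
  1.5 (`kh_weiss()`), i.e. 0.0296399, the value usually quoted rounded as
  0.02964. We deliberately default to the *unrounded* formula value rather
  than the rounded constant: the predicted-chemistry table this model
  reproduces is internally consistent only with the unrounded value (with
  the rounded constant, two of the 24 predicted entries drift by one unit
  in the last printed digit).
* `pka1 = 6.35`, `pka2 = 10.15` — apparent (not thermodynamic)
  dissociation exponents for a BG-11-like ionic background at 30 °C,
  obtained by acid titration (below). Apparent constants absorb
  activity-coefficient effects, so no separate activity model is used.
* `pkw = 13.83` — water ion product at 30 °C; only the titration charge
  balance and the optional full-charge-balance pH solver use it.
* `baseline_na = 32.0` mM in `total_sodium()` — sodium contributed by the
  BG-11 salts plus NaOH used to set the HEPES buffer to pH 7.5,
  back-calculated from the reported medium totals; the reported four totals
  constrain it to the interval [31.99, 32.03), and 32.0 reproduces all of
  them at the printed precision.

`equilibrium_ph()` inverts the dosing calculation by root-finding the pH at
which the predicted CA equals the supplied dose (Brent's method on pH in
[2, 12], alkalinity residual below $10^{-9}$ mM). By default it ignores
water self-ionization, which makes it the *exact* inverse of
`nahco3_dose()`; `water = TRUE` solves the full charge balance instead,
which matters only at near-zero alkalinity (an undosed medium under 30%
CO2 equilibrates near pH 4.2).

### Titration and pKa fitting

The apparent pKa values are calibrated by titrating 20 mM Na2CO3 with 1 M
HCl. `simulate_titration()` models this as a *closed* system: total
inorganic carbon is conserved (no CO2 escape during a rapid titration) and
the pH at each point solves the charge balance
$\mathrm{Na^+} + \mathrm{H^+} = \mathrm{Cl^-} + \mathrm{OH^-} +
[\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}]$, with dilution by the added
acid volume included. The closed-system assumption is the model's main
simplification — a slow titration of a carbonate solution open to air
would degas CO2 near and below the second equivalence point and read
higher pH there.

`fit_pka()` recovers both exponents by full-curve least squares on the pH
residuals (Nelder-Mead). An endpoint-based estimate would use only the
two equivalence points; the full-curve fit uses all points and is the
natural choice when the curve is densely sampled. With electrode noise of
0.02 pH units the generating constants are recovered to within ±0.02,
matching the precision scale reported for the empirical titration
(6.35 ± 0.01, 10.15 ± 0.02).

## Growth utilities

`fit_growth_rate()` is an ordinary least-squares fit of $\ln(OD)$ versus
time restricted to OD readings inside a window (default [0.1, 0.3],
closed interval), the range in which photobioreactor OD tracks biomass
linearly; no weighting is applied. `generation_time()` is
$\ln 2 / \mu$. `correct_spectrum_scatter()` normalizes a whole-cell
spectrum at 730 nm and subtracts the chord through its 560 nm and 730 nm
points, the conventional first-order scatter correction; outside
560–730 nm the chord is extrapolated linearly by default (set
`extrapolate = FALSE` to leave that region untouched).

## From counts to gene fitness

The screen pipeline (`run_screen_analysis()`) proceeds in five steps.

**1. Normalization.** `size_factors()` computes median-of-ratios factors:
per sample, the median over guides of the ratio to the guide's geometric
mean across samples, restricted to guides positive everywhere. In a screen
where most guides are neutral this centres every sample on the neutral
majority, so control guides land at log2FC ≈ 0 without using them
explicitly. This is a deliberate simplification of a negative-binomial
count framework: no dispersion estimation and no fold-change shrinkage.
Shrinkage mainly stabilizes low-count guides; with the sequencing depths
simulated here (≈190 reads per guide per sample) its absence costs little,
and the pseudocount (default 0.5) bounds the low-count log ratios.

**2. Log2 fold changes.** Each (condition, replicate) is compared with its
*own* generation-0 sample; replicate-mean profiles are the average of the
per-replicate profiles.

**3. AUC fitness.** A guide's fitness is the trapezoidal area under its
log2FC-versus-generation curve, divided by the final generation (default).
The normalization puts the score on the per-generation log2FC scale: a
guide at a constant log2FC of $c$ from generation 4 onward scores $0.8c$
over the (0, 4, 8, 10) design, and a guide depleting linearly at slope $k$
per generation scores $5k$ over ten generations. Raw areas are available
with `normalize = FALSE`. The generation axis (not wall-clock hours) is
used throughout: turbidostat selection acts per population doubling, so
generations are the natural time unit and make the two conditions
comparable despite their different growth rates.

**4. Gene aggregation.** `guide_weights()` down-weights incoherent guides:
guide $i$'s weight is proportional to the mean over other guides of the
pairwise Pearson correlation of post-induction replicate-mean profiles,
*clamped at zero per pair*, times an optional repression-efficiency prior
(default 1; supply your own if an efficiency model is available). Pairwise
clamping (rather than clamping the mean) ensures that one anti-correlated
guide cannot drag down the weights of the coherent ones: with two
identical and one anti-correlated profile the weights are (½, ½, 0). If
all raw weights vanish — or only one guide remains — weights fall back to
uniform. `gene_fitness()` is the weighted mean with a percentile bootstrap
CI (default 1000 replicates), resampling guides with probability
proportional to their weights.

**5. Hit statistics.** Two Wilcoxon rank-sum families are computed, each
BH-adjusted separately: per-gene guide fitness against control-guide
fitness within each condition, and per-gene guide fitness between the two
conditions. For pooled sizes up to 20 the p-value is the exact permutation
distribution by complete enumeration of all $\binom{m+n}{m}$ assignments
(midranks under ties); beyond that, a normal approximation with tie and
continuity corrections. The between-condition test pools per-replicate
per-guide scores by default (5 guides × 4 vs 5 × 3 = 20 vs 15
observations). This choice matters: with one replicate-averaged score per
guide the smallest achievable two-sided exact p-value for a 5-vs-5
comparison is $2/\binom{10}{5} = 0.0079$, which after BH correction
across thousands of genes can never fall below 0.05 — genome-wide
discovery would be impossible by construction. Pooling replicates restores
the resolution the published analysis evidently had;
`between_scores = "guide"` switches to the conservative variant.

The per-gene summary is the **impact score**
$d = (y_0 - x_0)/\sqrt{2}$ — the signed perpendicular distance of the
point (fitness in condition A, fitness in condition B) from the identity
line, positive when repression helps relatively more under stress — and
the **combined score** $d \cdot (-\log_{10} p_{adj})$, which mixes effect
size with evidence. Hit classes use strict unit thresholds: depleted below
−1, enriched above +1. Genes with fewer than two usable guides are
reported with fitness but `p_adj = NA` rather than dropped.

## The synthetic screen

`simulate_screen()` provides ground truth for validating the estimator
chain. It emulates the *selective* structure of a turbidostat screen, not
its mechanism:

* Initial guide fractions are symmetric-Dirichlet (concentration 5,
  i.e. an abundance CV of ≈0.45, typical of a cloned plasmid library);
  the concentration is a knob because real library skew varies.
* A guide with gene-level selection coefficient $s$ and efficiency $e$ has
  relative fitness $w = 1 + s e$ and its fraction evolves as
  $f_i(g) \propto f_i(0)\,2^{g w_i}$, renormalized — selection per
  population doubling, log2-linear by construction. Efficiencies are
  Beta(5, 1): most guides repress well, a tail does not.
* Sequencing counts are multinomial at fixed depth, after multiplying the
  expected fractions by gamma noise with squared CV 0.004 (library-prep
  overdispersion). That value was chosen analytically so that the null
  log2FC standard deviation is ≈0.2 at the default depth of 2×10⁶ reads:
  the multinomial term contributes ≈0.15 and the gamma term ≈0.13 in
  quadrature.
* The replicate design is deliberately unbalanced (4 vs 3), mirroring a
  failed stress-condition culture, so the pipeline must handle unequal
  group sizes.

What it does **not** model: CRISPRi repression kinetics (induction is
instantaneous and complete at $e$), OD-feedback dilution dynamics, PCR
jackpotting beyond the gamma term, guide position effects, and
polycistronic or off-target effects. Recovery results on this simulator
therefore validate the *estimator chain* — normalization through hit
calling — not the biology of any real screen.

`default_recovery_scenario()` fixes the benchmark: 2,000 genes × 5 guides
plus 500 controls, selection coefficients 70% zero / 15% uniform in
[−0.6, −0.1] / 15% uniform in [0.05, 0.3] shared between conditions, and a
labelled 5% subset shifted by ±0.3 in the stress condition. On this
scenario the pipeline reaches Pearson r > 0.99 between true coefficients
and estimated gene fitness, full sensitivity for the shifted genes at BH
0.05 with observed FDR ≈ 0.03, and a control-guide fitness median within
0.005 of zero (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute these numbers from scratch).

## Numerical choices and problem sizes

* Root solving (equilibrium pH, titration) uses bracketed Brent/bisection
  on pH ∈ [0, 14] or [2, 12]; degenerate inputs (zero partial pressure,
  zero alkalinity without the water term) error rather than return a
  boundary value.
* Coverage-track ties (two overlapping guides with equal |fitness|) go to
  the positive value, then to the earlier-starting guide — deterministic
  and documented; intervals are 0-based half-open, GFF-style 1-based input
  is converted at the boundary.
* All randomness (simulation, bootstrap, noise in calibration curves)
  flows from explicit integer seeds; repeated runs are byte-identical.
* Default problem sizes — 2,000 genes, depth 2×10⁶, 1,000 bootstrap
  replicates, titration grids of ~110 points — were chosen so the full
  validation suite represents a realistic genome-scale screen while
  completing in about a minute; they are package defaults, not limits.

## Known limitations

The carbonate model is an equilibrium, apparent-constant model: no
pressure or nutrient corrections, no gas-transfer kinetics, no activity
model — appropriate for a bubbled freshwater medium near atmospheric
pressure, not for seawater carbonate-system work. The closed-system
titration ignores degassing. The screen statistics treat guides as
exchangeable within a gene apart from the correlation/efficiency weights;
systematic guide biases (position within the gene, strand) are not
modelled. The exact-match FASTQ counter discards reads with any spacer
mismatch, a stricter rule than alignment-based counting with a mapping
quality threshold.
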