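---
title: "Thermodynamic and yield analysis of cell-free glycine-synthesis cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic and yield analysis of cell-free glycine-synthesis cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcskit)
```

## The model

The reversible glycine cleavage system (rGCS) condenses CO₂, a methylene-THF
C1 unit and ammonia into glycine. Whether the system runs in the synthesis or
the cleavage direction is a question of transformed thermodynamics: the
transformed reaction Gibbs energy Δ<sub>r</sub>G′, stated at a pH, ionic
strength, temperature and set of reactant concentrations, both signs the net
direction and — through the flux-force relation — fixes how the total
unidirectional enzymatic flux partitions:

$$\Delta_r G' = -RT \ln\left(\frac{J^+}{J^-}\right), \qquad
  \frac{J^+}{J^+ + J^-} = \frac{e^{-\Delta_r G'/RT}}{1 + e^{-\Delta_r G'/RT}}.$$

`rgcskit` treats reference Δ<sub>r</sub>G′ values as data: they are stored
verbatim at the condition at which they were stated, and three independent
adjustments move them elsewhere.

**Concentration adjustment.** The reaction-quotient term
$\Delta_r G' = \Delta_r G'_{\mathrm{ref}} + RT\sum_i \nu_i \ln(c_i/c_{\mathrm{ref},i})$
with products positive. Water (activity 1) and H⁺ (absorbed into the
fixed-pH transform) never enter the quotient. Evaluating a reaction at its
own reference condition is exactly the identity — this is what anchors the
shipped catalog, whose energies are stated at pH 7.5, I = 0.20 M, 1 mM
reactants.

**Ionic-strength shift.** The extended Debye–Hückel activity model in the
Alberty convention: each species' transformed formation energy moves by
$-(z_i^2 - n_{H,i})\,\alpha(T)\sqrt I/(1 + 1.6\sqrt I)$, with the cubic
temperature fit $\alpha(T) = 9.20483\times10^{-3}T - 1.28467\times10^{-5}T^2
+ 4.95199\times10^{-8}T^3$ kJ mol⁻¹ M⁻¹ᐟ² (α(298.15 K) = 2.915). B = 1.6
M⁻¹ᐟ² is the de-facto convention of transformed biochemical thermodynamics.
Species charges and hydrogen counts must be supplied by the user; the
shipped catalog does not carry them, so catalog energies are only portable
across ionic strengths when that metadata is provided.

**Hess-law substitution.** Replacing one summand of an overall energy,
`overall − old_step + new_step`, is exact arithmetic. This is the coupling
analysis at the package's core: the rGCS overall with NADH (−1.2 kJ/mol)
contains the lipoamide re-reduction by NADH (−0.6 kJ/mol); substituting the
dithiothreitol (DTT) half-reaction (−7.4 kJ/mol) gives

```{r}
substitute_step(-1.2, -0.6, -7.4)
```

and the flux-force consequences on each side of the swap:

```{r}
flux_split(-1.2)
flux_split(-7.4)
```

The 38.1% reverse fraction at −1.2 kJ/mol is the quantitative statement that
the unmodified system is "almost 40%" reversible. Note the forward fraction
at −7.4 kJ/mol computes to 95.2% at 298.15 K (94.6% at 310.15 K) — a claim
of 96% is not reproducible under this formula at either temperature, and the
package reports the computed value rather than forcing agreement.

## The pathway catalog

`reference_catalog()` ships six candidate C1-to-glycine routes at the coarse
granularity of the published pathway map: the formate-based reductive
glycine pathway (P1), two formate-via-formaldehyde variants (P2, P3), direct
formate reduction (P4), NAD-dependent methanol dehydrogenation (P5), and
alcohol-oxidase methanol oxidation feeding the DTT-driven rGCS (P6). Step
energies the source prints are carried verbatim; all others are explicit
unknowns (`NA`), never invented numbers, so the corresponding profiles are
*partial* with feasibility undetermined:

```{r}
cat6 <- reference_catalog()
profile_pathway(cat6$pathways$P6, cat6)
```

Feasibility is classified as "no single step above a threshold barrier",
default +20 kJ/mol. The threshold is a heuristic for what a cascade cannot
push through by concentration adjustment alone (20 kJ/mol ≈ a 3000-fold
concentration ratio at 298 K); it is always user-overridable and echoed in
the profile. The bottleneck is the most positive step, earliest on ties.

## Rates, titers, yields

Initial rates are ordinary least-squares slopes of concentration against
time, reported in µM/min. The default window is the longest initial prefix
with R² ≥ 0.98 (minimum 3 points): production curves rise linearly and then
plateau, and the source does not state its window, so the package uses an
explicit, reproducible rule that tracks the linear phase and stops at the
plateau. Negative and flat slopes are reported and flagged, never hidden.

```{r}
fit_initial_rate(time_course(c(0, 10, 20), c(0, 0.064, 0.128)))
fold_change(6.4, 0.1)
```

Carbon yields are percentages of the theoretical maximum,
`100 · product / (substrate / equivalents)`, with the substrate total taken
as the cumulative amount fed (fed-batch additions sum: 10 + 10 mM
formaldehyde → 20 mM). Report rounding is half-up to integer percent — the
convention that matches every printed pairing (77.5 → 78, 85.5 → 86) — and
one decimal for g/L; unrounded values are always retained alongside.

```{r}
carbon_yield(17.1, 20, yield_spec("glycine", "formaldehyde"))$percent
mm_to_g_per_l(15.5, "glycine")
```

Serine counts two C1 equivalents per molecule (one methanol-derived carbon
via glycine, one via methylene-THF), so 7.5 mM serine on 50 mM methanol is
30% of theoretical maximum. Pyruvate mass defaults to the free-acid formula
(88.06 g/mol); salt forms are available by passing an explicit formula.

## Capture and labeling

Direct-air-capture bookkeeping is gravimetric: mass gain / 44.01 g/mol CO₂,
divided by absorber volume, gives bicarbonate equivalents (4 mmol in 20 mL →
200 mM), and `dilute()` conserves moles exactly into the working
concentration. `carbonate_ph()` solves the closed-system charge balance
`CB + [H+] = [OH−] + [HCO3−] + 2[CO3²⁻]` by bisection to a residual below
10⁻¹⁰ M (pKa 6.35/10.33). For the stated capture endpoint (1 M KOH, 0.2 M
CO₂) the closed-system pH computes to 13.78, far above the reported ~8.6 —
that triple is not mutually consistent under closed-system speciation
(a pH of 8.6 with 0.2 M carbon implies nearly all carbon as bicarbonate and
essentially no free base, i.e. far more than 4 mmol CO₂ absorbed per 20 mL).
The function returns the computed value and the report layer flags the
discrepancy; nothing is tuned to reproduce 8.6.

The ¹³C model is deliberately nominal: each labeled carbon retained by a SIM
fragment adds +1 m/z with probability equal to its source pool's enrichment
(CO₂ pool for the carboxyl carbon; formaldehyde pool for the methylene and
serine-β carbons), giving a Poisson-binomial envelope over base+0…base+n.
Natural-abundance correction of the derivative's H/N/O/Si atoms is out of
scope: at the near-complete labeling these cascades produce, nominal shifts
carry the signal. Which atoms each published fragment retains is not stated;
the shipped maps (glycine m/z 246 = both carbons, 218 = methylene only — the
M−57/M−85 pattern of silyl derivatives; serine 390/302/288 analogously) are
editable assumptions in `inst/extdata/fragments.csv`. Enrichment inversion
is least squares over one or more fragments jointly; a two-carbon fragment
drawing on both pools is symmetric in them, so assignment requires a second
fragment lacking one carbon, and a pool absent from every supplied fragment
is reported as undetermined rather than zero.

## Synthetic data and what passing tests show

The generators emulate the study's input classes with known ground truth:

* HPLC time courses: `c(t) = min(rate·t, plateau)(1 + ε)`, ε ~ N(0, CV),
  truncated at zero, with optional post-plateau first-order decay for
  intermediates. Multiplicative noise matches HPLC error structure; the
  default CV of 2% reflects routine amino-acid quantification. Defaults
  (75 µM/min, 16 mM plateau, 8 samples at 10 min) mirror the optimised
  production runs.
* SIM intensities: multinomial draws over the fragment envelope —
  counting-statistics noise.
* Energy tables: Gaussian perturbation of the known catalog energies, for
  robustness analysis (at SD 0.5 kJ/mol the DTT-coupled overall never
  changes sign across 1000 seeds).

Each generator is a pure function of its arguments including the seed
(per-analyte sub-streams are derived deterministically), so runs are
byte-identical and never disturb the session RNG. What the recovery tests
show is that the estimators invert these generating models accurately
(median rate error < 3% at CV 2–5%; enrichment recovered to ±0.02 at 10⁵
counts). What they do not show: robustness to baseline drift, detector
saturation, co-eluting peaks, or natural-abundance interference — real
chromatograms and spectra are messier than the generating model.

## Numerical choices

* R = 8.314462618×10⁻³ kJ mol⁻¹ K⁻¹; default temperature 298.15 K. The
  source states no temperature for its energies (assays ran at 37 °C);
  temperature is a condition field and every report names the value used.
* Flux fractions saturate to {0, 1} when |Δ<sub>r</sub>G′/RT| > 700, the
  `exp()` overflow edge.
* Bisection for carbonate pH runs on pH ∈ [0, 14]; a boundary with residual
  below 10⁻¹⁰ M counts as the root (1 M strong base → pH 14.0 exactly).
* Enrichment inversion uses box-constrained quasi-Newton from five starts to
  stay off the symmetric ridge of two-pool fragments.
* Test and recovery problem sizes — 100 random reactions for the quotient
  oracle, 200 seeded courses for rate recovery, 10⁵–10⁶ counts for
  inversion, 1000 seeds for the sign-stability Monte Carlo — are chosen so
  the full suite completes in seconds while the binomial/Monte-Carlo error
  of each check sits well inside its asserted tolerance.

## Known limitations

* Catalog energies are single stated values; no uncertainty propagation
  beyond the perturbation generator.
* No component-contribution estimation of formation energies, no pMg or
  metal-binding corrections, no max–min driving force optimisation.
* Carbonate chemistry is closed-system only (no pCO₂ equilibration) and
  activity corrections are not applied to the speciation constants.
* Specific fixation rates (nmol/min/mg) need the total enzyme mass, which
  published comparisons often omit; the test fixture documents a back-solved
  mass and is labeled synthetic, not asserted as measured truth.
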