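---
title: "Methods: models, parameters and design choices in grazesel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in grazesel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazesel)
```

# Scope

`grazesel` analyses diet selection in grazing trials on temperate
steppe-type grasslands. Four measurement layers feed the analysis:

1. **Vegetation quadrat surveys** — clipped dry biomass per species,
   summarized into availability, diversity and nutrient content.
2. **Tri-axial accelerometry** — raw surge/sway/heave acceleration,
   classified into grazing vs non-grazing time via ODBA.
3. **Marker-dosed fecal chemistry** — TiO~2~ concentration, fecal crude
   protein and ash, giving fecal output, digestibility and intake.
4. **Fecal DNA metabarcoding read tables** — ASV counts, giving
   family-level diet proportions, diet nutrients and dietary richness.

A synthetic-data generator emulates all four layers with known ground
truth, so every downstream module can be validated end to end without any
field data. This vignette documents the models, the parameters that
matter, and the choices made where the methodology left the design open.

# The models

## Vegetation: availability, diversity, nutrients

Relative abundance of species *i* is $p_i = n_i / N$. The classical
definition uses individual counts; quadrat surveys weigh clipped biomass
and rarely count ramets of clonal grasses, so **biomass is the default
abundance measure** (`relative_abundance()` accepts counts in the same
column if a count-based index is wanted). Diversity is the Shannon–Wiener
index $H' = -\sum_i p_i \ln p_i$, computed per plot from the pooled
quadrats, which yields three replicate values per grazing unit and period.

Food-item availability (VRA) is the share of each of six items — Poaceae,
Cyperaceae, Rosaceae, Amaryllidaceae, Fabaceae, and pooled forbs — in
total above-ground biomass. Community and per-item CP/NDF/ADF are
biomass-weighted means of per-species laboratory values, which are inputs
here (the assays themselves are out of scope).

## Behaviour: ODBA and the 0.1 g rule

Dynamic acceleration is raw acceleration minus a **centred running mean**
per axis (default window 2 s, configurable; edges use the truncated
mean, so output length equals input length). No particular filter is
canonical for the static/dynamic split; a short centred mean is the
simplest choice whose attenuation of genuine movement is negligible at
the bout time-scales involved. ODBA is
$|d_x| + |d_y| + |d_z|$, and behaviour is classified per epoch
(default 60 s of mean ODBA) by a single threshold: grazing above 0.1 g,
non-grazing below. The two strict inequalities leave exact equality
undefined; `classify_behavior()` labels it non-grazing, a measure-zero
tie policy that merely needs to be stated. Units are gravitational g
throughout, with an m·s^−2^ conversion flag.

## Intake: the marker chain

With an inert external marker dosed at $2.5$ g·day^−1^,
$\mathrm{FO} = \mathrm{dose} / [\mathrm{TiO_2}]$ (g dry matter·day^−1^),
$\mathrm{FOM} = \mathrm{FO}\,(1 - \mathrm{ash}/100)$, digestibility
follows the regression
$\mathrm{OMD} = 0.899 - 0.644\,e^{-0.5774\,\mathrm{FCP}/100}$
(FCP in percent of fecal dry matter), and
$\mathrm{OMI} = \mathrm{FOM} / (1 - \mathrm{OMD})$.

The regression's published typesetting is ambiguous about whether FCP is
scaled; the literal left-to-right reading (divide by 100) is implemented,
and all four constants live in `omd_model()` so an alternative
calibration is a configuration change. Two numerical notes: the curve is
bounded in $(0.255, 0.899)$ and strictly increasing, but in double
precision the exponential term is absorbed against the asymptote once
FCP exceeds roughly $6.6\times10^3$ — beyond that the computed value
*equals* 0.899. And the inversion used by the simulator is only defined
on the open interval $(0.255, 0.899)$; a requested true OMD at or
beyond the asymptote is rejected rather than clamped.

## Diet: DRA, nutrients, richness

Taxonomic assignment is deliberately minimal: an ASV is assigned iff its
sequence matches exactly one reference barcode at 100% identity
(case-insensitive, no gaps); ambiguous and non-matching ASVs stay
unassigned. Denoising (primer trimming, quality filtering, DADA2) is a
published upstream toolchain, not re-implemented — the package consumes
denoised or simulated count tables.

Relative read abundance (DRA) sums assigned reads within food items and
normalizes over **assigned reads only**; the unassigned fraction is
reported separately rather than diluted into the composition. DRA is
treated as a direct, unbiased estimate of diet proportion — no
copy-number or marker-recovery correction — and the simulator makes the
matching assumption (no per-species amplification bias), so recovery
tests validate the estimator, not the absence of real-world PCR bias.

Dietary richness is the expected number of distinct ASVs in a
standardized subsample: `bootstrap_richness()` resamples **without
replacement** (classical rarefaction, so the Monte-Carlo mean converges
to the hypergeometric closed form; with-replacement by flag), default
1000 iterations, standardized depth defaulting to the minimum assigned
depth in the comparison set.

## Selectivity: Jacobs' D

$D = (r - p) / (r + p - 2rp)$ compares use $r$ (DRA) with availability
$p$ (VRA of the same plot and period). $D$ is antisymmetric under
swapping $r$ and $p$, strictly increasing in $r$, and spans $[-1, 1]$
with 0 at proportional use. The degenerate cases $r = p \in \{0, 1\}$
are returned as `NA` and excluded, not imputed as zero.

Departure from neutrality is tested per item with a one-sample Wilcoxon
signed-rank test against zero. The implementation is in-package because
the required behaviour — an exact null for $n \le 25$ that remains exact
under tied absolute values (selectivity values at the $\pm 1$ bounds tie
routinely) — is obtained by convolving the sign-pattern polynomial over
doubled mid-ranks, something standard implementations refuse with ties.
Zeros are dropped before ranking (Wilcoxon's original treatment; Pratt's
is a flag), and $n > 25$ uses the normal approximation with tie and
continuity corrections.

## Comparative statistics

*Bray–Curtis*, $\sum|u_i - v_i| / \sum(u_i + v_i)$, is implemented
directly (`vegan::vegdist` serves as a test oracle only).

*perMANOVA* is the one-way distance-based pseudo-F:
$SS_{total}$ from all pairwise squared dissimilarities divided by $n$,
$SS_{within}$ from within-group pairs divided by each group's size
(unbalanced-safe), and
$F = (SS_B/(k-1)) / (SS_W/(n-k))$, with significance from free
permutation of labels and the add-one estimator
$p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$, default 999 permutations.
An exhaustive mode enumerates all relabelings for small $n$. On
Euclidean distances of univariate data the pseudo-F reduces to the
classical ANOVA F, which the tests exploit, alongside a brute-force
enumeration oracle built on the independent Gower-trace formulation.
Free (unrestricted) permutation mirrors the analysis style the method
is normally reported with; plot-restricted permutation is a known
refinement deliberately not defaulted.

*NMDS* wraps `vegan::monoMDS` (Kruskal stress-1) in a multi-start
driver: first start from the metric (principal-coordinate)
configuration, remaining starts random, best stress kept, ties to the
earliest start, and the winning configuration rotated to principal axes
for a reproducible orientation. Twenty starts by default. A matrix of
all-equal dissimilarities embeds exactly (regular simplex) and returns
stress 0 with a warning.

*t-tests and ANOVA* delegate to base R with pooled variance by default
(`var.equal = TRUE`), because the design of interest — nine replicate
values per group — is conventionally analysed with the equal-variance
test reporting $df = 16$; Welch is a flag. *Richness regressions* are
OLS on z-standardized predictors (height, biomass, diversity, CP, NDF,
ADF) so coefficients are comparable effect sizes on one axis; Wald
statistics, two-sided p-values and 95% CIs per coefficient, adjusted
R² via `glance()`. Rank-deficient designs error naming the collinear
columns.

# The synthetic trial

`simulate_trial()` emulates the study conditions:

* **Layout** — four animal strategies (LA, LM, EM, EA) where LM and EM
  share physical plots (the mixed-grazing unit), three replicate 2-ha
  plots per unit, three sampling periods, three focal animals per plot
  (so nine intake animals per strategy and 18 in the mixed unit), ten
  50 × 50 cm quadrats per plot and period.
* **Species pool** — 37 species across the six items; family biomass
  shares put the five named families at 83% of standing biomass with
  graminoid dominance. Per-family nutrient ranges give every forb higher
  CP and lower NDF than every grass — the contrast the selectivity
  analysis is about.
* **Quadrats** — lognormal quadrat totals (median 35 g per 0.25 m²,
  i.e. ~140 g·m^−2^, typical of such steppe) with Dirichlet composition
  around the pool mean (concentration 150, chosen once as realistic
  between-quadrat heterogeneity).
* **Diets** — expected item share ∝ availability × preference,
  renormalized; individual diets are Dirichlet draws (concentration 80)
  around that expectation, spread over species within item by pool
  biomass. Neutral preferences make expected Jacobs' D zero for every
  item, which the type-I-error tests use. Default preferences emulate
  the trial's qualitative structure: mixed-grazing animals and ewes
  favour forbs, lambs alone avoid them.
* **Reads** — one multinomial draw of the requested depth over species
  barcodes per sample. No PCR bias, chimeras or sequencing error: the
  generator validates estimator arithmetic, not laboratory artefacts.
* **Accelerometry** — two-state exponential-bout process (defaults:
  grazing mean bout 25 min, non-grazing 17 min, so roughly 60% of a
  13 h daylight session is grazing), per-axis Gaussian dynamic noise
  scaled so expected per-sample ODBA is 0.3 g (grazing) vs 0.02 g
  (non-grazing), and a gravity static component on a slowly drifting
  orientation. Sample rate defaults to 1 Hz — the threshold rule is
  rate-agnostic once ODBA is epoch-averaged — and a 13 h session at
  1 Hz is 46 800 samples.
* **Fecal chemistry** — true fecal output lognormal around 600 g
  DM·day^−1^, ash 12–18%, OMD uniform on (0.55, 0.72) well inside the
  invertible range; TiO~2~ concentration is dose/FO under mean-one
  multiplicative lognormal noise (CV 5% by default — concentrations are
  positive and right-skewed), FCP from inverting the OMD regression,
  ash consistent with true FOM. With the noise switched off the whole
  marker chain round-trips to 10 significant digits, which is asserted
  in the tests. Five daily grab samples pooled per animal-period are
  represented as a single composite sample.

A single integer seed drives everything; each stage derives its own
stream deterministically from the seed and the stage name, so stages can
be rerun independently yet reproducibly, and `run_pipeline()` output is
byte-identical under a fixed seed (checksummed in its manifest).

## What passing tests do and do not show

The generator's diets are exactly compositional, its reads exactly
multinomial, and its marker chemistry exactly consistent with the intake
equations. Green recovery tests therefore demonstrate that the
estimators are correct under their own assumptions at realistic effect
sizes and sample sizes — not that real rbcL metabarcoding is unbiased,
that ODBA thresholds transfer across collars, or that TiO~2~ recovery
is complete in live animals.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen to keep the full test
suite around a minute while leaving Monte-Carlo error well inside the
asserted tolerances: 10³ animals for the marker round trip; 100 random
datasets for the pseudo-F/ANOVA identity; exhaustive permutation checks
at n = 6 and 7; 10³ null simulations with 199 permutations each for
perMANOVA size; 50 random tables (500 iterations each) against the
rarefaction closed form; and an 18-animal, three-period, depth-10⁵
end-to-end recovery of a 9:1 forb preference.

# Known limitations

* One-way perMANOVA only; no nested or restricted permutation schemes.
* The behaviour module is a two-class threshold ethogram; no
  ruminating/walking split and no learned classifier.
* No marker-recovery correction in the intake chain.
* Exact-match assignment is intentionally simplistic; real reference
  databases need upstream curation and a proper classifier.
* The threshold-calibration procedure for ODBA (direct observation
  sessions) is consumed as a given constant, not reproduced.
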