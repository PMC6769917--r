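---
title: "Frontal affinity chromatography glycan profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal affinity chromatography glycan profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faclectin)
```

## The measurement model

Frontal affinity chromatography infuses a dilute analyte continuously
through a small column carrying immobilized lectin. With a single class of
independent binding sites at equilibrium, the elution front of the analyte
is retarded relative to a non-binding standard by

$$V - V_0 = \frac{B_t}{K_d + [A]_0},$$

where $B_t$ is the effective ligand content of the column (nmol), $K_d$ the
dissociation constant (mol/L) and $[A]_0$ the infused analyte concentration
(mol/L). All volumes are in μL; since nmol/μL ≡ mmol/L, the implementation
carries an explicit $10^3$ factor and every unit conversion is pinned by the
dimensional test case $B_t = 1$ nmol, $V - V_0 = 1000$ μL $\Rightarrow$
$K_d = 10^{-6}$ M. Inverting gives $K_d = B_t/(V - V_0) - [A]_0$; at the
standard 2.5 nM loading of tagged oligosaccharides the $[A]_0$ term
contributes at most $[A]_0/K_d$ in relative terms (about 1.3% at
$K_d = 2 \times 10^{-7}$ M, far less elsewhere), which is why the
simplified form $K_d = B_t/(V - V_0)$ is also provided. Association
constants are reported as $K_a = 1/K_d$, with below-detection entries
rendered as $K_a = 0$ alongside an explicit flag.

Assumptions: one independent site class, equilibrium at the front, no
cooperativity, and no flow-rate or temperature corrections. Multi-site
models are out of scope.

## Column calibration

$B_t$ and the reference $K_d$ are estimated from a concentration-dependence
series by the Woolf–Hofstee linearization: plotting $y = V - V_0$ against
$x = (V - V_0)[A]_0$ gives a line with slope $-1/K_d$ and intercept
$B_t/K_d$. The estimator is deliberately the unweighted ordinary least
squares fit of that line — that is what the linearized plot defines — and a
nonlinear least-squares refit of the hyperbola is provided only as a
diagnostic cross-check (`woolf_hofstee_refit_nls()`). A non-negative slope
means no saturable binding and is raised as an error rather than clamped,
since a negative $K_d$ is not a parameter value.

The exact concentrations of a real calibration series are
instrument-specific; the package's default design places five points at
$[A]_0 \in \{0.1, 0.3, 1, 3, 10\} \times K_d$, bracketing the informative
range of the isotherm on both sides of $K_d$. On noiseless data the fit
recovers the generating parameters to $10^{-6}$ relative error; under 2%
multiplicative noise on the retardations the median relative error of
$K_d$ stays below 10% at this design (500-replicate simulation in the test
suite).

## Front detection

Instrument software reports only $V - V_0$; how the front volume is located
on the raw breakthrough curve is unspecified, so two standard surrogates
are implemented. Both first screen the curve: provisional baseline and
plateau are medians of the leading 5% and trailing 10% of samples, the
noise level is the pooled MAD of the edge residuals, and the rise must
exceed 5× the noise (configurable) or detection fails. An isotonic
regression of the signal then locates the mid-level crossing and the
16%/84% crossings; half their distance estimates the front width
$\hat\sigma$. Baseline and plateau are finally re-estimated as means of all
samples more than $6\hat\sigma$ from the front. This windowing matters on
long volume grids: with edge-only level estimates, a level error
$\delta$ shifts the equal-area front position by roughly $\delta$ times the
distance to the grid edge, whereas the windowed estimate reduces that
lever arm to a few front widths.

* `half_height` reports the interpolated crossing of the isotonic fit at
  the refined mid-level — fast and local.
* `equal_area` (default) reports the volume $V^*$ at which the missing area
  below the plateau left of $V^*$ equals the excess area above baseline
  right of $V^*$, integrated over the $\pm 6\hat\sigma$ window. This is the
  mass-conserving front position, the convention in frontal analysis, and
  is robust to front asymmetry.

Both methods agree exactly on an ideal step and to < 0.01 μL on noiseless
symmetric fronts; both are translation-equivariant in volume and invariant
to signal scaling. Under 2% fluorescence noise the mean absolute location
error is about $\sigma/50$ at the default front width $\sigma = 1.5$ μL —
comfortably inside the $\sigma/10$ the profiling stages assume. Curves
whose signal is still rising at the end of the grid ("no plateau"), or
whose rise is indistinguishable from noise, raise classed detection errors;
at the pipeline level such glycans are logged and flagged below detection
rather than aborting a run.

## Below-detection convention

Retardations at or below `v_min` (default 0.5 μL, configurable) are treated
as no measurable affinity: $K_d$ is NA and $K_a$ is reported as 0 with a
flag. Real profiling panels show many such glycans, and published profiles
do not state their instrument's detection floor, so the floor here is an
explicit, stated parameter rather than an inferred one. The same floor
defines the $K_a$ value used to keep undetected entries finite in profile
comparisons ($K_{a,\mathrm{floor}} = v_{\min} \times 10^3 / B_t$).

## HAI titers and censored MICs

Hemagglutination-inhibition plates dilute a saccharide 2-fold down the
plate against lectin at a fixed titer. The minimum inhibitory concentration
is the lowest concentration of the topmost contiguous block of completely
inhibiting wells; if even the starting well fails, the MIC exceeds the
tested range and is censored as "> start". Exact grid values are stored
(7.8125 mM) and rounded only for display, because published tables mix 2-
and 3-significant-figure entries (7.8, 12.5, 6.25). Non-monotone plates —
an inhibiting well below a non-inhibiting one — violate the assumed
monotone dose response and resolve conservatively (stray wells ignored)
with a warning. Units (mM vs %w/v) are tags carried through and never
converted, as the two are incommensurable without molar masses. Titers are
$2^{-n}$ with $n$ the last positive well of the leading block.

## Profiles, classification and comparison

A specificity profile maps every panel glycan to $(V-V_0, K_d, K_a)$ with
its detection flag; relative affinity normalizes $K_a$ to the strongest
binder (100%), the convention for cross-lectin bar profiles whose absolute
scales differ by orders of magnitude.

mJRL classification follows the field's two-level scheme — group A binds
high-mannose-type glycans, group B does not; subgroups reflect the
preference for complex-type glycans — but published figures give no numeric
decision boundaries, so the rules here are explicit, configurable
thresholds documented as this package's choices:

* group A iff the detectable fraction over the *high-mannose axis* is
  $\geq \theta_A = 0.2$. The axis is the high-mannose class plus
  core-pentasaccharide-flagged glycans: lectins that bind only the
  Man₃GlcNAc₂ core among mannose glycans are still mannose-core
  recognizers, and excluding the core glycans would misplace them in
  group B.
* subgroup 1 iff the detectable fraction over the complex-type classes
  (agalacto + galactosylated + sialylated) is $\geq \theta_C = 0.5$ *and*
  binding is reduced by a bisecting GlcNAc: mean relative affinity on
  bisecting-flagged complex glycans $\leq \rho = 0.5$ times that on
  non-bisected ones. The bisecting comparison is flag-wise (bisected vs
  non-bisected complex glycans), not structure-paired; per-glycan pairing
  would require structural identities the panel format does not carry. With
  no bisected glycans on the panel the criterion is vacuously satisfied.
* subgroup `unclassified` iff the complex-type fraction is
  $< \theta_{\min} = 0.1$ (no binding to complex-type glycans); anything
  else is subgroup 2.

All computed fractions are returned as evidence, and the rules use only
detectability fractions and affinity ratios, so assignments are invariant
to uniform rescaling of $K_a$ (e.g. column-to-column potency offsets).
The default thresholds reproduce the three archetype assignments —
(A, 1), (A, 1), (A, unclassified) — in at least 95% of 200 seeded noisy
simulations in the test suite.

Profile comparison reports *concordance* — the Spearman rank correlation
of $\log_{10}(K_a + K_{a,\mathrm{floor}})$ over the shared panel, which is
exactly 1 for profiles differing by any uniform potency factor and is
undefined (NA, with a note) when the detectable sets are disjoint — and a
*discordant* list: glycans detectable in exactly one profile, plus glycans
whose log-affinity difference departs from the global median offset by more
than a configurable gap (default 1 log₁₀ = 10-fold). The median-offset
correction makes a global ~100-fold potency shift between two
similarly-specific lectins produce an empty discordant list except for
genuinely divergent glycans.

## The synthetic-data generator

The generator stands in for the instrument and for a full profiling panel,
which is not redistributable. What it emulates, and its defaults:

* **Panel**: 130 glycans — 61 N-linked (9 high-mannose, 8 hybrid, 12
  agalacto, 20 galactosylated, 12 sialylated), 39 glycolipid-type, 30
  others — with sentinel records for the glycans the archetype rules name:
  "003"/"015" (core pentasaccharide), "017" (plant-type Fuc/Xyl core),
  "913" (Manα1–3Man only), "914"/"915" (Manα1–6Man), "701"–"710"
  (chitin-type). The composition is fixed; it is a synthetic archetype
  panel, not a reconstruction of any published appendix.
* **Archetypes**: PPL2A-like (complex-type binder, $K_d$ centered at
  $2 \times 10^{-7}$ M), PPL3-like (same support plus "017", 100× weaker),
  PPL4-like (high-mannose/hybrid + Manα1–6Man + chitin binder,
  $2 \times 10^{-5}$ M), nonbinder. Per-glycan $K_d$ scatter is log-normal
  with sd 0.3 log₁₀ units — an invented dispersion, stated as such. The
  scatter deviates are keyed to (seed, panel), not to the archetype, so the
  PPL2A-like/PPL3-like pair is glycan-by-glycan correlated at a constant
  100-fold offset: they model two iso-specific lectins of different
  potency, which is what makes their discordant set exactly {"017"}.
* **Curves**: signal $= \Phi((v - V_\mathrm{front})/\sigma)$ with
  $\sigma = 1.5$ μL plus Gaussian noise (2% of plateau). The normal-CDF
  front is the simplest dispersion surrogate; $\sigma$ is configuration,
  not science. The standard elutes at the bed volume (31.4 μL). The
  default grid (0–1200 μL, 0.5 μL steps) spans the strongest archetype
  retardations (~730 μL for the PPL2A-like column at its lowest simulated
  $K_d$).
* **HAI plates**: well $k$ inhibits iff its concentration
  $\geq$ the true MIC, with an optional flip rate for robustness tests —
  so `mic()` always returns the smallest grid value $\geq$ the truth, or a
  censored ceiling.

Each generator draws from an RNG stream keyed by (seed, operation), so
fixtures are independent yet bit-reproducible. What the generator does
*not* emulate — plate-theory dispersion, baseline drift, carryover,
non-equilibrium kinetics, real glycan structures — bounds what the tests
show: passing the closure suites demonstrates that the estimators invert
the stated measurement model correctly under the stated noise, not that
real chromatograms obey that model.

## Problem sizes and numerical choices

The test suite runs the classification stability study at 200 seeded
replicates of the 130-glycan panel across the three archetypes at the
measurement level (2% front noise applied to retardations), the front-bias
study at 200 replicates on a 500-point grid, and the noisy-calibration
study at 500 replicates of the five-point design — sizes chosen to estimate
the relevant rates to a few percent while keeping the whole suite in
seconds. Full curve-level closure (archetype → curves → fronts → $K_d$ →
profile → classification) is exercised in single end-to-end runs, where
noisy 2%-noise curves recover detectable $K_d$ to a median relative error
well under 1%.

Ties and degenerate inputs: Woolf–Hofstee designs need ≥ 3 points and ≥ 2
distinct concentrations (a repeated single point is an error, not a fit);
front detection requires ≥ 20 samples, a strictly increasing grid, ≥ 3
samples on each side outside the front window, and errors rather than
extrapolates when the front abuts the grid edge; `mic()` on an
all-inhibiting plate returns the lowest concentration on the plate,
uncensored, since the grid cannot resolve below it.

## Known limitations

* Single-site equilibrium model only; strong avidity or multivalent
  effects in real lectin columns are not represented.
* The classifier thresholds are calibrated on the archetypes; applying
  them to lectins with qualitatively different specificities (e.g.
  strict group B binders with partial complex-type binding) may need
  re-tuning, which is why every assignment ships its evidence fractions.
* Relative affinity uses per-lectin max normalization; published
  "relative affinity (%)" figures do not define their basis, and a
  different basis would rescale, though not reorder, the profiles.
* The synthetic panel's class composition matches published counts, but
  its glycan identities are placeholders; motif flags are inputs, not
  derived from structures.
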