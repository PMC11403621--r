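---
title: "Models and methods behind mitopharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopharm)
```

mitopharm analyses the quantitative readouts used in discovery campaigns
against protein-protein interactions of mitotic kinases — the motivating
system is a kinase whose spindle localization and activation depend on a
partner protein, so that disrupting the interaction displaces the kinase
from the spindle and suppresses its activating autophosphorylation. This
vignette describes the models, the tunable parameters, what the synthetic
generators emulate (and what they deliberately do not), and the numerical
choices made where the design was open.

## Competitive binding in fluorescence polarization

A labeled peptide probe L reports binding to protein P through its
anisotropy (in mP): bound probe tumbles slowly and polarizes more. With a
competitor B the system obeys two simultaneous equilibria,

$$P + L \rightleftharpoons PL \;(K_{dL}), \qquad
  P + B \rightleftharpoons PB \;(K_{dB}),$$

and the free-protein concentration is the physical root of a cubic in
$[P]$ whose coefficients come from the two mass balances. `bound_direct()`
solves the two-species case from the quadratic mass balance (using the
numerically stable root form $2 P_0 L_0 / (s + \sqrt{s^2 - 4 P_0 L_0})$);
`bound_competitive()` evaluates the exact three-species solution.

**Numerical choice.** The textbook trigonometric real-root expression of
the cubic is exact algebra but not exact arithmetic: when the competitor
swamps the system, free protein falls many orders of magnitude below the
cubic's coefficient scale and the expression cancels catastrophically (we
measured relative errors up to $10^4$ in double precision). mitopharm
therefore uses the trigonometric root only as an initial guess and always
refines it with a safeguarded Newton iteration on the free-protein mass
balance over the bracket $[P_0/m(0),\,P_0]$, where
$m(P) = 1 + L_0/(K_{dL}+P) + B_0/(K_{dB}+P)$ is the (decreasing) binding
multiplier — the root $P^\ast = P_0/m(P^\ast)$ always lies inside.
Out-of-bracket Newton steps fall back to bisection in log space, which
preserves *relative* accuracy however small the root is. The test suite
checks agreement with an independent bracketed root solve to better than
$10^{-8}$ relative over $10^4$ random parameter draws spanning
$10^{-12}$–$10^{-2}$ M.

Observed anisotropy is modeled as a brightness-weighted interpolation
between the free and bound end points,
$r = (q f_b r_b + (1-f_b) r_f)/(q f_b + (1-f_b))$, with the quantum-yield
ratio $q$ defaulting to 1: the instrument monitors total fluorescence for
artifacts, and mitopharm follows that practice by *flagging* points whose
total fluorescence deviates more than 20% from the series median, never
correcting or dropping them.

**Fitting.** `fit_direct_kd()` and `fit_competition_kd()` are bounded
Levenberg-Marquardt least squares with the dissociation constant searched
on a log10 scale over $[10^{-12}, 10^{-1}]$ M, initialized at the
geometric mean of the tested concentrations. Confidence intervals are
percentile bootstraps (1000 resamples by default) over replicate groups
within each concentration. A fitted displacement amplitude below three
residual standard deviations is reported as "too weak to measure" with the
estimate pinned at the top of the search range — a lower bound, not a
measurement, mirroring how an undisplaceable off-target isotherm should be
reported.

**Design note on direct titrations.** With the probe far above its own
$K_d$ the titration becomes stoichiometric and the curve shape carries
little information about affinity: a Cramér-Rao calculation for a probe at
$9\times K_d$, 2 mP read noise, 12 concentrations in triplicate caps the
probability of recovering $K_d$ within ±20% at about 0.70 for *any*
estimator. The package's recovery simulation therefore follows the
standard design rule — probe at or below $K_d$ (1 nM against a 1.2 nM
probe constant, protein titrated 2-fold from 50 nM) — where the same
noise level permits ~97% and the suite observes 98/100. Competition fits
use the assay composition as given (30 nM protein, 10 nM probe) and
recover a 19 nM competitor within ±20% in 100/100 seeded runs.

## High-content mislocalization scoring

The imaging assay asks, per well: *what fraction of mitotic cells has lost
the kinase from the spindle?* The algorithm, per field of three channels
(DNA / mitotic marker / readout):

1. **Background**: per channel, the median of the lowest-intensity
   quartile of pixels — robust as long as objects cover a minority of the
   field; clamped at zero.
2. **Nuclei**: connected components of DNA-channel pixels above 100× the
   channel background, filtered to 30–600 µm² (pixel size 0.65 µm/px by
   default, emulating a 20× objective with 2×2 binning).
3. **Mitotic cells**: nuclei whose mean marker intensity exceeds 100× the
   marker-channel background.
4. **Spindle mask**: white top-hat (image minus its opening) of the marker
   channel with a 25 µm disc element, thresholded and restricted to a
   60 µm window around the nucleus. The top-hat passes structures finer
   than the disc — the spindle — and removes the diffuse cell body. The
   mask is derived from the *marker* channel, never the readout channel,
   because it must exist even when the readout is fully displaced.
5. **Scores**: each mitotic cell's mask samples the readout channel; the
   per-plate threshold is the highest intensity among the darkest 10% of
   control (vehicle-well) cells, and a well's score is the percentage of
   its mitotic cells strictly below that threshold. The
   dephosphorylation variant substitutes a whole-nucleus mask and the
   phospho-specific readout. Wells with fewer than 20 scored cells are
   flagged and excluded from dose-response fits.

Two implementation details matter. The top-hat is computed over the whole
field and then windowed: computing it inside a clipped window lets a
*neighboring* cell body, sliced by the window edge, defeat the opening and
leak into the mask. And the mask threshold is referenced to the unfiltered
marker-channel background (100× by default) rather than to a background
statistic of the top-hat output: the latter lands in the same intensity
band as the faint cell-body rim that discretization leaves in the top-hat,
making masks knife-edge unstable. Both references remain configurable
(`hcs_config(tophat_background=)`).

Scoring uses no random numbers, so a plate scores identically on reruns,
and every step is linear or rank-based in intensity: multiplying all
channels by a constant leaves every well score unchanged (the suite checks
this exactly; the morphology normalizes channels to unit range internally,
which is also what makes the rank filters reliable).

By construction of the threshold rule, untreated wells score close to the
decile parameter (10%) — the suite verifies the control false-positive
rate sits inside its binomial confidence band on a full 96-well synthetic
plate — and assay EC50s come from a four-parameter logistic fit of
percent-positive against dose.

## Dose-response, synergy, and scalar pharmacology

`fit_4pl()` fits $r(d) = b + (t-b)/(1+(d/m)^s)$ by bounded
Levenberg-Marquardt with the midpoint on a log scale, trying both slope
signs and keeping the better optimum. Zero doses are admitted through the
slope-sign limit of the untransformed model (no pseudo-dose enters the
reported parameters), and results are canonicalized to $b \le t$ (the
$(b,t,s) \to (t,b,-s)$ reparametrization leaves the curve unchanged, so
this costs nothing). Fits with amplitude under three residual standard
deviations report `converged = FALSE` rather than a midpoint. Viability
input is normalized as fold-survival,
$(raw - \overline{blank})/(\overline{vehicle} - \overline{blank})$, in
which case the midpoint is a GI50.

`bliss_analysis()` evaluates checkerboards against Bliss independence:
with single-agent inhibitions $E_a, E_b$ taken from the vehicle row and
column, the expected combination inhibition is $E_a + E_b - E_a E_b$ and
the synergy score is observed minus expected (positive = synergy).
Inhibition is $1 -$ fold-survival clamped to $[0,1]$ (excursions beyond
±0.05 are errors, smaller ones are clamped and flagged). Because surfaces
are easier to inspect than to rank, two scalar summaries are added: the
mean score over combination cells and the maximum mean over any 2×2
window. The synthetic checkerboard generator builds its null as
multiplicative survival — on such data the scores vanish identically — and
adds any synergy bump on the *inhibition* scale, so a +0.1 bump appears as
a score of exactly +0.1 at the bumped cells.

Ligand efficiency defaults to the $1.4 \cdot pK_d / N_{heavy}$ convention
(kcal/mol per heavy atom at ~300 K); the exact $-RT \ln K_d / N_{heavy}$
at a configurable temperature is available
(`ligand_efficiency(convention = "thermodynamic")`). Selectivity ratios
carry "greater-than" semantics when the off-target constant is only a
lower bound. Tumor volumes use the sphere formula on the geometric-mean
radius of three caliper diameters, and free drug is total concentration
times unbound fraction.

## Flow-cytometry biomarkers

Event tables carry DNA content (calibrated to diploid = 1), two marker
intensities, and a tumor-identity flag. Gates are conjunctive and nested:
tumor; mitotic = tumor ∧ DNA in the 4n window ∧ mitosis-marker positive;
and among mitotic cells, those below the activation-marker threshold. The
published gating windows for this assay are not available, so all gates
are configuration with documented defaults: 4n window [1.8, 2.2] diploid
units, positivity thresholds 3 (between the generator's lognormal negative
and positive populations at 0.5 and 10). The two end points are the
fold-change in mitotic fraction versus vehicle and the fraction of mitotic
cells that lost activation, each with a percentile bootstrap CI. For a
binary per-event statistic, resampling $n$ events with replacement makes
the resampled count exactly $\mathrm{Binomial}(n, \hat p)$, and the
bootstrap is implemented through that identity — statistically identical
to index resampling and orders of magnitude faster.

## What the synthetic data emulates — and what it does not

The generators produce every input the pipeline consumes, with ground
truth recorded, and are pure functions of (parameters, seed); the
temporary RNG state is restored afterwards, so they never disturb the
caller's stream.

* **FP titrations**: twelve 3-fold dilutions in triplicate from 100 µM,
  anisotropy from the exact competition model plus Gaussian read noise
  (σ = 2 mP by default, a typical plate-reader figure).
* **Imaging plates**: 96-well geometry, 12 fields/well of 280 px at
  0.65 µm/px; ~10 cells per field of which 28% mitotic, giving ~100
  mitotic cells per triplicate well. Nuclei are 4.5 µm-radius discs;
  mitotic cells add a 15 µm-radius diffuse marker body — deliberately
  larger than the 25 µm top-hat element so the opening removes it — and a
  spindle rendered as a capsule (8 µm long, 1.5 µm half-width). The
  readout sits on the spindle footprint or, with the dose-dependent
  mislocalization probability (a 4PL in dose), diffusely on the body.
  Read noise is Gaussian at 2% of nucleus intensity; images clamp at 0.
* **Checkerboards**: 8×8, vehicle as the first dose of each series,
  Bliss-null survival with optional inhibition-scale bump.
* **Flow events**: DNA as a two-component Gaussian mixture at 1 and 2
  diploid units (CV 4%), lognormal marker populations, programmed mitotic
  and activation-loss fractions.

These are geometric and statistical stand-ins, not microscope or cytometer
physics: no point-spread function, no illumination gradients, no touching
nuclei (separation is enforced at placement, and the scorer accordingly
does not attempt declumping), no doublets or spillover in flow, no
anaphase morphologies. Passing tests therefore demonstrate that the
*algorithms* recover known truth under realistic noise — not that the
pipeline is robust to every artifact of real acquisitions, which is the
usual division of labor between such a package and its instrument-side QC.

Problem sizes in the regression suite (a 96-well control plate, a 30-well
9-point 2-fold triplicate EC50 plate, $10^4$-event flow samples over 50
seeds, 100-seed titration recoveries) were chosen so the whole suite
exercises every claim at meaningful statistical power while remaining
routine to run during development.

## Known limitations

* The competition model assumes pure 1:1 competitive binding — no ternary
  complexes, cooperativity, or incomplete labeling.
* Fold-survival normalization trusts the vehicle wells; plate drift and
  edge effects are not modeled (the plate maps place blanks on the
  outermost wells, as the underlying assays do).
* The 4PL fitter reports, but does not correct, poorly identified plateaus
  when a titration fails to bracket the midpoint; titrations should be
  centered on the expected potency.
* FCS ingestion is out of scope: flow events arrive as plain CSV columns.
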