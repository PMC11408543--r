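---
title: "Connectome-based lesion-symptom mapping: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based lesion-symptom mapping: models, parameters, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsmr)
```

## The problem

Classical lesion-symptom mapping asks which lesioned *voxels* predict a
deficit. Connectome-based lesion-symptom mapping (CLSM) asks instead which
disrupted *white-matter connections* do: a lesion is intersected with a
normative streamline tractography atlas, each ROI-ROI connection of a gray
matter parcellation receives a disconnection severity — the percentage of
its streamlines interrupted by the lesion — and those severities become the
predictors of a behavioral or electrophysiological symptom across a patient
cohort.

`clsmr` implements this chain for a Go/NoGo inhibitory-control setting with
three symptoms per patient:

* the **performance index** $(100 - \mathrm{FA}\%)/\overline{RT}_{hit}$,
  which rewards both accuracy (few false alarms on NoGo trials) and speed
  (fast correct Go responses);
* the **N2** and **P3 global field power (GFP) amplitudes**, the mean GFP
  of the patient's correct-rejection ERP over component-specific periods of
  interest fixed on the grand average.

Because the clinical data such analyses are built on cannot be shared, the
package includes a synthetic study generator with known ground truth, so
every stage — including the statistics — can be exercised and validated
end to end.

## Disconnection severity

Lesion masks, the parcellation and streamline paths share one isotropic
voxel grid (`grid_spec()`). A streamline is an ordered voxel path;
`assign_endpoints()` applies the *End* criterion: a streamline belongs to
connection $(A, B)$ iff its two terminal voxels carry parcel labels $A$ and
$B$, $A \neq B$, both nonzero. Streamlines ending in background or within a
single parcel stay unassigned.

A streamline is *disconnected* by a lesion iff any voxel of its path is
lesioned — no sub-voxel geometry, since masks and atlas share the grid. The
severity of connection $(A,B)$ is

$$\mathrm{sev}(A,B) = 100 \times
  \frac{\#\{\text{disconnected streamlines of } (A,B)\}}
       {\#\{\text{streamlines of } (A,B)\}} .$$

`voxel_disconnection_map()` marks every voxel on the full path of each
disconnected streamline (disconnection propagates along the whole tract,
well beyond the lesion), and `coverage_map()` counts, per voxel, the
patients whose lesions disconnect a streamline through it; thresholding
that count (default 7 patients) yields the mask where the cohort has any
statistical power. Before testing, `filter_connections()` keeps only
connections damaged — severity strictly above a configurable threshold,
default 0 — in at least `min_patients` patients (default 7; the behavioral
and ERP analyses carry independent copies of this knob because published
analyses have used 7 and 10).

All of these operations are verified exactly against brute-force
(voxel × streamline) oracle implementations on random small instances.

## Behavioral scoring

`score_trials()` reduces a trial record to hits, misses, false alarms and
correct rejections. Hits slower than the patient's calibration threshold
RTt are flagged "too late" but remain hits for rates and reaction times;
their percentage is reported separately. Sensitivity uses the log-linear
correction: 0.5 is added to every cell of the 2×2 table before computing
rates, so

$$H = \frac{h + 0.5}{h + m + 1},\quad F = \frac{f + 0.5}{f + c + 1},\quad
d' = z(H) - z(F),\quad c = -\tfrac{z(H) + z(F)}{2},$$

with $z$ the standard-normal quantile. The corrected rates are strictly
inside $(0,1)$ even for perfect performance, which is the point of the
correction. The implementation was checked to $10^{-10}$ against an
independent quantile oracle.

The sentence defining the performance index ("100 minus the percentage of
FA divided by the response time") admits two precedences; we compute
$(100 - \mathrm{FA}\%)/\overline{RT}$ because only this reading rewards
both speed and accuracy, which is the index's stated purpose — the
alternative $100 - \mathrm{FA}\%/\overline{RT}$ would *reward* slowing.
The mean RT uses correct (hit) Go trials only.

## ERP branch

The preprocessing kept here is the part that matters for clean synthetic
data: common-average re-referencing (`rereference_average()`),
pre-stimulus baseline correction (`baseline_correct()`; the default window
is the pre-stimulus period, ~102 samples at 1024 Hz), optional bad-channel
reconstruction by multiquadric radial basis functions
$\varphi(r) = \sqrt{r^2 + \varepsilon^2}$ with a constant polynomial term
(`interpolate_bad_channels()`; $\varepsilon$ defaults to the median
inter-electrode distance), and trial averaging. Band-pass filtering and
artifact-removal plugins are deliberately out of scope — the generator
produces clean data, and those steps would be identity operations with
extra parameters.

GFP is the population (divide-by-$C$) spatial standard deviation of the
scalp field at each sample — reference-free by construction, invariant to
channel permutation and to any time-varying constant added to all
channels (asserted to $10^{-9}$ in the tests). The period of interest of a
component is the grand-average GFP peak latency ±40 ms, searched inside a
component window (defaults: N2 200–350 ms, P3 330–500 ms; both
configurable), with ties broken to the earliest sample and clipping to the
epoch flagged. POIs are fixed **once on the grand average of all
subjects** and applied unchanged to every individual GFP — there is no
per-subject peak hunting, matching how condition-level POIs are defined in
GFP methodology. POI endpoints are sample-inclusive.

## The statistical model

For each connection, `clsm()` fits the simple GLM
$y_i = a + b\,\mathrm{sev}_i + \varepsilon_i$ and uses the slope $t$
statistic, sign-flipped so positive values mean the symptom falls as
disconnection grows — the one-tailed direction in which lesions are
assumed to act. Any monotone-equivalent statistic would give identical
permutation p-values; the slope $t$ is chosen for interpretability.

Family-wise error over connections is controlled by maximal-statistic
permutation: for each of $B$ permutations of the symptom values across
patients (severities fixed — the exchangeability null), all edge
statistics are recomputed and their maximum $M_b$ recorded; then

$$p_{\mathrm{FWER}}(e) = \frac{1 + \#\{b : M_b \ge t_e\}}{B + 1},$$

the add-one (Phipson–Smyth) convention, so p-values are valid and never
zero. Defaults follow the published analysis: $B = 5000$, corrected
$\alpha = 0.05$, one family per symptom. The result object stores the full
permutation-max sample, so any stricter display threshold (e.g. the 0.01
used in figures) is recoverable without re-running; `significant_edges()`
reports at any level with parcel names attached. Constant-severity columns
are excluded before permutation (the max runs over testable edges only)
and listed in the result. Perfect fits are capped at a large finite
statistic and flagged rather than propagating infinities.

Numerical notes: correlations are clamped to $[-1, 1]$; the permutation
loop reuses the centered design, so each permutation costs one
matrix-vector product; the critical value is the empirical
$\lceil (1-\alpha) B\rceil$-th order statistic of $\{M_b\}$.

## The synthetic generator

`make_study()` builds, in causal order: phantom → streamlines → lesions →
severity matrix → symptoms. The severity matrix fed to the symptom
simulators is computed by the same disconnectome code the analysis uses,
so symptoms are causally downstream of disconnection exactly as the model
assumes, and regenerating severities from the saved lesions reproduces the
matrix bit-identically.

* **Phantom brain** (`make_phantom_brain()`): an ellipsoidal mask split
  into hemispheres, parcellated by nearest-seed growth into a cortex-like
  shell plus a deep subcortical set; the mid-depth band is the "white
  matter" streamlines traverse.
* **Streamlines** (`make_streamline_atlas()`): spline curves through
  jittered control points between random voxels of the two parcels,
  discretized to 26-connected voxel paths with endpoints pinned inside
  their parcels (bounded retries otherwise).
* **Lesions** (`sample_lesions()`): volumes drawn log-uniformly over
  0.001–1.72 % of brain volume — matching the strong median ≪ mean skew of
  unselected stroke cohorts — on the right side with probability 28/96;
  each lesion grows from a seed voxel by stochastic dilation, giving
  irregular but 6-connected unilateral masks of exact target volume. The
  generator does not model etiology, lesion age, or hemorrhagic/ischemic
  differences.
* **Behavior** (`simulate_behavior()`): ex-Gaussian Go RTs whose mean
  grows linearly with the patient's disconnection load
  $\sum_e \beta_e \mathrm{sev}_e$ on the true edges, Bernoulli NoGo false
  alarms whose rate grows likewise (clamped to [0.01, 0.99]), a small
  constant miss rate, and a per-patient RTt threshold. Baselines (FA 15 %,
  mean RT ≈ 426 ms) sit at typical stroke-cohort values. Trial-level
  randomness is binomial/ex-Gaussian only; between-patient heterogeneity
  beyond the lesion effect enters through patient-level RT and FA shifts
  with configurable SDs.
* **EEG** (`simulate_epochs()`): each trial is i.i.d. Gaussian channel
  noise plus two fixed zero-mean topographies (frontocentral N2 at 300 ms,
  centroparietal P3 at 400 ms, Gaussian time courses) scaled by
  $\max(0,\, 1 - \sum_e \beta_e \mathrm{sev}_e)$. Zero-mean patterns make
  the average-reference contract hold by construction. This is
  phenomenological — no dipole forward model, no 1/f background, no
  artifacts — so passing tests validate the pipeline's algebra and
  inference, not its robustness to real EEG noise.

Sample counts use floor-plus-inclusive-start rounding:
`n = floor((end - start) * srate / 1000) + 1`, e.g. 820 samples for a
−100…700 ms epoch at 1024 Hz. All randomness derives from one master seed
through fixed substreams per stage (`P001`'s behavior, `P002`'s EEG, the
permutation stream, … each have their own), so identical configurations
reproduce bit-identical studies and the manifest written by
`run_pipeline()` suffices to replay a run exactly.

Ground-truth effects are non-negative by construction: disconnection can
only slow responses, raise false alarms and attenuate components, matching
the one-tailed analysis. With no true edges the generator is a global
null: symptoms are independent of lesion anatomy.

## Validation design and problem sizes

The package validates itself at four levels (all in the test suite, with
the family-wise error simulation also available as
`scripts/acceptance.R`):

1. **Exactness**: disconnectome outputs equal brute-force oracles on
   random 16³–20³ instances; analytic GFP/d′/index identities hold to
   stated tolerances; the Monte-Carlo corrected p agrees with exhaustive
   enumeration of all 5040 permutations at $n = 7$.
2. **Error control**: 200 simulated global-null studies (60 patients,
   ~100 filtered connections on a shared phantom apparatus, $B = 1000$)
   must show a fraction of studies with any significant edge no larger
   than 0.05 plus two-sided 95 % binomial Monte-Carlo error. The phantom
   apparatus (48³ grid, 28 parcels, 330 bundles of 12 streamlines) is
   shared across studies — the draws that matter for independence
   (lesions, symptoms, permutations) are fresh per study; regenerating the
   identical deterministic atlas 200 times would only cost runtime.
3. **Power and specificity**: the planted effect for this check lives on a
   severity column drawn *independently of the anatomy* (zero-inflated
   uniform), appended to the phantom matrix, with noise set for population
   $R^2 = 0.25$ at $n = 60$. On a lesioned connectome, severities of
   different edges are strongly correlated, so an anatomically planted
   effect genuinely propagates to correlated neighbors — those are
   discoveries, not false positives, and specificity would be ill-defined.
   With the independent planted column, every anatomical edge is a true
   null: the planted edge must be recovered in ≥ 80/100 studies and
   anatomical edges flagged in no more than the nominal-level binomial
   bound.
4. **End-to-end recovery**: a deliberately high signal-to-noise study
   (40 patients, large lesions, strong effects, low noise) must recover
   every planted edge for all three symptoms at the stricter 0.01
   threshold, and a replay from the manifest must be bit-identical.

Problem sizes in the routine test run are scaled for quick iteration
(32³–48³ grids, 8–60 patients, $B \le 4000$); the generator's scientific
defaults (96 patients, 64 channels at 1024 Hz, 240 + 240 trials,
$B = 5000$) describe the full-size study the defaults emulate.

## Known limitations

* The phantom's geometry is convex and its parcels are compact seeds — no
  gyrification, no spatial lesion-frequency gradient (real stroke lesions
  follow vascular territories), so the coverage map's realism is limited.
* Severity correlations between edges are induced by shared lesions but
  not calibrated to any empirical connectome.
* The ERP generator has no forward model; topography checks are sign
  conventions, not physiology.
* The permutation test assumes exchangeable patients under the null; with
  covariates (e.g. lesion volume) one would residualize first — supported
  deliberately nowhere in the default path, since the published model uses
  a single variable of interest.
* `filter_connections()` treats any nonzero severity as damage by default;
  with probabilistic atlases a higher `damage_threshold` would be
  appropriate.
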