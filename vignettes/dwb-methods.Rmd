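---
title: "Models and methods behind dwbr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dwbr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwbr)
```

`dwbr` quantifies posturo-locomotor alteration in freely moving rats from a
pressure-sensitive floor, the measurement used to follow vestibular
compensation after a unilateral vestibular neurectomy (UVN). This vignette
is the package's own account of its models: what is assumed, what is
tunable, what the synthetic data generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The measurement model

The plate is a square grid of vertical-force sensors under a walled arena.
Defaults (`plate_geometry()`): 44 × 44 = 1936 cells on 25 × 25 cm — the
closest square grid to the nominal "~2000 sensors" of the commercial
device — at 30 Hz, with a one-cell wall band. Cell indices are 1-based;
`x` runs rightward along columns and `y` forward along rows, in cm. The true
grid layout of the device is unpublished; everything downstream takes the
geometry as a parameter.

Per-session outcomes (`summarize_session()`), all computed over the
*analyzable time* only:

* **Stance-time fractions** — per frame, the number of paws (FL, FR, HL, HR)
  with positive load; tail/belly contacts never count. Reported as % of
  analyzable frames for n = 0…4.
* **Front-paw contact time** — % of analyzable frames with FL (resp. FR)
  load > 0. "Contact" means load above the detection threshold; there is no
  second contact threshold.
* **Axis weight distributions** — each paw's mean load *while in contact*,
  as % of body weight, summed into front/hind and left/right.
* **Barycenter-like statistic** — with `W` the per-paw aggregated weights
  and `TWP` their four-paw total:
  `PRP = (W_FRP + W_RRP)/TWP × 100`, `PFP = (W_FRP + W_FLP)/TWP × 100`.
  `PRP + PLP = 100` and `PFP + PHP = 100` hold identically.

**Why contact-conditional means.** A healthy rat spends over a third of its
session rearing, with zero front-paw load. If per-paw weights were averaged
over *all* analyzable frames, the front axis percentage of a healthy rat
would sit near 15% of body weight and front+hind would fall far short of
100. The published healthy values this field reports (~73% hind, ~26%
front, summing to ≈ 98.5 with the small remainder on tail/belly) are only
arithmetically consistent with each paw's load averaged over the frames in
which that paw is down — which is also the per-paw quantity the commercial
acquisition software reports. `dwbr` therefore defaults to contact-
conditional means both for the axis percentages and for the barycenter
aggregation (`barycenter(method = "contact_means")`). Two alternatives
remain selectable: `"ratio_of_sums"` (sums over all analyzable frames
before forming ratios) and `"mean_of_ratios"` (average of per-frame
ratios); all three satisfy the complementarity identities and coincide when
every paw is loaded in every frame.

## 2. The synthetic rat

The device and live animals are not reproducible in CI, so the generator
(`simulate_session()`) states one explicit world. Per-frame ground truth
(state, per-support loads, paw centroids, body pose) makes every downstream
stage testable against what was actually rendered.

**Behavioural schedule.** Four states: quadruped stance, bipedal rearing,
locomotion, wall-leaning. Dwell times are exponential (means 2 s for
quadruped, 1.5 s otherwise). A pure first-order Markov chain cannot pin
empirical occupancy to the configured rates at 5 minutes (the sampling
standard deviation of a 38% occupancy is ≈ 0.05), so each new segment's
state is sampled with probabilities tilted by the remaining occupancy
deficit. The schedule still looks like stochastic bout alternation, and
empirical occupancies land within ~0.01 of the configured
`rearing_rate`/`wall_lean_rate` at 300 s (tested at fixed seeds).

**Loads.** Body weight `W` (default 300 g, inside the 250–350 g range used
for adult rats) splits by two fractions: paw-borne front share
`0.26 + ap_bias` and right share `0.5 + lateral_bias`, applied
multiplicatively per paw, so `PRP = 50 + 100·lateral_bias` by construction.
In quadruped stance a small `tail_belly_load_fraction` (default 0.02) rests
on the belly and tail — hence front+hind ≈ 98 in a pure-stance session.
When rearing, the rat sits back with 25% of `W` on the tail/haunches, which
keeps each hind paw's contact-conditional load near its quadruped value —
the property the published healthy hind/front percentages require.
Locomotion is a duty-0.75 four-beat gait (one paw in swing at any instant,
stride 0.5 s) with the swung paw's share renormalised onto the stance paws;
wall-leaning transfers 5% of `W` to a blob in the wall band.

**Rendering.** Paws are 2 × 2 cell blocks (load split equally), the belly a
3 × 3 block, the tail a 6-cell line trailing the body; the body turns toward
its direction of travel at ≤ 12°/frame (no instantaneous pivots — an
instantaneous 180° layout flip is untrackable in principle, by any method).
Noise, when enabled, is zero-mean Gaussian per cell (default sd 0.5 g),
truncated at zero and quantised at a 0.5 g floor so recordings stay sparse;
the device's real noise spectrum is unpublished, and these constants were
chosen once to make detection non-trivial, not calibrated to data.

**What the generator does not emulate** — and therefore what a green test
does not establish: real paw-print shapes and sizes, stepping kinematics of
swing paws, grooming and immobility, body-weight change across days, the
device's proprietary file format, and any sensor nonlinearity. Green tests
establish that the pipeline recovers what the generator put in, at the
stated tolerances.

**Lesion phenotypes.** `make_phenotype_profile(day, condition)` encodes the
qualitative post-lesion course as defaults: rearing collapses from ~38% to
≤ 8% on D1–D3 and recovers by D7; weight shifts forward (`ap_bias ≈ +0.05`)
and to the contralateral right (`lateral_bias = +0.031`, i.e. +3.1 PRP
points) on D1–D2; the lateral bias reverses to the lesioned left side
(−0.02) from D7; the symptom set decays 15 → 10 → 6 → 3 → 1. The
`reactivated` condition (tail-hanging test, modelled purely as a phenotype
switch) halves D7–D21 rearing. These are stated once and not tuned further.

## 3. Detection and assignment

**Blobs.** Cells ≥ `activation_threshold` (default 1 g) are grouped under
8-connectivity (diagonal paw-pad cells merge); components below `min_cells`
(default 1) are dropped. Blobs are ordered by descending load, ties broken
by the smallest member cell. Partition identities (every activated cell in
exactly one blob; loads conserved) and threshold monotonicity are tested as
properties.

**Analyzable mask.** A frame is excluded when a blob of at least
`wall_min_load` (5 g) touches the wall band, or when the assignment stage
flagged it ambiguous. The 5 g floor exists because truncated-Gaussian noise
puts a ≥ 1 g speckle somewhere in the 168-cell wall band in ~98% of frames;
a speckle is not a paw against the wall. The ambiguity flag is the
package's deterministic surrogate for the experimenter's manual correction
step — ambiguous frames are dropped, never guessed.

**Pose and labels.** The body centroid is the load-weighted mean of blob
centroids (blobs ≥ 5 g only, so scattered speckle cannot drag it). The
heading of `estimate_body_pose()` is the displacement between consecutive
15-frame window means of the centroid, defined when it exceeds 0.8 cm —
thresholds chosen so that posture transitions (which shift the load
centroid by up to ~0.6 cm) do not masquerade as turns while 3 cm/s walking
(1.5 cm per window) does register. The classifier, however, does not trust
the displacement heading per frame: the load centroid wobbles ±1.3 cm with
the gait cycle (a 3-point support cannot preserve the centroid), which makes
any displacement-only heading flip and stick. Instead the body **axis** is
estimated from the paw-candidate geometry itself — the principal axis of
four candidates, or the perpendicular of the closest (lateral) pair for two
or three — and only its *sign* is taken from the previous orientation. A
sign error would need a > 90° single-frame rotation, which the ≤ 12°/frame
world cannot produce.

Label rules: a blob within 1.8 cm of the body centroid is BELLY; an
elongated blob (load-weighted principal-axis ratio ≥ 2.5) trailing behind
all candidates is TAIL; compact blobs between `min_paw_load` (10 g) and 60%
of frame load are paw candidates, split front/hind along the axis and
left/right across it. A lone lateral pair is read as the hind paws — a
rearing rat stands on its hind paws, never on its front paws alone. Two
blobs competing for one identity, or more than four candidates, flag the
frame ambiguous. The 60% cap deliberately exceeds one half because a
rearing hind paw carries ~49% of the frame load; a 40% cap would make
bipedal stance unclassifiable.

**Tracks.** Per identity, consecutive observations are linked under a
2 cm/frame centroid gate; gaps ≤ 2 frames inside a contact are bridged with
linearly interpolated load; longer gaps split the contact interval
(half-open `[start, end)`). Gate, gap and window are conventions exposed in
`assign_params()`.

## 4. Syndrome score and exclusion

`score_symptoms()` is additive over tumbling 5, retropulsion 4, circling 3,
bobbing 2, head tilt 1 (range 0–15; canonical states 15/10/6/3/1; empty set
scores 0). The source protocol's text rates the bobbing+head-tilt state 2 in
one place and 3 in another; the additive convention (3) is adopted because
it is the only one consistent with the other four states, and the ratings
are exposed as data (`symptom_ratings()`) rather than buried. An animal is
excluded when it still shows the maximal syndrome (15) at the 48 h
observation, or when its acquisition files are unusable; a missing 48 h
observation yields "indeterminate", not exclusion.

## 5. Statistics layer

All functions take an animals × days `measure_matrix()` with explicit `NA`
for missing sessions and report the n actually used — animal counts in this
kind of study are untidy (enrolled vs analysed vs excluded), so silence is
not an option.

* `group_summary()` — per-day mean and SEM (`sd/sqrt(n)`); SEM is `NA` for
  a single animal, by documented convention.
* `rm_anova(matrix, alpha)` — one-way repeated-measures ANOVA with day as
  the within factor, on listwise-complete rows. `F = MS_day/MS_error`,
  `df = (d−1, (d−1)(n−1))`. The Greenhouse–Geisser epsilon is computed and
  reported but **not** applied, since the original analysis applied none;
  `p_gg` is available to the reader. Degenerate inputs: a constant table
  gives F = 0; zero error variance with real day effects gives F = Inf.
* `tukey_kramer()` — studentized-range pairwise comparisons with the
  unequal-n correction, pooled within-day mean square as error term; reduces
  exactly to Tukey HSD at equal n (tested against `TukeyHSD`).
* `bonferroni_pairwise()` — paired t-tests over a day set (default
  D0/D1/D21) with `p·n_pairs` correction.
* `critical_value_decision()` — reject iff F exceeds `qf(1−α, df1, df2)`.
  The protocol's stated "α = 0.01%" conflicts with its own "confidence
  superior than 99%" and with its F-table value of 2.8, which equals
  `qf(0.99, 8, 64)`; `dwbr` therefore makes `alpha` a required explicit
  argument everywhere — there is no silent default — and prints the implied
  confidence level.
* The "several factors" of the original ANOVA are unstated; the package runs
  one-way RM per condition, which is what its printed degrees of freedom
  support.

Oracles in the test suite are independent routes: `aov()` error strata for
the RM decomposition (swept over a deterministic family of small integer
tables), `TukeyHSD` at equal n, a hand-written studentized-range computation
at unequal n, the qbeta identity for F quantiles, and a 2000-replicate null
simulation that checks the RM-ANOVA rejects at 5% ± 1.5% under H0.

## 6. Reproducibility and IO

Everything stochastic flows from explicit integer seeds: a session is
bit-identical given `(phenotype, sim_config)`, and `run_study()` derives one
sub-seed per session from the study seed, so re-running any subset
reproduces the full run's sessions. Session containers are plain text
(key-value metadata, sparse `frame,row,col,load` cell table, ground-truth
table); a dense 300 s frame stack would be ~120 MB of text for no benefit.
Reports carry the MD5 of the scientific configuration (output paths
excluded) in a header comment. The per-animal supplementary spreadsheet of
the original study is not redistributable; `synthetic_supplementary_data()`
is a clearly labelled stand-in that carries the published group means and
SEMs as per-animal values, for exercising `read_supplementary_table()` and
`group_summary()` — it contains no information beyond those statistics.

## 7. Known limitations

* The generator's gait renormalisation raises stance-paw loads while
  walking, so contact-conditional front+hind can slightly exceed 100% of
  body weight in locomotion-heavy sessions (~102–103 for the healthy
  preset); real plates report ≈ 98–99. The discrepancy is a property of the
  stated gait model, documented rather than tuned away.
* Wall-leaning is stylised: the body does not move to the wall; a wall-band
  blob simply appears with 5% of the body weight. The excluded-time
  accounting this exercises is the point; the posture is not.
* Classification assumes at most one animal and no prone/immobile postures
  beyond the four states.
* With heavy noise (sd well above 1 g at the default 1 g threshold),
  speckle merging can erode blob shapes; raise `activation_threshold` or
  `min_cells` together with the noise.
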