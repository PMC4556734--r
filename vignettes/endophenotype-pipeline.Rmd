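---
title: "Methods: connectivity endophenotype analysis and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity endophenotype analysis and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the generative
model behind the synthetic cohorts, the analysis pipeline and its
parameters, the numerical conventions, and the design choices made where
the design was genuinely open.  It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The scientific design

The pipeline targets a three-group endophenotype design: participants with
an autism spectrum condition (ASC), unaffected siblings of autistic
individuals (SIB), and typically-developing controls (CON), matched in
size (14 per group).  The central quantity is whole-brain functional
connectivity; the endophenotype hypothesis predicts a graded group
difference — controls strongest, ASC weakest, siblings intermediate — with
a significant ASC-vs-CON contrast.  A significant SIB-vs-CON contrast is
of interest but not required: an endophenotype is defined by the marker
appearing in affected individuals *and* being shifted in their relatives,
not by relatives differing from probands.

## The synthetic cohort model

Real covariance structure in region-of-interest fMRI is unknown and
subject-specific, so the generator uses a factor model, which is positive
semidefinite by construction and exposes exactly one knob per group for
the hypothesis of interest.  For a subject in group *g* with nodes
partitioned into functional networks, the signal at node *i* is

    x_i(t) = g · G(t) + w · F_{net(i)}(t) + c1_i · CSF(t) + c2_i · WM(t)
             + sigma · eps_i(t) [+ artifact]

where `G` is a global factor shared by all nodes, `F_k` one factor per
network, `CSF`/`WM` two nuisance signals with known half-normal per-node
loadings, and `eps` i.i.d. Gaussian noise.  All factors are unit-variance
Gaussian series band-limited to 0.01–0.1 Hz at the sampling interval
(TR = 2 s), so the preprocessing band-pass is non-destructive for signal:
what the filter removes is noise and artifact, never the modelled
connectivity.  In the noiseless, confound-free limit the model implies a
correlation of 1 between same-network nodes and g²/(g² + w²) between
networks, which the test suite checks against simulation at T = 2000.

Defaults: `g` = 0.8 / 0.6 / 0.4 for CON / SIB / ASC,
`within_network_loading` = 0.4, `noise_sd` = 1, T = 300.  No published
effect size pins these down; they were chosen once as values giving a
clearly detectable but not degenerate gradient at realistic scan length,
and the no-effect control (equal `g`) is simulated alongside wherever the
recovery properties are tested.

**Parcellation.** Centroids are drawn uniformly in a brain-scale ellipsoid
(semi-axes 70 × 85 × 60 mm, rejection sampling) and assigned to 14
networks of near-equal size; 9 networks are flagged as analysed for hub
tallies.  The packaged 264-region stand-in plus a 6-node exclusion list
(both generated synthetically, marked `_synthetic` in the file names)
yields the 258 analysis nodes.  Only relative distances matter downstream,
so uniform geometry is an adequate stand-in for stereotaxic coordinates.

**Motion.** Realignment traces are cumulative Gaussian random walks over
the six rigid-body parameters (step sd 0.02 mm translations, 2e-4 rad
rotations) plus persistent repositioning spikes: with probability 0.02 per
frame, one translation jumps by 0.5 mm (random sign) and stays — heads
reposition, they do not oscillate back.  Each subject's magnitudes are
scaled by a lognormal multiplier (sd 0.5), reproducing the usual cohort of
mostly low movers with a few big movers.  Framewise displacement is
FD = Σ|Δtrans| + 50 mm · Σ|Δrot|.

**Motion artifact.** When `artifact_gain > 0` the generator injects
`gain · FD(t) · w_i`, where the static spatial profile `w` is drawn per
subject from a Gaussian process with mean 1 and covariance
exp(−d/`artifact_distance_scale`), default scale 50 mm.  Three properties
motivated this construction over a profile redrawn at every frame:

1. expected inter-node sharing decays exactly as exp(−d/scale), giving the
   distance-dependent inflation of short-range connectivity that motion
   artifacts show;
2. the positive profile mean makes movers show systematically *higher*
   mean connectivity, the signature used to argue that group
   hypoconnectivity is not a motion artifact;
3. the artifact time course is FD(t) itself, which the squared-derivative
   confound regressors track well (for Gaussian steps, |Δp| and (Δp)²
   correlate at ≈ 0.94), so nuisance regression demonstrably shrinks the
   artifact's distance slope — the qualitative behaviour a real cleanup
   pipeline should show, and a property the test suite asserts.

What the generator does *not* emulate: haemodynamics, task-evoked
structure (conditions differ only by seed and label), spatially realistic
network topography, non-Gaussian noise, and scanner drifts.  Passing
recovery tests therefore shows that the analysis chain detects the
structure it assumes, not that real data satisfy those assumptions.

## Preprocessing

Order of operations is despike → regress → filter in one pass per subject.
Regression precedes filtering so that projecting out confounds cannot
reintroduce out-of-band energy.

- **Confound set**: the 8 base series (6 realignment + CSF + WM) are
  expanded to 32 regressors: base, backward-difference derivatives (first
  row zero), squares of base, squares of derivatives.  Constant and exactly
  duplicated columns are dropped before fitting (with synthetic motionless
  traces, many expansion columns are degenerate); genuinely collinear
  columns are an error naming the offenders.
- **Filter**: an ideal zero-phase DFT mask (bins below 0.01 Hz, including
  the mean, and above the optional 0.1 Hz edge are zeroed).  An ideal mask
  is deterministic, linear and idempotent, all of which are tested; an IIR
  realisation would be none of these exactly.  The low-pass can be
  disabled (`lowpass_hz = NULL`) for the task-evoked variant, and
  `run_pipeline(compare_lowpass = TRUE)` reports both variants side by
  side from identical cohorts.
- **Despike**: values deviating more than 4 MADs from a running median
  (window 7) are shrunk to that bound.  On smooth series the running
  median interpolates the data and the MAD of the deviations degenerates
  to zero; the scale then falls back to the standard deviation.  Off by
  default for synthetic runs.

## Connectivity and graph metrics

- **Threshold**: the retained count is round(density · M) with half
  rounded *away from zero* (R's default banker's rounding would make edge
  counts depend on parity), ties at the cut broken by (row, column) order.
  "Strongest" means largest signed correlation — at 20% density retained
  weights are in practice positive, and a warning is raised if not; an
  absolute-value mode exists behind `mode = "absolute"`.  At N = 258 and
  density 0.2 this retains 6631 of 33153 pairs.
- **Whole-brain connectivity** defaults to the mean over retained edges; a
  mean over all pairs (zeros included) is available because group averages
  of thresholded matrices can be defined either way.
- **Clustering** uses the Onnela geometric-mean form with weights scaled
  by the network maximum — the de-facto standard for weighted undirected
  matrices; nodes with binarized degree < 2 contribute 0.
- **Efficiency** maps weights to lengths as 1/w and averages inverse
  shortest-path lengths, with disconnected pairs contributing 0.
  Both metrics are verified against brute-force oracles (exhaustive triple
  enumeration; Floyd–Warshall) on hundreds of random graphs with N ≤ 6.
- **Null ensemble**: topology is randomised by degree-preserving
  double-edge swaps (10 attempted swaps per edge, via igraph); the
  original weight multiset is then reassigned by greedy rank matching
  against residual node strengths in 20 re-ranked batches.  Node count,
  edge count, degree sequence and weight multiset are preserved exactly —
  exact strength-sequence preservation is impossible in general — and the
  strength correlation with the original exceeds 0.9 by contract (in
  practice ≈ 0.999 at full scale).  Normalised C and E divide by the
  ensemble mean.
- **NDI** regresses (subject − template) strengths on the template with an
  intercept, so NDI(k·s, s) = k − 1 exactly.  The template is the
  control-group mean; alternative group templates and a leave-one-out mode
  are provided for homogeneity analyses.
- **Hubs**: top round(0.2 · N) nodes by strength (52 at N = 258), ties
  broken by node id; counts are tallied over the 9 analysed networks.  A
  degree-based hub definition is available as an alternative ranking but
  no equivalence claim is attached to it.

## Motion QC

Per-edge FC–motion correlations across subjects are profiled against
inter-node Euclidean distance: a centred moving average (window 5% of
edges, minimum 3, shrunk at the boundaries — padding would bias the ends)
for display, and an OLS line through the *raw* per-edge correlations for
the slope, reported per metre.  Fitting the raw correlations rather than
the smoothed curve avoids making the slope depend on the display window.
The subject-level motion scalar is configurable (`max_fd` default,
`mean_fd`, `max_spike`), since maximum framewise displacement is the more
stringent artifact probe while mean motion is the conventional summary.
Significance uses 100 permutations of the subject→motion assignment with
the add-one estimator p = (1 + #{|null| ≥ |obs|})/(1 + n_perm): 100
permutations cannot support p < 1/101, and the estimator is never zero.
Calibration (rejection rate at the nominal level under no artifact) is
asserted in the test suite over 200 simulated cohorts.

## Group statistics

One-way fixed-effects ANOVA with (k−1, N−k) degrees of freedom — for the
3 × 14 design that is (2, 39); note that some statistical software
historically labels the error df as N − 1, printing (2, 41) for the same
F value, a notational quirk deliberately not replicated.  Planned
comparisons use Student's pooled t (df = n₁ + n₂ − 2 = 26 for two groups
of 14) rather than Welch, matching the reported df convention of this
design.  `anova_from_summary()` reconstructs F from printed means, sample
SDs and group sizes via SSB = Σ n_g(m_g − m̄)², SSW = Σ (n_g − 1)sd_g²,
and is algebraically identical to the raw-data ANOVA (a property tested to
1e-10 over 500 random datasets).  No multiple-comparison correction is
applied anywhere, in keeping with the exploratory design; the statistics
table records the number of tests performed instead.

The pattern classifier codifies the endophenotype rule: significant ANOVA
*and* strictly monotone group means CON > SIB > ASC *and* significant
ASC-vs-CON contrast (SIB-vs-CON reported, not required); the inverted
ordering gives `reversed_endophenotype`; a significant ANOVA without
monotone ordering gives `nonlinear`; anything else `none`.  Ordering uses
sample means without a formal trend test, because the design runs none.

## Pipeline orchestration and reproducibility

Every random stage derives its seed as `stage_seed(master, stage_name)`,
so changing, say, the permutation count cannot perturb cohort generation,
and identical configurations give bit-identical reports.  Conditions are
independent simulation passes sharing the group assignment; with more than
one condition the per-subject metric means are also analysed collapsed
across conditions, plus a cross-condition correlation matrix.  The report
embeds the fully resolved configuration — no hidden defaults.

## Problem sizes in the test suite

The suite exercises full scale (258 nodes, 14 per group, T = 300) where
the claim is about the study design itself — edge/hub counts, null-model
strength tracking, gradient and pattern recovery, the NDI expectation
ordering — and scaled-down cohorts (20–30 nodes, T = 100–200) for
calibration loops that need hundreds of replicates, such as the
permutation-test level and the artifact slope sign.  These sizes are the
package's chosen compromise between statistical resolution and a test
suite that runs in minutes.

## Known limitations

- The NDI group separation (SIB vs ASC) is an expectation-level effect in
  the factor model: proportional thresholding compresses between-group
  strength-profile differences, so single synthetic cohorts frequently
  invert SIB and ASC mean NDI even when whole-brain connectivity separates
  cleanly.  The suite therefore asserts the ordering of means over 20
  seeded cohorts, not per-cohort ordering.
- Exact strength-sequence preservation in the null model is approximate by
  necessity; the 0.9 correlation contract is the operative guarantee.
- The despike rule and the 32-regressor composition are explicit,
  documented stand-ins for tool-internal behaviour that is not fully
  specified anywhere; both are parameterised.
- Group statistics assume independent subjects; no repeated-measures
  modelling is attempted for multi-condition runs beyond averaging.
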