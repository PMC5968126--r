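---
title: "Models and methods behind fibrofocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrofocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Focal atrial tachycardia (FAT) is driven by an ectopic focus that can sit
almost anywhere on the atria. Body-surface potential maps (BSPM) acquired
with multi-electrode vests carry enough information to point at the region
of origin non-invasively: each atrial activation sequence leaves a
characteristic spatial signature in the per-electrode time integral of the
P wave (the body-surface potential integral map, BSPiM). Atrial fibrosis
perturbs conduction — slowing wavefronts, blocking them outright, and
reshaping activation sequences — and therefore degrades any BSPiM-based
localization. `fibrofocal` provides a desk-scale simulation and analysis
chain to quantify that degradation: membrane models, a tissue-level
monodomain solver for controlled slab experiments, a stochastic fibrosis
generator staged on the Utah scale, a synthetic two-chamber atlas with an
eikonal activation surrogate, a dipole-sum forward model, and a clustering /
validation / classification pipeline from BSPiMs to atrial regions.

# Membrane models

Myocytes follow the Courtemanche–Ramirez–Nattel (CRN) human atrial model
(21 state variables; constants recorded in
`inst/extdata/crn_constants.yaml`). Regional electrophysiological
heterogeneity is expressed as multiplicative factors on three maximum
conductances — transient outward (`g_to`), L-type calcium (`g_CaL`) and
rapid delayed rectifier (`g_Kr`) — across 11 atrial regions
(`atrial_region_table()`). The table has 11 columns even though the
heterogeneity is usually described as covering 10 regions; we implement all
11 and treat the crista terminalis / Bachmann's bundle entry as one label.

Fibroblasts follow the MacCannell active model: exactly four membrane
currents (`I_Kv`, `I_K1`, `I_NaK`, `I_bNa`), fixed intracellular
concentrations, and a capacitance of 6.3 pF
(`inst/extdata/maccannell_constants.yaml`). The uncoupled fibroblast rests
near −49 mV, well above the myocyte resting potential, which is what drags
the resting potential of coupled myocardium upward near fibrotic tissue.

Integration uses Rush–Larsen exponential updates for gating variables and
forward Euler for concentrations, `dt = 0.02` ms by default — the standard
stable choice for CRN-class models. Voltage-dependent gate coefficients are
tabulated on a 0.02 mV grid per `dt` and interpolated linearly; this
changes action-potential metrics by well under the measurement tolerances.
The stimulus convention is a rectangular pulse of 2 ms at twice the
diastolic threshold (found by bisection), expressed in pA/pF with
depolarizing currents positive.

Single-cell pacing (`pace_single_cell()`) runs 20 beats at a 500 ms basic
cycle length before measuring the final beat, mirroring the stabilization
used for the tissue models. Note that a tissue-level "control" action
potential differs from the isolated cell's: electrotonic loading in a
propagating wavefront blunts the peak to a few mV (against ~+28 mV in the
isolated cell) and reshapes APD; `fibrofocal` exposes both readings (the
paced single cell, and probe traces from `solve_monodomain()` runs).

# Monodomain tissue solver

`solve_monodomain()` integrates the monodomain reaction–diffusion equation
on a regular voxel lattice with Godunov operator splitting: a membrane
reaction step (CRN or MacCannell per voxel label) followed by explicit
diffusion through a 7-point anisotropic Laplacian with harmonic-mean face
conductivities and no-flux boundaries. Local activation time (LAT) is the
first upward crossing of −40 mV after stimulus onset, interpolated within
the step. Mixed tissue is equilibrated for 200 ms before the stimulus so
that myocyte–fibroblast resting gradients are established.

Conductivity is expressed directly as a monodomain diffusivity (mm²/ms).
Three tissue-level constants are calibrated once on the 50 × 50 × 0.3 mm
slab experiments and then frozen (`slab_calibration()`):

* `d_healthy = 0.3068` mm²/ms — bisected so a planar wavefront crosses the
  healthy left-atrial slab in 59.0 ms (conduction velocity ≈ 0.85 m/s).
  The regional table also lists a left-atrial longitudinal conduction
  velocity of 63.3 cm/s; the slab anchor wins for slab experiments, and the
  table's velocities drive the organ-scale surrogate.
* `d_fibroblast_factor = 0.25` — fibroblast-voxel diffusivity along the
  fiber axis relative to healthy tissue.
* `fb_density` — a multiplier on the fibroblast membrane current density
  standing for the fibroblast count per voxel, tuned so that a one-voxel
  (0.3 mm) fibroblast barrier delays the slab crossing by about 5%, a
  two-voxel barrier by about 20%, and a three-voxel barrier blocks.

Fibrotic tissue is strongly anisotropic: its transverse diffusivity
fraction is far below the healthy 0.35. This is required for the two slab
experiment families to coexist — the barrier experiments need substantial
longitudinal coupling through the band, while the conduction-channel
experiments need the lateral fibroblast pull to be weak enough that a
1.5 mm healthy channel rests near −66 mV and still conducts. Isotropic
fibrotic voxels make every channel block, so the package treats fibrosis as
raising transverse resistance, in line with the histology of patchy
fibrosis (collagen strands along fibers).

# Stochastic fibrosis generator

`place_seeds()` distributes 50 seeds across the pulmonary-vein ostia,
coronary sinus, fossa-ovalis ring and posterior left-atrial wall (equal
weights by default; the literature gives proportions only qualitatively).
`grow_fibrosis()` expands the fibrotic set by whole frontier layers and
reverts each newly added contour element with probability `drop_prob = 0.3`
(chosen once to produce irregular contours with occasional surviving healthy
islands). Growth stops at the first layer where the size-weighted fraction
reaches its target, so the achieved fraction can overshoot by at most one
frontier layer — on the default atlas this is a few percent at the higher
stages, and stage bands should be read accordingly.

Staging follows the Utah quartiles (`classify_utah_stage()`: I < 8.1%,
II < 16%, III < 21%, IV ≥ 21%, half-open with the boundary belonging to the
upper stage). Stages IV and V share the top quartile and are realized as
two growth targets; the default targets `c(0.02, 0.12, 0.18, 0.28, 0.40)`
span the 2–40% range. Within a case, stages are grown incrementally from
the same seeds and RNG stream, so stage sets nest and the whole model is
byte-reproducible from `(domain, seeds, targets, rng_seed)`.

# Synthetic atlas and eikonal activation

The anatomical stand-in (`build_atlas()`) is deliberately simple: two
subdivided icosahedral shells (2562 vertices each by default) scaled into
left- and right-atrial ellipsoids, labeled geometrically with the regions
the pipeline needs (posterior LA wall, four PV ostia, appendages, valve
rings, fossa ovalis and its ring, coronary sinus, crista terminalis /
Bachmann's bundle band, pectinate muscle field), and joined by explicit
inter-atrial connection edges (Bachmann's bundle, fossa-ovalis rim,
coronary sinus). A torso ellipsoid sampled with a Fibonacci lattice
(14,157 nodes by default) carries the electrodes. 57 ectopic foci are
placed by farthest-point sampling (32 LA + 25 RA), with a marked primary
subset of 19 used for fibrotic simulations. The real anatomy's focus
coordinates are unavailable, so foci are placed by region spread only; the
atlas is a surrogate that preserves labels, two-chamber topology and
conduction heterogeneity, not patient geometry.

Organ-scale activation uses fast marching (`eikonal_activation()`) rather
than the monodomain solver: per-vertex conduction speeds come from the
regional table (cm/s), and fibrosis modulates them through rules calibrated
on the slab experiments — fibrotic vertices at a patch boundary are slowed
by a factor of 10 (a 0.3 mm crossing at 0.85 m/s plus a 3 ms delay is an
effective ~0.1× speed), and fibrotic vertices whose entire neighbourhood is
fibrotic (a local width of three elements-equivalent or more) are blocked.
A focal trigger excites a small neighbourhood rather than a point: capture
fails — and the run is excluded, mirroring the exclusion of non-propagating
simulations — only when the focus vertex and its one-ring are all blocked.
Under the default conditions this yields no exclusions below stage 3.

The fast-marching solver uses the Kimmel–Sethian triangle update with an
edge fallback, jump edges for the inter-atrial connections, and an exact
straight-line near field around each source (first-order fast marching is
least accurate where the front is strongly curved). On a subdivided
icosphere its arrival times match closed-form great-circle times within 2%.

# Forward model and BSPiM

`build_lead_field()` projects atrial sources to torso electrodes with an
infinite homogeneous volume-conductor dipole sum: each surface triangle
contributes a current dipole proportional to its area times the in-plane
gradient of the transmembrane voltage, observed through the `r/|r|³`
kernel, with a zero-mean reference across electrodes. Torso inhomogeneity
(lungs, liver, bone) is out of scope; this changes absolute potentials but
preserves the spatial pattern structure the pipeline consumes.

Per-vertex transmembrane signals are the paced action-potential template
shifted to each vertex's LAT (1 kHz sampling); unreached vertices stay at
rest, and fibrosis-adjacent vertices are amplitude-attenuated (factor
0.578, the coupled-to-control amplitude ratio class observed in the slab
probes). White Gaussian noise is added at a signal-to-noise power ratio of
3 (≈ 4.8 dB; powers are treated as relative, only the ratio is physical),
then each channel is smoothed with a Savitzky–Golay filter (window 21
samples, order 3 — unstated in the source literature, chosen as a standard
P-wave setting).

The P-wave integral window is `[0, max LAT + 10 ms]` — the depolarization
sequence. This is a substantive choice: the time integral of a shifted
template over a window that contains the whole action potential is
shift-invariant, so integrating over activation *and* full repolarization
would erase the activation-sequence information the BSPiM exists to encode
(we verified this: with a full-AP window, within-focus feature distances
exceed between-focus distances and clustering collapses). Integration is
trapezoidal per electrode, and the map is normalized to [−1, 1] by its
maximum absolute value.

# Localization pipeline

* **Electrode reduction** (`reduce_electrodes()`): recursive bisection of
  the torso nodes along the widest axis into 256 size-balanced contiguous
  patches (≈ 55 nodes each on the default torso), one seeded random
  representative per patch.
* **Clustering** (`ward_cluster()`): Ward variance-minimization linkage on
  Euclidean distances (`stats::hclust`, `ward.D2`), cut at K = 2…10.
* **Cluster validation** (`ectopic_graph()`, `compute_metrics()`): each
  focus owns the geodesic-Voronoi patch of atlas vertices nearest to it;
  foci are graph-adjacent when their patches share a border. Persistence
  of a focus is |label set|/K. OR is the percentage of foci appearing in
  more than one cluster. CR counts isolated foci: a member of a
  multi-focus class with no same-class neighbour is isolated, and CR is
  the percentage of non-isolated memberships — this is the node-based
  reading that reproduces the worked example (two isolated foci among 19
  give 89.4%); a largest-component variant (`cr_largest`) and a
  class-connectivity variant (`cr_cluster`) are also reported. Region
  areas are summed per cluster with double counting of multiply-labeled
  foci, then averaged over clusters.
* **Feature selection** (`chi2_select()`): chi-square statistic of
  per-class sums of each feature min-max rescaled to [0, 1] (the statistic
  needs non-negative inputs; the SVM consumes the original features). One
  global ranking serves every N, so larger selected sets contain smaller
  ones; ties break toward the lower electrode index.
* **Classification** (`classify_cv()`): RBF-kernel SVM (`e1071::svm`),
  4-fold stratified cross-validation (75%/25% train/test), cost and kernel
  width tuned per training split by an inner 3-fold grid search (cost in
  {1, 10, 100}, width in {0.5, 1, 2} × 1/p).

# Numerical choices and degenerate inputs

Ties everywhere break toward the lower index; all stochastic steps
(seeding, growth reversion, representative draws, fold shuffles, noise)
take explicit integer seeds and restore the caller's RNG state. Degenerate
cases are errors with named conditions: non-finite membrane states,
stimuli outside the grid or on dead tissue, channels or barriers wider
than the slab, zero-signal noise calibration, all-zero integral maps
(warning, normalization skipped), single-class label vectors, and blocked
focus neighbourhoods (`no_capture`).

# Problem sizes

The package's study conditions are: 167 × 167 × 1 voxel slabs (0.3 mm);
atlas subdivision 4 (5124 vertices, 10,240 faces), 14,157 torso nodes
reduced to 256 electrodes; 5 fibrosis cases × 5 stages; 57 foci (19
primary), giving 57 + 475 candidate runs. These sizes run the full
pipeline on a single CPU in minutes while keeping every structural feature
of the full-scale problem.

# Known limitations

The fibroblast coupling strength that reproduces the barrier and channel
experiments makes voxel-scale *patchy* fibrosis aggressive: at mild stages
the patchy slab conducts with the expected resting-potential elevation and
amplitude reduction near patches, but at dense stages (III and above on the
0.3 mm lattice) the ragged myocyte–fibroblast interface depolarizes
surrounding myocardium far enough to trigger spontaneous activity and
widespread conduction failure rather than delayed-but-complete activation.
Organ-scale fibrosis effects therefore run through the calibrated
eikonal rules, not through monodomain patchy slabs. The atlas geometry is
schematic, foci are placed by region spread rather than clinical
coordinates, and the torso is homogeneous.

# What the synthetic data do and do not show

The generator emulates the statistical structure of the localization
problem — regional conduction heterogeneity, stochastic patchy fibrosis
with staged burden, fibrosis-induced slowing/block/exclusion, calibrated
measurement noise — on simplified geometry. Passing tests therefore
demonstrate that the methods behave as designed under those conditions:
they do not demonstrate clinical localization accuracy on real anatomies,
real fibrosis distributions, or clinically filtered P waves (no QRS
subtraction or baseline-wander correction is modeled). Classification
accuracies obtained on anatomically detailed organ-scale simulations are
likewise not reproducible at desk scale; the test suite checks trends and
closed-form examples instead.
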