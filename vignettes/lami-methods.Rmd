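---
title: "Shape-adaptive excitation power in multiphoton microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-adaptive excitation power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lamikit)
```

# The problem

Two-photon fluorescence scales with the *square* of the excitation power
that reaches the focus. In scattering tissue the ballistic excitation decays
roughly exponentially with in-tissue path length, so laser power must rise
steeply with depth to keep signal constant — but no further than necessary,
because photobleaching and photodamage grow supra-linearly with excitation.
For a flat sample a single exponential-versus-depth profile suffices. For a
curved sample (a lymph node is the motivating case) the required power at a
point depends on the full 3D geometry between the focus and the surface:
marginal rays of the focusing cone travel sub-linearly growing in-tissue
paths, so the required power is *sub-exponential* in depth and its
functional form changes across the sample.

`lamikit` implements a learned solution: identically labeled cells
("standard candles") are imaged once at randomized known powers; each
candle's measured brightness, field position, and a histogram of in-tissue
ray distances to the mapped surface form a feature vector; a small neural
network learns to map features to the modulator voltage that delivers a
target brightness. The package also provides the supporting stack —
a ray-optics reference model, a raster-scan modulation-pattern engine,
three-stage volume registration, candidate segmentation with active
learning, and track motility statistics — and a phantom module that
generates synthetic scattering samples with known ground truth so the whole
pipeline can be validated end to end.

# The phantom forward model

A `lami_sample` is a convex-per-lobe geometry (flat slab, sphere,
ellipsoid, or two-lobe union) with a homogeneous scattering mean free path
`ls` (micrometers). Coordinates are right-handed with z increasing *into*
the tissue. The forward model for a candle of intrinsic brightness `b`
at position `p` imaged with power `P0` is

```
F = gain * b * vignette(x, y) * (P0 * A(p))^2
A(p) = sum_i w_i exp(-d_i / ls)
```

where the sum runs over the rays of the objective's focusing cone
(Gaussian amplitude at the back focal plane, zero phase; weights combine
the Gaussian intensity with the aperture area element) and `d_i` is the
analytic in-tissue path length of ray `i`. Shot noise is Poisson on the
expected brightness. Choices worth stating:

* **One attenuation term.** Excitation scattering and emission-path losses
  are lumped into the single per-ray exponential; the learned model makes
  no distinction between the two losses, so the phantom does not need to
  either.
* **`ls = 100` um** is the package default — a realistic value for a
  highly scattering lymphoid organ; it is shared between the phantom and
  the ray-optics model everywhere.
* **Candle brightness noise**: lognormal with CV 0.15, representing
  cell-to-cell labeling-density variation. Mean is exactly 1.
* **Vignette**: a cos^4-like radial falloff of relative sensitivity across
  each 220-um field, 1 at the center and 0.85 at the corner by default.
  It gives the network a learnable field-position effect.
* **Plumbing constants**: detector gain 1 by default (400 in the phantom
  calibration experiment so typical brightnesses are a few hundred
  photons), candle blob sigma 2 um for rendering.

What the phantom does *not* emulate: wave-optical focusing and
aberrations, heterogeneous scattering, photobleaching kinetics, emission
reabsorption as a separate process, or tissue motion during a single
frame. Tests passing on the phantom therefore demonstrate the
*computational* correctness and the learnability of geometry-conditioned
power control under shot noise and labeling noise — not performance on
real tissue.

# Surface mapping and shape features

`build_surface()` Delaunay-triangulates the XY projection of picked
surface points and interpolates z linearly: a single-valued height map,
undefined outside the convex hull. Points implying vertical overhangs are
outside the model. The interpolant is cached on a regular grid (4 um
default) and queried bilinearly during feature extraction; thin NA seams
that degenerate (co-circular) triangulations can leave inside the hull
are filled from neighboring cells, while the outside-hull region stays
undefined.

`distance_to_surface()` measures the in-tissue distance from a focal
point along a ray by binary search: start at 2000 um, halve until the
bracket is below the tolerance, testing at each step whether the point is
above the interpolated surface *or outside its domain* (undefined counts
as "above", which makes rays exit cleanly at the hull edge). The
tolerance is **1 um**, well below the 4-um plane spacing, giving the
documented 11 halvings.

The descriptor casts 12 rays at a 20-degree inclination to the optical
axis with equally spaced azimuths (ray 0 along +x; the phase is
irrelevant for rotationally symmetric surfaces and tested to be so) and
bins the distances into edges `f(k/12) = (k/12)^1.5 * 350` um. Distances
beyond 350 um are clamped into the last bin rather than dropped, so the
counts always sum to 12 — an invariant the tests rely on. Binning builds
the microscope's rotational symmetry into the representation instead of
asking the network to learn it.

Surface sampling density matters more than it may appear: with 30-um
point spacing on a 510-um sphere the piecewise-linear sagitta error near
the curved rim reaches tens of micrometers, which relabels genuinely
deep candles as "at the surface" and poisons the shallow feature
buckets. The phantom experiments sample at 12 um; hand-picked maps of
real samples should be densified wherever the surface is steep.

# The power predictor

Features (brightness, field x, y, 12 histogram counts) are standardized
element-wise by the training mean and SD. The network is a single
200-unit hidden layer (ReLU) with a scalar output: the EOM voltage. The
loss converts predicted and recorded voltages to *power* through the
sinusoidal calibration before squaring, so training optimizes what
matters physically and is invariant to reparameterizations of the
voltage axis. Training uses Adam, dropout 0.5, batch size 1000, a 10%
validation split, and early stopping.

Two departures from the plainest reading of that recipe, both about
optimization rather than the model:

* The output weights start small with the bias at the mean training
  voltage, so initial predictions sit on the monotonic branch of the
  calibration sinusoid (outside it the loss gradient reverses sign and
  training can stall).
* A fixed patience of 10 at one learning rate stops while the *rare*
  feature regions are still converging: the power-space loss concentrates
  gradient on deep, high-power records, and shallow records (relative
  power near 1) contribute almost nothing even when they are 30% wrong —
  which matters for brightness uniformity since brightness goes as power
  squared. The phantom calibration therefore uses learning rate 3e-3
  with patience 60 and five restore-and-anneal cycles (learning rate / 3
  on each validation plateau), plus a running weight average over the
  final stage that is kept only if it does not hurt validation loss.
  Early stopping on the validation plateau is retained; only the
  schedule is longer.

At inference dropout is off, outputs are deterministic, and voltages are
clipped to the calibration range (networks extrapolate poorly; clipping
is safer than trusting the sinusoid outside its fitted branch). The
brightness element of the query is a z-score of the training brightness
distribution: 0 requests the training-mean brightness, -1 one SD dimmer.
`predict_grid()` evaluates an 8 x 8 pattern per field for the pattern
engine; out-of-hull nodes inherit the nearest featurizable node's value.

The architecture is fixed at one hidden layer; the package does not
implement deeper variants, so the claim that extra layers would not help
is a design premise rather than something re-verified here.

# Ray-optics model, lookup table, and volume accounting

`relative_power()` is the reciprocal of the pupil-averaged attenuation —
the factor by which input power must rise to cancel scattering losses.
For spheres it is parameterized by (vertical depth to the surface,
surface-normal inclination) and tabulated by `precompute_lut()`; bilinear
lookup is exact at nodes, within 2% off-node at the default grid, and
micro-seconds per query.

`imageable_volume()` reproduces the shell accounting of how much of a
510-um-radius sample each strategy can expose correctly: a 25-um shell
times 1/4 for constant illumination; `pi r^2 h` cylinders for
depth-only modulation with validity radius r (h = 140 um for an
exponential profile, 300 um at the laser's depth limit; the cylinder form
is an explicit assumption, since only h and r are specified for these
rows); and the full shell down to 300 um for the learned method. The
learned/constant ratio at the default parameters is ~26.6.

# The phantom calibration experiment

`calibrate_on_phantom()` reproduces the calibration protocol: 10^4
candles in a 510-um sphere, each imaged at the spherical model's power
times a per-Z-stack (per-tile) uniform factor in [0.5, 2], features
against the 12-um sampled surface map, network trained through the
synthetic sin^2 EOM curve (full power 100 relative units at 1.2 V).
`evaluate_on_phantom()` then tests on a *differently shaped* sample — an
ellipsoid with semi-axes 450 x 350 x 300 um, a one-time choice mimicking
a mediastinal versus inguinal node — with unit-brightness candles over
0-300 um depth within the mapped cortical cap (surface-normal angle up
to 60 degrees, emulating surface-guided acquisition of the cortex facing
the objective; beyond that the single-valued height map no longer
describes the near-vertical wall).

Three strategies are compared on achieved-brightness uniformity:

* **learned**: the trained predictor at target z-score 0;
* **spherical physics model**: the precomputed lookup table applied as
  its real counterpart had to be — assuming the sample *is* the
  calibration sphere, tangent at the measured apex. Queried instead with
  the test sample's true per-point depth and angle (and sharing the true
  `ls` and pupil), the spherical model nearly matches the learned one on
  this phantom; the precomputed, shape-unaware form is both what the
  source describes and what produces the observed strategy ordering;
* **constant power** (its CV is independent of the constant chosen).

Typical results at the default seed: median relative power error ~5%
against the forward-model oracle, achieved-brightness CV ~0.15 for the
learned strategy, ~0.7 for the spherical model, ~1.4 for constant power.

# Pattern engine (TR-SLM)

The 8 x 8 pattern is bilinearly interpolated to pixel resolution (exact
for affine patterns), the resonant fast axis follows the inverse-cosine
time-to-position map (dwell time ~ 1/sin(pi x): edges dwell longer), the
slow axis advances linearly, and the commanded voltage is quantized to 12
bits of the 1.2 V full scale and *held* between updates. The default
update interval gives 16 updates per line, chosen so the qualitative
behavior matches the reported hardware: vertical pattern edges stay
sharp, horizontal transitions smear, and smooth gradients — the realistic
case — are reproduced within 1% RMS. Rounding to the nearest DAC code
bounds quantization error at half a step but can exceed a pattern
maximum by that half step; the energy-bound test allows exactly this
granularity.

# Registration and drift

*Stage 1 (within-stack breathing motion).* One XY shift per plane,
found by minimizing the sum of pixel-wise squared differences between
consecutive bilinearly resampled planes, normalized by the stack's total
squared intensity (making the step size brightness-independent), plus
`lambda (||x||^2 + ||y||^2)` with `lambda = 8e-3`. All channels except
the structural (SHG-like) one contribute. Optimization is Adam at
learning rate 1 with exact analytic gradients of the bilinear resampler,
plateau-triggered step annealing, and (by default) initialization from
the integer argmax of pairwise plane cross-correlations so the gradient
refinement starts inside its attraction basin. 5% of pixels at each
border are masked from the loss, since zero-padded resampling invents
content there. Shifts are identifiable only relative to each other; the
quadratic penalty fixes the gauge near zero mean, so accuracy statements
refer to the de-meaned shifts.

Two properties of this objective are worth knowing before trusting it.
First, its data term is bounded (a normalized ratio never far above 1)
while the penalty grows without bound, so the optimum deliberately
*shrinks* large corrections: on a 20-plane stack, roughly a third of any
per-plane displacement beyond ~2 px is retained, and dense
several-pixel jitter on every plane is irrecoverable by construction.
This matches its intended regime — breathing artifacts confined to
single planes at about a pixel of displacement — and the package's
recovery tests operate there. Second, the stiffness of the data term
comes from fine image texture correlated across planes; on synthetic
stacks of isolated sparse blobs the objective is nearly indifferent to
alignment, which is why the test fixtures include an
autofluorescence-like background texture.

*Stage 2 (between time points).* Integer 3D shifts from the argmax of
the FFT cross-correlation (mean-removed), cumulatively summed over the
series. Exact on circular shifts by construction; no subpixel refinement.

*Stage 3 (stitching).* Each stack gets a 3-vector offset (first stack
pinned); the objective is the mean correlation coefficient over the
overlap of every adjacent pair — correlation, not cross-correlation,
because it is invariant to tile-to-tile brightness changes. Stacks
should be time-averaged first (stage 2 having removed relative motion);
an autofluorescence pseudo-channel (minimum over channels) is available
as a fiducial. Optimization is Newton's method with a trust-region
constraint, with finite-difference gradient/Hessian over the small
parameter space. Zero-variance overlaps are skipped with a warning.
Memory stays modest at the test scales used here; very large volumes
should be downsampled before stitching.

*Z drift.* The per-slice maxima of the 3D cross-correlation between
consecutive time points are spline-interpolated over the z lag; the
continuous argmax gives a sub-plane offset, which updates an exponential
moving average (weight 0.5, configurable — the value is not given by the
source) so both the current correction and the predicted next-step drift
are available.

# Candidate identification and active learning

Segmentation is the classical cascade: Gaussian smoothing, local
background subtraction (a wide Gaussian as a rolling-ball-style
estimate; the estimator behind the original commercial tool is not public), global
threshold, 6-connected components, and splitting by seed points — local
maxima at least `seed_size` apart, each claiming its nearest voxels.

Features per candidate, in fixed order: the background-subtracted
channel-mean vector normalized to unit length, its magnitude, a
zero-spectrum flag, pairwise distances between the intensity-weighted
per-channel centers of mass, distances from each to the unweighted
centroid, the upper triangle of the channel correlation matrix, then
per-channel mean/sd/min/max, voxel count and bounding box. The COM and
correlation features target the failure mode where one segmented region
covers two spectrally distinct touching cells.

The normalized-cut subregion extractor builds voxel adjacencies
`w_ij = exp(-d_ij)`. The literal distance formula adds `beta * s_i^T s_j`, which
makes *similar* spectra increase distance — contradicting its stated
purpose — so the default is `beta * (1 - s_i^T s_j)`; the literal form
is preserved behind `literal_formula = TRUE`. Spectral clustering is the
standard symmetric-normalized-affinity eigenvector embedding with
k-means; the returned cluster is the one whose mean unit spectrum best
matches the reference, ties going to the larger side. The partition is
invariant to global intensity rescaling because only unit spectra and
positions enter.

The classifier is an ensemble of small networks (12 hidden units; 3
members during learning, more for final calls) whose sigmoid outputs are
averaged; uncertainty sampling queries the unlabeled example with score
closest to 0.5 (ties to the lowest index). The labeling simulator
replays this against a ground-truth pool starting from one random
positive and one random negative. The default pool is two Gaussian
classes at 0.5% prevalence (20 positives in 4000), separation 3.5 SDs —
rare-positive, mostly separable with some overlap. Performance is
recorded as raw and *balanced* accuracy on the remaining unlabeled pool;
balanced accuracy is the robust choice at 0.5% prevalence, where raw
accuracy saturates at 99.5% for a trivial rejector.

# Motility statistics

The motility coefficient of a track is the slope of the time-averaged
MSD over the first third of lags, divided by 6 (3D), with a log-log
exponent flagging sub/superdiffusion; the estimator is not standardized
in the field, so this definition is stated prominently and used
consistently. Displacement-versus-sqrt(time) curves pool per-track
displacements from the start, fit a locally linear LOWESS (tricubic
weights; bandwidth is manual, default span 0.75), and get 95% bands by
resampling *tracks*, not points, 500 times. Diagnostics report the
origin-constrained slope, the intercept CI, and a curvature statistic
(upper-half slope minus lower-half slope; negative means saturation,
the confined signature). Neighbor density at each time point is the
mean over cells of (other cells within 100 um) / (cells detected at
that time point); averaging the per-cell values, rather than any other
aggregation, is this package's documented choice.

# Numerical choices and test scales

Tolerances: binary search 1 um; LUT grid 8 um x 5 degrees; stage-1
finite-difference epsilon 1e-3 px; stitching epsilon 0.25 voxel, initial
trust radius 2. Degenerate inputs error early with specific messages
(non-positive `ls`, collinear surface points, zero-variance feature
columns by name, all-zero stacks, single-class labels, empty pools).

The shipped tests exercise the full calibration experiment at 10^4
training candles and ~1400 test candles, registration at
64 x 64 x 20 x 6 voxels, active learning on a 4000-candidate pool over
10 seeds, and bootstrap coverage at 120 replicates of 20 tracks — sizes
chosen so the whole suite runs on a laptop-class single core in well
under half an hour while leaving each statistical check adequately
powered.

# Known limitations

Homogeneous scattering only; no wave optics or adaptive optics; surfaces
must be single-valued in z; the two-lobe geometry is the only non-convex
sample and is convex per lobe; the registration stages are rigid
(translations only); the classifier and power network are deliberately
small and are not drop-in models for real data without retraining; and
all empirical performance figures in this vignette are phantom results,
not tissue results.
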