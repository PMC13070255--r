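---
title: "Methods: quantitative image analysis of receptor co-clustering and the efferocytic synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative image analysis of receptor co-clustering and the efferocytic synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efferoquant)
```

efferoquant implements five quantitative analyses used to characterize how
an efferocytic receptor (such as MERTK) organizes with its integrin
co-receptors on the macrophage surface, plus the synthetic-data generators
needed to validate each one against a known ground truth. This vignette is
the package's account of the methods: the models, the tunable parameters
and their defaults, the numerical choices, and the limits of what the
synthetic validation shows.

## Conventions

All coordinates are continuous 2-D positions in nanometres, origin at the
bottom-left, y up. Images are matrices with dimension 1 = x and dimension
2 = y; the centre of pixel (i, j) is at ((i − 0.5)·px, (j − 0.5)·px) for a
pixel size of px nm. Frames are 0-based. Every generator draws from one
locally seeded RNG per call (the global RNG state is saved and restored),
so a fixed seed gives bit-identical output.

## Co-clustering statistics on localization data

`radial_distribution()` computes the cross-species radial distribution
G(r): for annuli around each reference molecule, the density of target
molecules divided by the target's mean density over the ROI. G(r) = 1 for
independent species; enrichment below ~100 nm indicates intermixing within
shared nanoclusters, a secondary bump at 100–300 nm indicates clusters in
contact without intermixing. Because the raw values scale with protein
density, a min–max scaled curve is returned alongside.

*Edge correction* is border exclusion: a reference point contributes to an
annulus only if the annulus fits entirely inside the ROI around it. This
is simple and unbiased; it discards some data near the boundary but is
exactly reproducible by a brute-force oracle, which the test-suite
exploits (the grid-accelerated counting is required to agree with an
all-pairs loop to machine precision). Toroidal wrapping was rejected
because real ROIs are not periodic.

*Default bins*: 10 nm annuli from 0 to 500 nm, matching the 100–300 nm
length scales at which receptor nanodomains live. Configurable.

*Null model*: `randomize_positions()` redraws molecule positions i.i.d.
uniformly over the ROI, mimicking non-interacting proteins;
`mc_envelope()` builds a pointwise 95% envelope from the 2.5th/97.5th
percentiles of G(r) over ≥ 20 (default 100) randomizations of the
reference species. A percentile envelope is used rather than a parametric
interval because it is distribution-free; pointwise envelopes overstate
global significance slightly, which matters for hypothesis tests but not
for the enrichment-versus-random comparisons made here.

*Cluster extraction* (`extract_clusters()`) is OPTICS with generating
distance `max_reach_nm` and `min_points` neighbours (the point itself
included), followed by reachability-threshold extraction at
`max_reach_nm`; clusters smaller than `min_points` become noise. Cluster
boundaries are convex hulls — alpha-shapes were rejected to avoid an
extra shape parameter — and the cluster diameter is the maximum pairwise
member distance (computed exactly on hull vertices).

*Cluster relations* (`classify_cluster_relations()`): a cluster of
species A is **colocalized** with B if at least `intermix_frac` (default
0.5) of its members fall inside some B-cluster hull; otherwise
**contacting** if its hull lies within `contact_dist_nm` (default 20 nm,
about one localization precision) of a B hull; otherwise **neither**.
Colocalized is evaluated first, making the categories mutually exclusive;
the three fractions sum to one. Both thresholds are config-exposed and
echoed into the output because the underlying biology offers no single
canonical value. Supplying an ROI repeats the classification after
randomizing the B positions (and re-extracting B clusters with the same
parameters), giving the chance baseline; on co-clustered synthetic data
the randomized fractions fall well below the observed ones.

A practical note observed on synthetic data: with only ~10 molecules per
cluster, a convex hull covers just over half the true disk, so the
intermixed fraction of a genuinely co-clustered pattern hovers near the
0.5 threshold and clusters spill into the "contacting" class. At ≥ 40–50
localizations per cluster the hull fills the disk and classification is
stable. Sparse clusters are therefore better interrogated with G(r) than
with relation fractions.

## Molecular counting by stepwise photobleaching

A cluster's background-subtracted intensity trace under continuous
maximal excitation is a noisy monotone staircase; each downward unit step
is one fluorophore bleaching. `detect_steps()` fits the staircase by
greedy binary segmentation: change points are inserted where they most
reduce the residual sum of squares, while the reduction exceeds a penalty
of `1.5·σ²·log(n)` (σ estimated robustly from first differences).
Downward transitions smaller than `min_step_size` (default 3σ) and all
upward transitions (blinking, arrivals) are merged away, because the
counting model assumes monotone bleaching.

The penalty constant is deliberately permissive. Over-segmentation is
harmless here: `count_molecules()` snaps the plateau levels onto the
integer ladder `baseline + k·unit` (the unit found by a lattice grid
search over ±22% of the median drop, then refined by a length-weighted
regression over reliable plateaus), and a spurious change point whose two
plateaus land on the same rung simply vanishes. A missed step, by
contrast, is recoverable only when it merges into a double-height drop —
the ladder then counts two — but a missed *first* plateau (the first
fluorophore bleaching in frame 1) loses a molecule irrecoverably, which
is why the penalty errs low.

Counting: if the ladder count does not exceed `direct_count_limit`
(default 28, the reliability bound for direct step counting) the count is
reported directly. Larger clusters are counted by dividing the initial
background-subtracted intensity by a per-fluorophore unit intensity,
obtained as the OLS slope of plateau level versus remaining-fluorophore
count over the final `window_last_k` plateaus. The source protocols
quote this regression window inconsistently (10–15 versus 15–20 events);
the default is 15, configurable over 10–20, and the choice is echoed in
the output metadata. Using ladder-derived remaining counts as the
regressor (rather than plateau rank) keeps the slope unbiased when two
fluorophores bleach in the same frame.

On the reference synthetic conditions — unit 100, Gaussian noise sd 20
(= 0.2 unit), geometric bleach schedule at 0.005 per frame — exact
recovery is ≥ 96% at every true count from 1 to 35, and the regression
extrapolation counts 200-fluorophore clusters within 10%.

## Sensitized-emission FRET

Integrin conformation is read out by FRET between a donor-labelled
integrin headgroup antibody (FITC) and a membrane dye acceptor
(octadecyl-rhodamine B). Three channels are acquired (donor Idd, transfer
Ida, acceptor Iaa); four bleed-through coefficients are measured on
single-label controls after subtracting the per-channel median of an
unstained control: β = Ida/Idd (donor-only), α = Idd/Iaa and γ = Ida/Iaa
(acceptor-only), and δ = Idd/Ida (acceptor-only). Coefficients are
median-of-ratios over above-background pixels, robust to bright debris.

The estimator is the standard corrected sensitized-emission form
consistent with those four definitions:

F_c = Ida − β·(Idd − α·Iaa) − γ·Iaa,  E_A = F_c / Iaa,

clamped to [0, 0.3136], the theoretical maximum of the FITC/ORB pair
(used as a clamp constant, not re-derived). δ is reported but does not
enter the estimator; under the forward model used here its defining ratio
equals α/γ, and it is exposed as an optional second-order diagnostic.
Pixels with Iaa below 3 background sds are undefined rather than divided.
The unclamped map is kept alongside the clamped one, because clamping
censors the noise distribution at E = 0 and would bias ROI averages of
low-FRET regions upward; `roi_fret(..., clamped = FALSE)` averages the
unclamped values.

The synthetic generator (`gen_fret_stack()`) is the exact algebraic
inverse of this estimator — Iaa = Am, Idd = Dm(1−E) + αAm,
Ida = βDm(1−E) + γAm + E·Am, plus backgrounds and Gaussian noise — so the
estimator/forward-model round trip is machine-exact at zero noise by
construction. This validates the bleed-through algebra and the masking
logic; it cannot validate the published coefficient values themselves,
which depend on the actual filter set.

Masking follows the stated protocol: Otsu threshold on Iaa and on Idd,
logical AND, one dilation with a 3×3 (8-connected) element.

Sign convention, asserted in tests: the *bent* (inactive) integrin holds
the FITC headgroup close to the membrane dye and FRETs strongly;
activation extends the integrin and moves the headgroup away, so integrin
activation is a **decrease** in E_A. Display maps invert E_A accordingly.

## Single-particle tracking

Trajectories (produced by an external detection/linking pipeline, or by
the package's generator) are filtered at a mean localization precision of
25 nm and a minimum length of 20 frames. Per track:

- **D** from the OLS slope of the time-averaged MSD over the first 4 lags
  (free intercept absorbing the 4σ² localization-error offset), D =
  slope/4.
- **MSS**: the moments μ_ρ(τ) = ⟨|Δr(τ)|^ρ⟩ for ρ = 1..4, each fitted as
  a power law in τ over lags up to a quarter of the track length; the MSS
  slope is the OLS slope of γ_ρ versus ρ constrained through the origin
  (γ₀ = 0 analytically; an unconstrained fit is available). Short-lag
  emphasis reduces confinement bias on free tracks. No moment
  deconvolution of localization error is attempted.
- **Class**: confined below `low`, free within `[low, high]`, directed
  above `high`; defaults low = 0.30, high = 0.63. The Brownian value is 0.5, but the
  MSS slope of a finite 100-frame track scatters with sd ≈ 0.07, so the
  band is asymmetric around 0.5 and was chosen on the simulator to give
  ≥ 90% per-class accuracy at the study geometry (100-frame tracks,
  D = 0.1 µm²/s, 200 nm corrals, 1 µm/s drift, 20 nm error); at those
  conditions per-class accuracy is ≥ 97%. Both thresholds are
  config-exposed.
- **Confinement diameter** for confined tracks. The chosen
  operationalization — an interpretation, not a transcription of any
  published formula — is the 90th percentile of pairwise distances
  between positions projected on the major axis of the positional
  covariance matrix, divided by the same statistic of a uniformly
  occupied circular corral of unit diameter (0.5888, from numerical
  convolution of the semicircle projection density; re-derived in the
  test-suite). When per-localization precision is available, the
  projected spread is first shrunk by √(1 − σ²/var) to deconvolve
  localization error. On simulated 200 nm corrals the estimate is within
  ~5% (well inside the 15% validation band).

The corral boundary uses specular reflection rather than rejection
sampling; this preserves the step-length distribution but smooths the
shortest-lag MSD slightly near the boundary, a second-order effect at
the geometries above.

## Morphometry

- `feret_diameter()`: maximum caliper distance, exact via convex-hull
  vertex pairs; `expansion_series()` normalizes each time point to the
  first visible synapse. Visibility in the source assay is a focal-plane
  criterion that 2-D outlines cannot recover, so visibility is
  operationalized as outline area above a configurable minimum.
- `pearson_colocalization()`: Pearson correlation over masked pixels.
- `radial_profile()`: annulus means about a centre, pixel-count weighted,
  so total intensity is conserved; annuli are implicitly clipped at image
  bounds.
- `cup_profile()`: channel ÷ membrane (WGA) intensity along the cup axis
  from base to leading edge, min–max scaled to [0, 1]; cups outside the
  50–75% engulfment window are rejected so that profiles are compared at
  matching engulfment stages.
- `uptake_index()`: in beads mode, targets are segmented by connected
  components; a target is bound (non-internalized) when ≥ 50% of its
  footprint carries outside-label signal (surface labelling reaches only
  non-internalized targets), a declared choice since partial engulfment
  scoring has no canonical rule; the index is the mean internalized per
  cell. In apoptotic-cell mode, the outside-label channel is
  Otsu-thresholded, the mask inverted and applied to the dye channel, the
  dye integrated per cell ROI and optionally normalized to a
  control-group mean.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* each analysis
assumes: CSR/co-clustered/contacting two-species point patterns at the
sparse labelling density of ~1 fluorophore per 2.5 µm² (0.4 µm⁻²);
geometric-lifetime bleaching staircases; three-channel FRET stacks that
invert the estimator exactly; Brownian/confined/directed trajectories
with additive Gaussian localization error; and raster uptake scenes with
non-overlapping circular targets. The localization precision of the
SMLM-style patterns defaults to 10 nm — a generator configuration choice,
stated here because the source imaging protocol specifies precision only
for the tracking data (25 nm cutoff), not for the localization
microscopy.

Deliberately not modelled: fluorophore blinking and other photophysics
beyond single-step bleaching; camera noise beyond additive Gaussian plus
offset; 3-D structure; drift; and detection/linking errors in tracking.
Passing tests therefore demonstrate correctness of the estimators under
their stated models, not robustness to every artefact of real
acquisitions — coefficient drift, incomplete background subtraction and
linking errors must still be controlled experimentally.

Validation problem sizes (chosen as the smallest at which the asymptotic
behaviour is visible): 5000 points per species and 100 randomizations for
the CSR envelope calibration; 50 traces per count for counts 1–35 for the
step counter; 200 tracks × 100 frames per motion class for diffusion,
classification and confinement.

## Pipeline driver

`run_stage()` executes any generator or analysis stage from a flat YAML
config (per-stage key schema; unknown keys are errors naming the key, so
a typo cannot silently fall back to a default) and writes results plus a
provenance record — package version, stage, parameters, seed, input
checksums — sufficient to re-run deterministic stages bit-identically.
A thin command-line wrapper over `run_stage()` ships in
`inst/scripts/efferoquant.R`.
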