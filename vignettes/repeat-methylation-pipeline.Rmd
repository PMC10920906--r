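---
title: "Quantifying repeat DNA methylation readouts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat DNA methylation readouts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatmeth)
library(dplyr)
```

`repeatmeth` implements the quantification stack used to relate cell-culture
density and adherens-junction signaling to the DNA methylation state of
centromeric alpha-satellite repeats: per-nucleus quantification of a
fluorescence-complementation methylation reporter, chromatin-mobility
analysis by mean square displacement (MSD), methylation-sensitive
restriction enzyme (MSRE) qPCR, control-gated flow cytometry, and the
per-biological-repeat statistics layer that compares two conditions. Because
such studies rarely deposit primary images or plates, every input the
pipeline consumes can be generated by the package's own simulators, whose
presets encode the relevant published effect directions and magnitudes. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the simulations do and do not establish.

## The synthetic generators

### Nuclei fields

`simulate_nuclei_stack()` renders a two-channel confocal stack
(`r scene_config()$n_slices` z-slices by default, matching a 1.2 um stack at
200 nm step): a DNA-stain channel with disc-shaped nuclei and a signal
channel carrying either diffuse nuclear staining (a 5mC immunostain) or 2-3
bright Gaussian reporter foci per nucleus, the morphology of a
dCas9-anchored methylation reporter targeting the alpha-satellite clusters.
Key parameters (all intensities in arbitrary units, geometry in pixels,
`pixel_size` in um/px, default 0.1):

* `nucleus_radius_range` (14-20 px): uniform radius sampling; a sigmoidal
  edge of width `edge_softness` (1.5 px) replaces a hard rim.
* `spots_per_nucleus_range` (2-3): reporter foci per nucleus, placed within
  0.6 radius of the centre so each spot lies fully inside its nucleus.
* `spot_amplitude` (150), `nuclear_background` (20),
  `extranuclear_background` (2), `noise_sd` (2): the noiseless forward model
  is exactly additive, so the brightest reporter pixel sits at
  amplitude + nuclear background + field background.
* `nucleus_brightness_cv` (0.1): cell-to-cell expression/staining
  variability, applied multiplicatively per nucleus.

Scenes are non-overlapping by construction: placement enforces a
centre-to-centre clearance of both radii plus `4 + 4 * edge_softness`
pixels, the distance at which two sigmoidal edge tails no longer fuse into
one thresholded component. Overcrowded configurations fail with an error
naming the limiting parameter rather than degrading silently.

Condition presets (`scene_preset()`) scale the generative constants:
`dense` (0.6x) and `aza_treated` (0.5x) dim the reporter spots relative to
`sparse`/`none`, and `bobcat_treated` raises the diffuse nuclear 5mC-stain
level 1.5x, the reported magnitude of the global-methylation increase under
TET1/2 inhibition. Ground truth (every nucleus and spot with its position
and amplitude) is returned alongside the pixels so recovery can be scored.

What the disc model deliberately omits: chromatin texture, nucleoli,
clumped or touching nuclei, photobleaching, depth-dependent PSFs. Passing
the recovery tests therefore demonstrates the correctness of the
measurement contracts (masking, background subtraction, area, intensity),
not robustness to crowded or textured real data; touching nuclei are not
split (no watershed) and remain a documented limitation.

### Spot motion and movies

`simulate_trajectories()` draws 2-D Brownian motion with per-axis Gaussian
increments of variance `2 * D * dt` (default `dt` 0.1 s, the 100 ms/frame
acquisition rate used for chromatin imaging), plus independent Gaussian
localization error `localization_sd` per observed coordinate, so the
ensemble expectation is `MSD(tau) = 4 D tau + 4 sigma_loc^2`. The confined
variant reflects each axis at `confinement_radius` around the start point;
its MSD plateaus below `2 * confinement_radius^2 + 4 * sigma_loc^2`. The
motion presets fix `D` at 0.010 um^2/s (sparse) and 0.005 um^2/s (dense):
the published observation is slower spot motion in dense cultures, with no
printed diffusion coefficient, so the 2x ratio is this package's choice of
a clearly resolvable effect at realistic chromatin-locus mobility scales.
`render_movie()` turns trajectories into single-channel TIFF-style movies
for end-to-end tracking tests.

### qPCR plates

`simulate_qpcr_plate()` generates Ct tables with the structure of the MSRE
assay: a control amplicon without AciI sites (the input normalizer) and a
target amplicon whose unmethylated fraction is destroyed by digestion. With
amplification efficiency `E` per cycle, a sample with effective methylated
fraction `f` retains `f` of its amplifiable MSRE template, so

```
Ct_msre = Ct_control - log_E(f) + noise .
```

Both amplicons of a well pair quantify the same DNA input, so the target Ct
is anchored to that sample's realized control Ct; each well adds
independent `N(0, technical_sd)` noise (default 0.2 cycles). `f = 0` leaves
no template and produces the "undetermined" sentinel. The default model is
all-or-nothing protection by a single effective fraction `f` — one
parameter, identifiable from one delta-Ct; a per-site option
(`per_site_k`: amplifiable fraction `p^k` across `k` sites) exists for
sensitivity analyses but is not the default. The expression (RT-qPCR) wells
are analogous, with a reference gene as normalizer and the target offset by
`-log_E(fold)`.

The qPCR presets encode the published effect sizes: 5-aza-dC halves the
methylated fraction (MCF10A preset 0.80 to 0.40; MCF7 preset 0.70 to 0.35 —
both a 50% reduction, the reported magnitude in each line). Dense cultures
carry a lower methylated fraction than sparse ones; only the direction and
significance of that difference is published, so the preset magnitude
(dense = 0.75x sparse) is a free parameter fixed here once at a
conservative, clearly detectable value. Transcript presets double the
alpha-satellite ncRNA level under 5-aza-dC and in dense cultures (again a
direction-only published result).

### Flow cytometry

`simulate_flow_population()` draws 10^4 events per sample (the gated count
used in the reference experiments) from a two-component log-normal model:
a reporter-positive population and a small autofluorescent fraction shared
with the parental control, which contains only the negative component.
`shift_factor` multiplies the positive intensities; the log-normal median
scales by the same factor, which is what the relative-median readout must
recover.

## The quantification stack

### Image quantification

`max_project()` takes per-pixel maxima over consecutive z-slices.
`segment_nuclei()` applies a global Otsu threshold to the projected DNA
channel, labels connected components, removes objects under `min_area`
(default 200 px^2) and drops border-touching nuclei, following the rule
that nuclei in contact with the image border are excluded. A blank field
yields zero nuclei, not an error.

`quantify_spots()` applies a per-nucleus spot threshold, mean + k sd of the
within-nucleus reporter intensities (k = 3 by default). A per-nucleus rule
was chosen over a global one because between-cell expression differences
would otherwise couple a cell's masking to its neighbours. The background
mask is the nucleus minus the spot mask — an exact partition — and the
corrected signal is the per-cell spot mean minus the per-cell background
mean (means are subtracted per cell, not per pixel: the simplest reading of
cell-by-cell background subtraction). This makes the corrected signal
exactly invariant under additive offsets and linear under gain, both pinned
by tests. A nucleus with an empty spot mask keeps its record with a missing
corrected signal so exclusions stay countable.

`mean_nuclear_area()` reproduces the projection - Gaussian smoothing -
threshold - area/number procedure. The smoothing kernel is matched to a
10-pixel artifact diameter by FWHM, `sigma = 10 / 2.355` — an
interpretation, since only the artifact diameter is stated. The stained
area uses a mass-conserving threshold: convolution preserves integrated
intensity, so the masked pixel count is set to the integrated
above-background signal divided by the per-pixel foreground level. A
fixed-height contour was rejected because it shrinks objects whose radius
is comparable to the kernel width (a 10 px disc loses ~20% of its area at
the half-height contour under a 4.25 px sigma kernel, while the
mass-conserving rule stays within a few percent).

### Mobility

`temporal_moving_average()` is a trailing 5-frame boxcar (frame `t` =
mean of `t..t+4`); the paper does not state the alignment, so trailing was
fixed and the time-origin shift of `(window-1)/2` frame intervals is
recorded on the result. `track_spots()` is a greedy nearest-neighbour
frame-to-frame linker: candidate links sorted by displacement, accepted
under `max_displacement`, ties broken deterministically by detection order,
no gap closing (a track terminates the first frame it goes undetected),
tracks shorter than `min_length` discarded. The published analysis used an
external tracker; greedy linking is the simplest contract that reconstructs
well-separated spots, which is what the simulated scenes provide.

`compute_msd()` implements `MSD(tau) = <|r(t) - r(t+tau)|^2>` with the
average over all ordered time pairs within a trajectory (overlapping
windows, maximal pair usage) and, in ensemble mode, pair-count-weighted
pooling across trajectories. Lags with zero pairs are omitted, never
reported as zero. The estimator is pinned exactly against a brute-force
double loop in the tests.

`scaled_mad_filter()` flags values more than three scaled median absolute
deviations from the median; the scale constant is fixed at 1.4826
(consistency with the sd under normality — the source states "scaled"
without a constant). When the MAD is zero, any value off the median is
flagged; this degenerate rule is explicit rather than accidental.

The 1-second mobility readout is ambiguous in its source ("integrating the
MSD over a short lag time of one second"): `mobility_summary()` therefore
reports both `msd_at_1s` (the value at tau = 1 s, the default comparison
readout) and `msd_mean_to_1s` (the mean over 0 < tau <= 1 s). Outlier
removal is applied per condition before aggregation — whether the original
analysis pooled conditions first is not stated, and per-condition filtering
is the choice least able to manufacture a between-condition difference.
`fit_diffusion()` is an ordinary least-squares line through `(tau, MSD)`
with `D = slope / 4`; a negative fitted `D` is returned with a warning
flag, never clamped.

### qPCR quantification

`msre_relative_methylation()` averages technical replicates on the Ct
scale first, then forms `delta_ct = Ct(msre) - Ct(control)` per condition
and biological repeat and reports `relative_methylation = E^-delta_ct`.
Averaging before exponentiation is pinned by a test: the alternative
(averaging linear-scale values) is Jensen-biased and would not be the
quantity a Ct-averaging workflow reports. The assay's own computation is
not printed in the source; `E^-delta_ct` with the undigested control as
input normalizer is the only reading consistent with that amplicon's
stated normalization role. `ddct_expression()` applies the standard
delta-delta-Ct with the reference gene (RPLP0 in the original assay) and a
reference condition, pairing by biological repeat when the repeat exists in
both conditions. Efficiency defaults to 2.0 (perfect doubling) and is
configurable per assay; no standard-curve fitting is included.

`count_enzyme_sites()` counts AciI motifs (`CCGC`); the enzyme is
non-palindromic, so a double-stranded site is `CCGC` on either strand and
the scan covers `CCGC` and `GCGG` with overlaps counted by default.
`validate_amplicon()` enforces the assay design: primers present and
oriented, at least one site in the MSRE target, none in the control, and no
internal XbaI (`TCTAGA`) site, since XbaI pre-fragmentation must not cut
inside either amplicon. The alpha-satellite locus coordinates underlying
the original primer pairs cannot be resolved to a unique retrievable
sequence (no chromosome is named), so site-count claims are exercised on
constructed fixtures only.

### Flow cytometry quantification

`derive_gate()` places the positivity gate at a percentile (default 99.5)
of the parental-control distribution — the control-based gating is stated
in the source, the percentile is not, so it is configurable. Medians are
computed over gated events by default (`gated = FALSE` gives the
all-events option; which was used originally is not stated).

### Statistics layer

`two_condition_normalize()` implements the per-repeat rule: both condition
means are divided by their within-repeat average, so each repeat
contributes a pair with mean exactly 1. Numerically the second value is
computed as `2 - first` so the conservation identity holds to the last
bit, not merely to rounding. `compare_conditions()` then runs a two-tailed
paired or unpaired t test on the normalized per-repeat values (the
unpaired test is the pooled-variance Student form by default, Welch by
flag), reporting raw p-values — no multiple-testing correction, matching
the original reporting — with the conventional star mapping (*p<0.05 to
****p<0.0001). Zero-variance degeneracies are flagged rather than patched.
`one_way_anova()` provides the classical F test for three-group
comparisons. Which readouts received paired versus unpaired tests is taken
as explicit configuration, never inferred.

## Problem sizes and verification scale

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to keep the whole suite in minutes on a single core while
leaving comfortable statistical margins: qPCR recovery uses 3 biological x
3 technical replicates at 0.2-cycle noise (and 200 repeats for bias
checks); diffusion recovery uses 500 trajectories of 100 frames; the
type-I-error check runs 2,000 simulated null experiments; segmentation
targets use 30-50 nuclei per field; flow samples use 10^4 events. At these
sizes the stochastic acceptance readouts have sampling sds of roughly 3
percentage points, within the tolerances they are checked against.

## Known limitations

* Disc-shaped, well-separated nuclei: no watershed splitting, no textured
  chromatin, no 3-D segmentation; results on clumped monolayer images are
  out of the tested envelope.
* The tracker does not close gaps or handle merges/splits; dense spot
  fields with crossing trajectories need a global assignment tracker.
* The digestion model's single effective fraction cannot represent
  site-to-site methylation heterogeneity within the amplicon (use
  `per_site_k` for that question).
* Amplification efficiency is assumed known; no standard curves.
* Flow simulation has one fluorescence channel and no compensation or
  hierarchical gating.
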