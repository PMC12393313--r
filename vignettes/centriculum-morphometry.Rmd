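---
title: "Measuring the centriculum: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the centriculum: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centmorph)
```

## The measurement problem

In early *C. elegans* embryos each centrosome sits inside a dense shell of
ER-derived membrane, the centriculum. In a confocal section through the
centre of the organelle the shell appears as a bright ring; the
pericentriolar material (PCM, marked by SPD-5) appears as a disk nested
inside it, and peri-centrosomal microtubules as a second, tubulin-positive
ring. Whether the shell filters microtubules — letting only thin, radially
oriented polymers through — is a geometric question, and answering it takes
three families of measurements:

1. **Ring morphometry** on fluorescence images: ring diameter, the area of
   the void enclosed by the shell, the area and intensity of the PCM, the
   width of the tubulin ring, and the *gap area* (void minus PCM) that
   quantifies free space between PCM and membrane.
2. **Porosity** of the shell itself, from segmented volume-EM panels: the
   size distribution of through-holes and the fraction of membrane area that
   is open, compared against the smallest hole a 25 nm microtubule can
   physically pass, $\pi \cdot 12.5^2 \approx 490\ \mathrm{nm}^2$.
3. **Microtubule trajectories** at the shell: whether traced microtubules
   stop inside the membrane slab or continue through it, and the angle each
   makes with the radial vector (the local membrane normal).

The original measurements were manual (freehand traces, cursor reads of
profile plots). This package re-states each one as a deterministic algorithm
over explicit inputs — calibrated rasters, polygon ROIs, trace tables — so
that every step can be tested against synthetic scenes with known truth.

## Conventions

Pixels are addressed by 0-based `(x, y)` coordinates; a pixel occupies the
unit square centred on its index, and polygon membership is decided at the
pixel centre, boundary inclusive (so reversing vertex order changes
nothing). Physical calibration is carried explicitly as a pixel size in µm
or nm; a scale bar marked as $n$ pixels spanning length $L$ gives $L/n$ per
pixel (the EM panels use $100/11 \approx 9.09$ nm/px). Channels of one
scene are co-registered by construction and measured in place; there is no
registration step.

## Ring morphometry

**Line scans and diameters.** A scan of given centre, angle, length and
width samples bilinear interpolations of the raster every half pixel along
the line and averages across the width. The scan-line width is exposed as a
parameter (`line_width`, physical units) rather than fixed: the manual
protocol used wide lines (of the order of 1 µm) to average speckle, but
width also mixes curvature into the profile, so narrow defaults are used on
clean synthetic data. Each profile contributes one diameter, the distance
between its highest local maximum left of the profile midpoint and the
highest right of it; the ring diameter is the mean of the two profile
diameters.

Two numerical details matter here. *Plateaus*: a run of equal samples (a
rectangular ring read along a scan) counts as one maximum, reported at the
run sample farthest from the midpoint — a deterministic stand-in for a
manual cursor read, which implies that rectangular-profile rings are read at
their outer edge. *Sub-sample refinement*: half-pixel sampling alternates
between samples that fall on pixel centres and samples interpolated between
them; the two classes are differently smoothed, which can bias the discrete
argmax by up to one sample. Isolated peaks are therefore refined with a
parabola through the peak and its two *same-parity* neighbours (±2 samples),
which restores sub-0.2-pixel accuracy on Gaussian-profile rings (see
`analysis/02_ring_morphometry.R` and the diameter-recovery tests).

**Threshold rules.** All segmentation is intensity thresholding with
region-statistic formulas, kept exactly as practised:

| rule | lower threshold | upper threshold | used for |
|---|---|---|---|
| torus | `(mean + min) / 2` of the traced torus | region max (*Maxthr*) | membrane ring, tubulin ring |
| void trace | `(mean + max) / 2` of the traced void | region max | inner edge of the tubulin ring |
| background sum | `background mean + background max` | image max | PCM ("wand" selection) |

Intervals are closed on both ends, so a perfectly uniform region is fully
selected. The PCM mask is the 8-connected component of above-threshold
pixels containing the seed (by default the brightest pixel — the wand-tool
click); a background brighter than the object raises a threshold-inversion
error rather than returning an empty mask.

**Void area and connectivity.** The void is the connected region of
non-ring pixels containing the declared centre. Background uses
4-connectivity while ring foreground is treated as 8-connected; the
complementary pairing guarantees that a closed diagonal chain of ring pixels
still confines the void. If the centre's region reaches the raster border
the ring is not closed, and the measurement fails loudly (open-ring error)
instead of silently filling. For the microtubule ring, pixels inside a
spindle-exclusion polygon are removed before measurement and the outer edge
is reconstructed across the excluded wedge by the convex closure of the
surviving mask.

**Ring width.** The threshold method converts the outer-edge and void areas
to circle-equivalent radii, $R = \sqrt{A/\pi}$, *even for non-circular
masks* — fidelity to the original estimator, documented as a bias source
rather than replaced by ellipse fitting. The line-scan method normalises
each of the four profile peaks to its own maximum and reads its width at
90% of that maximum by linear interpolation between samples; 90% is the
default because the trough between the two tubulin peaks typically sits near
85% of the peak, so lower fractions would merge the peaks. On ideal
rectangular-profile annuli the two estimators agree to within two pixels; on
Gaussian profiles the 90%-of-max width is systematically narrower than the
full wall width — a property asserted, not corrected.

**Gap area.** `gap = void − PCM area`, computed from areas measured on the
two channels independently. Negative gaps are legitimate (thresholded
signals can overlap) and are flagged rather than clamped.

## Porosity

Holes are 4-connected components of the open phase of a binary panel; the
membrane is 8-connected (the same complementary pairing as above, applied to
the other phase, so diagonal membrane strands never leak two holes into
one). Components touching the panel border are excluded by default — their
true extent is unknown in a cropped panel, making exclusion the conservative
choice — and no minimum-size floor is applied at detection time: single-pixel
holes are kept so that the binned distribution sees the full population
below the passability cutoff, and filtering happens only through
`passable_holes()`. The cutoff itself is $\pi (d/2)^2$ for a microtubule of
diameter $d$ (25 nm by default), with an `as_printed` helper that truncates
to integer nm² for comparison with conventionally quoted values. Bins are
right-closed — (0, 500], (500, 1000], (1000, 2000], …, (9000, 10000],
(10000, ∞) — reading "1001 to 10000 binned at every 1000" as right-closed
intervals; both the count and area percentages must sum to 100 exactly.
Side (cortical/pronuclear) and phase labels are metadata carried to reports,
never used in computation. The en face check accepts a panel only when the
line from the central fiducial to a top/bottom edge fiducial makes an angle
of less than 30° with the central plane.

## Microtubule angles

The curved membrane edge is approximated by straight interior/exterior
boundary lines supplied with the traces; the package never re-estimates
curvature. A trace that crosses the interior edge is *continuing* when it
reaches or crosses the exterior line — an endpoint exactly on the line
(tolerance $10^{-9}$ in coordinate units) counts as continuing, reading
"continued beyond" inclusively; *excluded* when it terminates inside the
slab but is present in the slice sets above or below (supplied as boolean
flags with the trace: the 3-D check is data preparation, not computation
here); and *stopped* otherwise. The angle to the radial vector is
$90° - \theta_t$, with $\theta_t$ the acute angle between trace and tangent;
results are invariant to reversing either direction vector and to global
rotations, and are reported in tables rounded to 0.1°.

## Synthetic scenes and what they do (not) show

The generators emulate the study's input classes with controllable truth:

* `make_ring_image()` — radially symmetric annuli with rectangular or
  Gaussian cross-sections (defaults: peak 100 counts on background 5);
  optional noise applies Poisson shot noise to expected counts and then
  additive Gaussian read noise, in that order, and is **off by default** so
  geometry tests are exact.
* `make_scene()` / `scene_with_gap()` — co-registered membrane/PCM(/tubulin)
  channels around a common centre, the PCM radius solved from the designed
  gap ($r_{pcm} = \sqrt{r_{void}^2 - g/\pi}$), with the ROIs an analyst
  would trace emitted automatically. The default scene (4 µm ring, 0.5 µm
  wall, 0.05 µm/px, 192² px) keeps disk-discretisation error well below the
  5% recovery tolerance.
* `make_panel()` — non-overlapping rasterised discs (or rectangles) with
  areas drawn i.i.d. from a lognormal (default meanlog 6, sdlog 1.1, chosen
  so that the majority of holes fall below the 500 nm² bin, the shape seen
  in measured distributions) on a 2 µm × 2 µm panel at the 100/11 nm/px
  scale-bar calibration. The population is drawn *first*, until its
  rasterised areas hit the target open fraction within 0.5 percentage
  points, then placed largest-first with a one-pixel clearance — placement
  order keeps dense packings feasible without changing which holes exist.
  The truth record lists the exact rasterised area of every hole.
* `make_slab()` — traces crossing a horizontal slab, angles drawn as
  $|N(0, \sigma)|$ truncated at 90° (angle magnitudes only, as reported in
  practice), stopped traces ending uniformly inside the slab. Defaults
  (20 stopped / 20 continuing per slab, spreads 25° vs 8°, 200 nm slab)
  mirror the scale of a traced EM dataset and the qualitative contrast that
  continuing microtubules are the more radial, narrower population.

Passing on these scenes shows that the *estimators* are correct and stable
under discretisation, not that they are robust to everything real data
contains: out-of-focus light, anisotropic PSFs, intensity gradients,
segmentation errors in the EM volumes and curved membrane edges are all
outside the generators' scope. The threshold formulas in particular inherit
the original protocol's sensitivity to the traced region: the package makes
that dependence explicit (ROIs are inputs) rather than removing it.

## Statistical layer

Two-group comparisons follow the protocol's rule — normally distributed
samples get an unpaired t-test, otherwise a two-tailed Mann-Whitney — with
the qualitative "normally distributed" made operational as Shapiro-Wilk at
α = 0.05 on both groups (groups with n < 3, or constant groups, cannot be
screened and fall through to Mann-Whitney). The t-test is the classical
equal-variance Student test, matching the named test of the original
software. Mann-Whitney uses the exact distribution when the combined n is at
most 20 and there are no ties, and the tie-corrected normal approximation
otherwise; two fully tied groups return p = 1 by convention. Multi-group
comparisons run Kruskal-Wallis with Dunn z-tests on the joint ranks
(standard tie correction); the unspecified "correction for multiple
comparisons" defaults to Holm — assumption-light and conservative — and any
`p.adjust` method can be selected. Regression is ordinary least squares with
a two-sided slope test; a constant response returns slope 0 and R² = 0
explicitly, since the textbook R² is undefined there. The significance
criterion is fixed at p < 0.05 throughout, and summaries are reported as
mean ± standard deviation.

## Problem sizes and runtime choices

The test-suite and acceptance scenes are sized for exactness rather than
realism of field of view: 96²–192² px images (0.05–0.1 µm/px), 2 µm²
porosity panels (≈48,000 px, a few hundred to a thousand holes), five-slab
trace sets of 40 traces each, 200 slab replicates for the spread-contrast
rate and 1000 replicates for the type-I error of the auto-dispatched test.
These sizes keep every property identifiable (sub-pixel diameter errors,
exact hole-area round-trips, ±2 pp Monte-Carlo bands) while the whole suite
runs in well under a minute.

## Known limitations

* The circle-equivalence width estimator is biased for non-circular rings by
  construction; it is retained for comparability, with the line-scan method
  as the independent cross-check.
* Plateau peak reads place rectangular-profile ring diameters at the outer
  wall edge (see above); diameters of such rings are conventions, not
  estimates of the peak-to-peak distance.
* `pcm_threshold()` assumes the object out-scales the background after the
  mean + max rule; dim objects over bright backgrounds fail fast with a
  threshold-inversion error.
* Hole areas are pixel counts: sub-pixel hole geometry is not modelled, and
  panels are assumed binary (any grey-level panel is binarised at half its
  value range on load).
* The angle module takes the straight-line tangent approximation as given;
  strongly curved edges at trace scale would need curvature-aware inputs.
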