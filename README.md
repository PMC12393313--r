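# centmorph

Quantitative image analysis of the **centriculum** — the dense, ER-derived
membrane reticulum that envelops the centrosomes of early *C. elegans*
embryos — and of the evidence that it acts as a size/orientation **filter for
microtubules**. The package automates, and makes testable, the bespoke
measurements this question requires: ring morphometry of fluorescence
images, porosity analysis of segmented volume-EM membrane panels, and
stopped-versus-continuing classification of traced microtubules. It is aimed
at cell biologists quantifying annular pericentrosomal signals and at
image-analysis developers who need reference implementations of these
estimators with synthetic ground truth.

## What it computes

**Ring morphometry (fluorescence).** For an annular signal in the central
focal plane:

* *Diameter*: two perpendicular line scans through the ring centre; each
  profile yields the distance between its two intensity peaks, and the ring
  diameter is `(d1 + d2) / 2`.
* *Threshold masks* from region statistics of a rough trace: the torus rule
  sets the lower threshold to `(mean + min) / 2` of the traced ring region,
  the void-trace rule to `(mean + max) / 2`, and the PCM rule to
  `background mean + background max`; the upper threshold is always the
  region maximum (*Maxthr*). Masks are closed on both ends, `[lower, upper]`.
* *Void area*: the connected region of sub-threshold pixels enclosed by the
  thresholded ring (4-connected background inside an 8-connected ring).
* *Tubulin-ring width*, by two independent estimators: circle-equivalent
  radii `R1 = sqrt(A_outer / pi)`, `R2 = sqrt(A_void / pi)`, width
  `R1 − R2`; and the line-scan method — each of the four profile peaks is
  normalised to its own maximum and its width read at 90% of that maximum.
* *Gap area*: `void area − PCM (SPD-5) area`; negative values are flagged as
  overlap.

**Membrane porosity (volume EM).** On binary *en face* panels of segmented
membrane: per-hole areas (4-connected openings; border-touching holes
excluded), open-area fraction, the microtubule-passability cutoff
`pi * (25/2)^2 ≈ 490 nm^2`, binned size distributions (500 nm² bins to
1000 nm², 1000 nm² bins to 10,000 nm², overflow `>10000`), and the
30-degree en face viewing-angle check.

**Microtubule angles.** Traces crossing the reticulum's interior edge are
*continuing* if they reach its exterior edge, *stopped* if they terminate
inside the slab and are absent in adjacent slice sets, *excluded* otherwise;
each trace's angle to the radial vector is `90° − (acute angle to the
tangent line)`.

**Statistics.** Two-group comparisons (Shapiro-Wilk-gated unpaired t /
two-tailed Mann-Whitney), Kruskal-Wallis with Dunn pairwise z-tests and Holm
correction, OLS regression with slope tests, and CSV/plot report assembly.

Every input class has a seed-deterministic synthetic generator with a ground
truth record (`make_ring_image()`, `make_scene()`, `make_panel()`,
`make_slab()`), so the full pipeline is testable without microscope data.

## Worked example

```r
library(centmorph)

# a synthetic three-channel centrosome scene with a designed 2 um^2 gap
sc <- scene_with_gap(2)          # membrane ring: 4 um diameter, 0.5 um wall
m  <- measure_scene(sc)          # uses only the images + auto-traced ROIs
m$diameter
#> <diameter> d1 4.45, d2 4.425, average 4.438 um
m$gap
#> <gap_area> void 9.63 - pcm 7.62 = 2.01

# porosity of a synthetic membrane panel targeting 8% open area
pn <- make_panel(panel_spec(target_open_fraction = 8), seed = 42)
hs <- extract_holes(pn$panel)
hs
#> <hole_set> 462 holes, open fraction 8.05% of 4e+06 nm^2
passable_holes(hs)               # holes >= pi * 12.5^2 = 490.87 nm^2
#> <hole_set> 174 holes, open fraction 6.4% of 4e+06 nm^2
```

The measured diameter (4.44 µm) reads the ring at the *outer* edge of its
rectangular 0.5 µm wall — the peak-position convention for plateau profiles —
while the designed peak-to-peak diameter is 4 µm; Gaussian-profile rings are
recovered to within a fraction of a pixel. The gap statistic (2.01 µm²
against a designed 2 µm²) is the membrane void area minus the thresholded
SPD-5 disk area. In the panel, 288 of 462 holes (62%) lie below the 490 nm²
passability cutoff, yet removing them only reduces the open fraction from
8.05% to 6.4% — small holes dominate the count but not the area.

## Analysis workflow

The `analysis/` scripts run the study end to end on synthetic data and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # scenes, panels, trace tables (+ truth)
Rscript analysis/02_ring_morphometry.R  # diameters, void/PCM/gap cohort
Rscript analysis/03_porosity.R          # hole areas, passability, binned distributions
Rscript analysis/04_mt_angles.R         # stopped/continuing + angle summary
Rscript analysis/05_report.R            # report bundle (CSV tables + plots)
```

Stages 2–4 re-read the files stage 1 wrote (TIFF/PNG/JSON/CSV), never its
in-memory truth records, so the I/O layer is exercised on every run.

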