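#!/usr/bin/env Rscript
# Stage 5: assemble the report bundle from the stage 2-4 tables.
#
# Re-reads the saved CSVs (so the report can be regenerated without rerunning
# the measurements), reruns the group comparisons, and writes tables + plots
# under results/report/.

suppressMessages(library(centmorph))

gaps <- read.csv("results/morphometry_gaps.csv")
panels <- read.csv("results/porosity_panels.csv")
holes <- read.csv("results/porosity_holes.csv")
angles <- read.csv("results/mt_angles.csv")

comparisons <- list(
  open_fraction_by_side = compare_two(
    group_sample("cortical", panels$open_pct[panels$side == "cortical"]),
    group_sample("pronuclear", panels$open_pct[panels$side == "pronuclear"])),
  angle_by_category = compare_two(
    group_sample("stopped", angles$angle_to_radial[angles$category == "stopped"]),
    group_sample("continuing", angles$angle_to_radial[angles$category == "continuing"]))
)

hs <- structure(list(areas = holes$area_nm2,
                     panel_area = sum(holes$area_nm2) / (mean(panels$open_pct) / 100),
                     open_fraction = mean(panels$open_pct),
                     pixel_size = 100 / 11, meta = list()),
                class = "hole_set")

files <- build_report(
  measurements = list(
    gap_cohort = gaps,
    porosity_panels = panels,
    mt_angles = data.frame(group = angles$category,
                           value = angles$angle_to_radial),
    open_fraction = data.frame(group = panels$side, value = panels$open_pct)
  ),
  comparisons = comparisons,
  distributions = list(all_holes = bin_distribution(hs)),
  out_dir = "results/report"
)
cat("Report written:\n")
cat(paste(" ", files, collapse = "\n"), "\n")
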