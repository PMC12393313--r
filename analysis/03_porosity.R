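#!/usr/bin/env Rscript
# Stage 3: porosity of the segmented membrane panels.
#
# Loads the stage-1 panel PNGs, detects holes (4-connected openings,
# border-touching holes excluded), measures per-hole areas and the open-area
# fraction per panel, applies the microtubule-passability cutoff
# (pi * 12.5^2 = 490 nm^2 for a 25 nm microtubule) and builds the binned
# size distributions per side.
#
# Writes results/porosity_panels.csv, results/porosity_holes.csv and one
# binned-distribution CSV per side.

suppressMessages(library(centmorph))

dir.create("results", showWarnings = FALSE)
src <- file.path("results", "synthetic", "panels")
truth <- read.csv(file.path(src, "truth.csv"))

cutoff <- min_passable_area(25)
cat(sprintf("Minimum passable hole area for a 25 nm microtubule: %.2f nm^2 (printed: %d)\n",
            cutoff, min_passable_area(25, as_printed = TRUE)))

panels <- holes_all <- NULL
for (i in seq_len(nrow(truth))) {
  id <- truth$id[i]
  pn <- load_panel(file.path(src, paste0(id, ".png")), truth$pixel_size_nm[i],
                   side = truth$side[i])
  hs <- extract_holes(pn)
  ps <- passable_holes(hs, cutoff)
  panels <- rbind(panels, data.frame(
    id = id, side = truth$side[i], n_holes = length(hs$areas),
    open_pct = hs$open_fraction, true_open_pct = truth$true_open_pct[i],
    passable_n = length(ps$areas), passable_open_pct = ps$open_fraction,
    pct_holes_below_cutoff = 100 * mean(hs$areas < cutoff),
    pct_area_below_cutoff = 100 * sum(hs$areas[hs$areas < cutoff]) / sum(hs$areas)))
  holes_all <- rbind(holes_all, data.frame(id = id, side = truth$side[i],
                                           area_nm2 = hs$areas,
                                           panel_area_nm2 = hs$panel_area))
  cat(sprintf("  %s: %d holes, %.2f%% open (truth %.2f%%); %.0f%% of holes below cutoff\n",
              id, length(hs$areas), hs$open_fraction, truth$true_open_pct[i],
              100 * mean(hs$areas < cutoff)))
}
write.csv(panels, "results/porosity_panels.csv", row.names = FALSE)
write.csv(holes_all, "results/porosity_holes.csv", row.names = FALSE)

for (side in unique(holes_all$side)) {
  sub <- holes_all[holes_all$side == side, ]
  side_area <- sum(tapply(sub$panel_area_nm2, sub$id, `[`, 1))
  hs <- structure(list(areas = sub$area_nm2, panel_area = side_area,
                       open_fraction = 100 * sum(sub$area_nm2) / side_area,
                       pixel_size = truth$pixel_size_nm[1], meta = list()),
                  class = "hole_set")
  bd <- bin_distribution(hs)
  write.csv(as.data.frame(bd), sprintf("results/porosity_binned_%s.csv", side),
            row.names = FALSE)
  cat(sprintf("%s side: %.1f%% of holes in (0, 500] nm^2 (%.1f%% of open area)\n",
              side, bd$counts_percent[1], bd$area_percent[1]))
}

cmp <- compare_two(
  group_sample("cortical", panels$open_pct[panels$side == "cortical"]),
  group_sample("pronuclear", panels$open_pct[panels$side == "pronuclear"]))
cat(sprintf("Cortical vs pronuclear open fraction: %s, p = %.3g\n",
            cmp$test, cmp$p))
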