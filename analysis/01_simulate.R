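#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emits, under results/synthetic/:
#   scenes/   three-channel centrosome scenes (membrane ring + PCM disk) as
#             16-bit TIFFs with shot noise, designed gap areas 0..5 um^2,
#             plus the auto-traced ROIs as JSON and a truth table
#   panels/   segmented-membrane porosity panels (PNG) for the cortical
#             (~8% open) and pronuclear (~20% open) faces, plus truth tables
#   slabs/    microtubule trace tables and slab boundary lines (CSV/JSON)

suppressMessages(library(centmorph))

out <- file.path("results", "synthetic")
for (d in c("scenes", "panels", "slabs"))
  dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)

px_um <- 0.05   # confocal-like sampling, um per pixel
designed_gaps <- c(0, 1, 2, 3.5, 5)

cat("Simulating", length(designed_gaps), "three-channel scenes...\n")
scene_truth <- NULL
for (i in seq_along(designed_gaps)) {
  g <- designed_gaps[i]
  # membrane ring fixed at 4 um diameter, 0.5 um wall; PCM radius solves the
  # designed gap; Poisson shot noise on both channels
  spec <- scene_spec(
    ring_spec(4, "rectangular", 0.5, noise = "poisson"),
    pcm_radius = sqrt((4 / 2 - 0.5 / 2)^2 - g / pi)
  )
  sc <- make_scene(spec, image_size = 192, pixel_size = px_um, seed = 100 + i)
  id <- sprintf("scene_%02d", i)
  save_image(sc$channels$centriculum, file.path(out, "scenes", paste0(id, "_membrane.tif")))
  save_image(sc$channels$pcm, file.path(out, "scenes", paste0(id, "_pcm.tif")))
  write_roi_json(unname(sc$rois), file.path(out, "scenes", paste0(id, "_rois.json")))
  scene_truth <- rbind(scene_truth, data.frame(
    id = id, designed_gap_um2 = g, void_area_um2 = sc$truth$void_area,
    pcm_area_um2 = sc$truth$pcm_area, center_x = sc$truth$center[1],
    center_y = sc$truth$center[2], pixel_size_um = px_um))
}
write.csv(scene_truth, file.path(out, "scenes", "truth.csv"), row.names = FALSE)

cat("Simulating porosity panels (cortical ~8%, pronuclear ~20% open)...\n")
panel_truth <- NULL
for (side in c("cortical", "pronuclear")) {
  target <- if (side == "cortical") 8 else 20
  for (rep in 1:3) {
    pn <- make_panel(panel_spec(target_open_fraction = target),
                     seed = 200 + 10 * (side == "pronuclear") + rep, side = side)
    id <- sprintf("panel_%s_%d", side, rep)
    png::writePNG(1 * pn$panel$mask, file.path(out, "panels", paste0(id, ".png")))
    panel_truth <- rbind(panel_truth, data.frame(
      id = id, side = side, target_open_pct = target,
      true_open_pct = pn$truth$open_fraction, n_holes = length(pn$truth$areas),
      pixel_size_nm = pn$panel$pixel_size))
  }
}
write.csv(panel_truth, file.path(out, "panels", "truth.csv"), row.names = FALSE)

cat("Simulating microtubule slabs...\n")
slab_rows <- NULL
for (rep in 1:5) {
  sl <- make_slab(slab_spec(n_stopped = 20, n_continuing = 20,
                            stopped_angle_sd = 25, continuing_angle_sd = 8),
                  seed = 300 + rep, slab_id = sprintf("slab_%d", rep))
  for (k in seq_along(sl$traces)) {
    tr <- sl$traces[[k]]
    slab_rows <- rbind(slab_rows, data.frame(
      slab_id = tr$slab_id, x1 = tr$start[1], y1 = tr$start[2],
      x2 = tr$end[1], y2 = tr$end[2],
      present_above = tr$present_above, present_below = tr$present_below,
      true_category = sl$truth$category[k], true_angle = sl$truth$angle[k]))
  }
}
write.csv(slab_rows, file.path(out, "slabs", "traces.csv"), row.names = FALSE)
jsonlite::write_json(
  list(interior = list(point = c(0, 0), direction = c(1, 0)),
       exterior = list(point = c(0, 200), direction = c(1, 0))),
  file.path(out, "slabs", "boundaries.json"), auto_unbox = TRUE, digits = NA)

cat("Done. Inputs under", out, "\n")
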