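#' Specification of a synthetic fluorescent ring
#'
#' Describes a radially symmetric annulus as it would appear in a single
#' confocal plane: ring diameter (peak-to-peak), a radial cross-section that
#' is either rectangular (`width_param` = full width) or Gaussian
#' (`width_param` = sd), peak and background intensity in counts, and an
#' optional noise model. Noise follows the standard fluorescence cascade —
#' Poisson shot noise on the expected counts, then additive Gaussian read
#' noise — and is off by default so geometry tests are exact.
#'
#' @param diameter ring diameter in physical units (peak to peak).
#' @param radial_profile `"rectangular"` or `"gaussian"`.
#' @param width_param full width (rectangular) or sd (gaussian), physical units.
#' @param peak_intensity,background counts; `peak_intensity > background >= 0`.
#' @param noise `"none"`, `"poisson"`, `"gaussian"` or `"poisson+gaussian"`.
#' @param read_noise_sd sd of the Gaussian read noise, counts.
#' @return object of class `ring_spec`.
#' @export
ring_spec <- function(diameter, radial_profile = c("gaussian", "rectangular"),
                      width_param, peak_intensity = 100, background = 5,
                      noise = c("none", "poisson", "gaussian", "poisson+gaussian"),
                      read_noise_sd = 2) {
  radial_profile <- match.arg(radial_profile)
  noise <- match.arg(noise)
  cm_assert(diameter > width_param && width_param > 0, "spec",
            "need diameter > width_param > 0")
  cm_assert(peak_intensity > background && background >= 0, "spec",
            "need peak_intensity > background >= 0")
  structure(list(diameter = diameter, radial_profile = radial_profile,
                 width_param = width_param, peak_intensity = peak_intensity,
                 background = background, noise = noise,
                 read_noise_sd = read_noise_sd),
            class = "ring_spec")
}

# Radial distance (physical units) of every pixel centre from `center` (px).
radius_map <- function(image_size, pixel_size, center) {
  nx <- image_size[1]; ny <- image_size[2]
  dx <- (0:(nx - 1)) - center[1]
  dy <- (0:(ny - 1)) - center[2]
  sqrt(outer(dy^2, dx^2, "+")) * pixel_size
}

ring_intensity <- function(r, spec) {
  R <- spec$diameter / 2
  amp <- spec$peak_intensity - spec$background
  if (spec$radial_profile == "rectangular") {
    spec$background + amp * (abs(r - R) <= spec$width_param / 2)
  } else {
    spec$background + amp * exp(-(r - R)^2 / (2 * spec$width_param^2))
  }
}

apply_noise <- function(px, noise, read_noise_sd) {
  if (noise %in% c("poisson", "poisson+gaussian"))
    px <- matrix(stats::rpois(length(px), as.vector(px)), nrow(px), ncol(px))
  if (noise %in% c("gaussian", "poisson+gaussian"))
    px <- pmax(px + matrix(stats::rnorm(length(px), sd = read_noise_sd),
                           nrow(px), ncol(px)), 0)
  px
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Render a synthetic ring image with ground truth
#'
#' @param spec a [ring_spec()].
#' @param image_size pixels, scalar (square) or `c(nx, ny)`.
#' @param pixel_size physical length per pixel.
#' @param unit unit of `pixel_size`.
#' @param seed RNG seed for the noise model (ignored when noise is off);
#'   identical spec + seed gives bit-identical images.
#' @param channel channel label for the image.
#' @return list with `image` (a [calibrated_image()]) and `truth` (centre in
#'   pixel coordinates, diameter, width parameter, inner/outer edge radii for
#'   rectangular profiles).
#' @export
make_ring_image <- function(spec, image_size = 128, pixel_size = 0.05,
                            unit = "um", seed = NULL, channel = "synthetic-ring") {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  cm_assert(spec$width_param >= pixel_size || spec$radial_profile == "gaussian",
            "spec", "ring width must be at least one pixel")
  center <- (image_size - 1) / 2
  extent <- spec$diameter / 2 +
    (if (spec$radial_profile == "rectangular") spec$width_param / 2
     else 3 * spec$width_param)
  cm_assert(extent <= (min(image_size) / 2 - 5) * pixel_size, "geometry",
            "ring does not fit in the image with a 5-pixel margin")
  r <- radius_map(image_size, pixel_size, center)
  px <- ring_intensity(r, spec)
  px <- with_seed_if(seed, apply_noise(px, spec$noise, spec$read_noise_sd))
  truth <- list(center = center, diameter = spec$diameter,
                width_param = spec$width_param,
                radial_profile = spec$radial_profile)
  if (spec$radial_profile == "rectangular") {
    truth$r_inner <- spec$diameter / 2 - spec$width_param / 2
    truth$r_outer <- spec$diameter / 2 + spec$width_param / 2
  }
  list(image = calibrated_image(px, pixel_size, unit, channel), truth = truth)
}

#' Specification of a three-channel centrosome scene
#'
#' A membrane (centriculum) ring, a PCM disk nested inside it, and optionally
#' a tubulin ring, co-registered by construction. The designed gap is the
#' membrane void area minus the PCM disk area.
#'
#' @param centriculum a [ring_spec()] (rectangular profile recommended so the
#'   void radius is exact: `r_void = diameter/2 - width/2`).
#' @param pcm_radius PCM disk radius, physical units.
#' @param pcm_intensity,pcm_background disk and background counts.
#' @param tubulin optional [ring_spec()] for the tubulin channel, or `NULL`.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(centriculum, pcm_radius, pcm_intensity = 100,
                       pcm_background = 5, tubulin = NULL) {
  cm_assert(inherits(centriculum, "ring_spec"), "spec",
            "`centriculum` must be a ring_spec")
  cm_assert(pcm_radius > 0, "spec", "`pcm_radius` must be > 0")
  structure(list(centriculum = centriculum, pcm_radius = pcm_radius,
                 pcm_intensity = pcm_intensity, pcm_background = pcm_background,
                 tubulin = tubulin),
            class = "scene_spec")
}

#' Render a co-registered three-channel scene with ground truth and ROIs
#'
#' Channels are rendered around a common centre. Alongside the images, the
#' ROIs a manual analyst would trace are emitted automatically: a torus pair
#' bracketing the membrane ring, a background box for the PCM threshold, and
#' (when a tubulin ring is present) a torus pair plus a void trace that
#' overlaps the ring's inner rim.
#'
#' @param spec a [scene_spec()].
#' @param image_size pixels, scalar or `c(nx, ny)`.
#' @param pixel_size physical length per pixel.
#' @param unit unit of `pixel_size`.
#' @param seed RNG seed for the noise models.
#' @return list with `channels` (named [calibrated_image()]s:
#'   `centriculum`, `pcm`, optionally `tubulin`), `rois` (named
#'   [polygon_roi()]s) and `truth` (centre, void/pcm areas, designed `gap`,
#'   ring geometry).
#' @export
make_scene <- function(spec, image_size = 128, pixel_size = 0.05, unit = "um",
                       seed = NULL) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  ring <- make_ring_image(spec$centriculum, image_size, pixel_size, unit,
                          seed = if (is.null(seed)) NULL else seed,
                          channel = "membrane")
  center <- ring$truth$center
  r_void <- spec$centriculum$diameter / 2 -
    (if (spec$centriculum$radial_profile == "rectangular")
       spec$centriculum$width_param / 2 else spec$centriculum$width_param)
  cm_assert(spec$pcm_radius <= r_void + spec$centriculum$width_param, "spec",
            "PCM disk extends beyond the membrane ring")
  r <- radius_map(image_size, pixel_size, center)
  pcm_px <- spec$pcm_background +
    (spec$pcm_intensity - spec$pcm_background) * (r <= spec$pcm_radius)
  pcm_px <- with_seed_if(if (is.null(seed)) NULL else seed + 1,
                         apply_noise(pcm_px, spec$centriculum$noise,
                                     spec$centriculum$read_noise_sd))
  channels <- list(
    centriculum = ring$image,
    pcm = calibrated_image(pcm_px, pixel_size, unit, "pcm")
  )
  half_w_px <- (if (spec$centriculum$radial_profile == "rectangular")
    spec$centriculum$width_param / 2 else 2 * spec$centriculum$width_param) / pixel_size
  ring_r_px <- spec$centriculum$diameter / 2 / pixel_size
  rois <- list(
    torus_outer = circle_roi(center, ring_r_px + half_w_px + 3, kind = "torus_outer"),
    torus_inner = circle_roi(center, max(2, ring_r_px - half_w_px - 3),
                             kind = "torus_inner"),
    background = polygon_roi(rbind(c(1, 1), c(9, 1), c(9, 9), c(1, 9)),
                             kind = "background")
  )
  truth <- list(center = center, r_void = r_void,
                void_area = pi * r_void^2,
                pcm_area = pi * spec$pcm_radius^2,
                gap = pi * r_void^2 - pi * spec$pcm_radius^2,
                centriculum = ring$truth)
  if (!is.null(spec$tubulin)) {
    tub <- make_ring_image(spec$tubulin, image_size, pixel_size, unit,
                           seed = if (is.null(seed)) NULL else seed + 2,
                           channel = "tubulin")
    channels$tubulin <- tub$image
    tub_r_px <- spec$tubulin$diameter / 2 / pixel_size
    tub_half_w_px <- (if (spec$tubulin$radial_profile == "rectangular")
      spec$tubulin$width_param / 2 else 2 * spec$tubulin$width_param) / pixel_size
    rois$tubulin_outer <- circle_roi(center, tub_r_px + tub_half_w_px + 3,
                                     kind = "torus_outer")
    rois$tubulin_inner <- circle_roi(center, max(2, tub_r_px - tub_half_w_px - 3),
                                     kind = "torus_inner")
    # void trace reaching half-way into the ring so its rim survives the
    # (mean+max)/2 threshold on all sides
    rois$tubulin_void <- circle_roi(center, tub_r_px - tub_half_w_px / 2,
                                    kind = "freehand")
    truth$tubulin <- tub$truth
  }
  list(channels = channels, rois = rois, truth = truth)
}

#' Scene with a prescribed gap area
#'
#' Convenience wrapper: fixes the membrane ring (rectangular cross-section)
#' and solves for the PCM radius that realises a designed gap area,
#' `r_pcm = sqrt(r_void^2 - gap/pi)`.
#'
#' @param gap designed gap area (physical units^2); must not exceed the void
#'   area. `gap = 0` gives a PCM disk exactly filling the void.
#' @param diameter,width membrane ring geometry (rectangular profile).
#' @param image_size,pixel_size,unit,seed as in [make_scene()].
#' @return as [make_scene()].
#' @export
scene_with_gap <- function(gap, diameter = 4, width = 0.5, image_size = 192,
                           pixel_size = 0.05, unit = "um", seed = NULL) {
  r_void <- diameter / 2 - width / 2
  cm_assert(gap <= pi * r_void^2 - pi * (2 * pixel_size)^2, "spec",
            "designed gap leaves no room for a PCM disk")
  r_pcm <- sqrt(r_void^2 - gap / pi)
  spec <- scene_spec(
    ring_spec(diameter, "rectangular", width),
    pcm_radius = r_pcm
  )
  make_scene(spec, image_size, pixel_size, unit, seed)
}

#' Specification of a synthetic porosity panel
#'
#' @param panel_size nm, scalar (square) or `c(width, height)`.
#' @param hole_areas either `list(type = "lognormal", meanlog, sdlog)` —
#'   defaults emulate a hole population whose majority lies below 500 nm^2 —
#'   or `list(type = "fixed", areas = c(...))` of target areas in nm^2.
#' @param target_open_fraction percent of panel area open, in (0, 60\];
#'   ignored for fixed lists (every listed hole is placed).
#' @param shape `"disc"` or `"rectangle"` (rectangles give exact pixel areas
#'   when the target area is a multiple of the pixel area).
#' @param pixel_size nm per pixel; default 100/11, the scale-bar calibration
#'   of 11 pixels per 100 nm.
#' @param max_attempts rejection-sampling bound per hole placement.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(panel_size = 2000,
                       hole_areas = list(type = "lognormal", meanlog = 6, sdlog = 1.1),
                       target_open_fraction = 8,
                       shape = c("disc", "rectangle"),
                       pixel_size = 100 / 11,
                       max_attempts = 1e4) {
  shape <- match.arg(shape)
  if (length(panel_size) == 1) panel_size <- c(panel_size, panel_size)
  cm_assert(hole_areas$type %in% c("lognormal", "fixed"), "spec",
            "hole_areas$type must be 'lognormal' or 'fixed'")
  cm_assert(target_open_fraction > 0 && target_open_fraction <= 60, "spec",
            "target_open_fraction must be in (0, 60]")
  structure(list(panel_size = panel_size, hole_areas = hole_areas,
                 target_open_fraction = target_open_fraction, shape = shape,
                 pixel_size = pixel_size, max_attempts = max_attempts),
            class = "panel_spec")
}

# Pixel offsets (dx, dy) of a hole footprint with ~`area_px` pixels.
hole_footprint <- function(area_px, shape) {
  if (shape == "disc") {
    r <- sqrt(area_px / pi)
    k <- ceiling(r)
    g <- expand.grid(dx = -k:k, dy = -k:k)
    g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  } else {
    w <- max(1, round(sqrt(area_px)))
    h <- max(1, round(area_px / w))
    expand.grid(dx = 0:(w - 1), dy = 0:(h - 1))
  }
}

#' Generate a porosity panel with known per-hole truth
#'
#' Holes are rasterised discs (or rectangles) with areas drawn from the
#' specified distribution, placed uniformly at random, rejected if they
#' overlap or come within one pixel of an existing hole or the panel border
#' (so every hole is a distinct interior 4-connected component), until the
#' open fraction is within 0.5 percentage points of the target. The truth
#' record lists the exact rasterised area of every hole.
#'
#' @param spec a [panel_spec()].
#' @param seed RNG seed; identical spec + seed gives identical panels.
#' @param side,phase metadata labels for the panel.
#' @return list with `panel` (a [membrane_panel()]) and `truth` (a
#'   `hole_set` of exact areas plus per-hole placement data in
#'   `truth$meta$holes`).
#' @export
make_panel <- function(spec, seed = NULL, side = "cortical",
                       phase = "prometaphase") {
  with_seed_if(seed, {
    ps <- spec$pixel_size
    nx <- round(spec$panel_size[1] / ps); ny <- round(spec$panel_size[2] / ps)
    mask <- matrix(TRUE, ny, nx)         # membrane everywhere
    blocked <- matrix(FALSE, ny, nx)     # holes dilated by 1 px
    panel_area <- nx * ny * ps^2
    target <- spec$target_open_fraction
    fixed <- spec$hole_areas$type == "fixed"
    # The hole population is fixed before any placement: areas are drawn
    # sequentially (so the realised population is an i.i.d. sample from the
    # specified distribution) until their rasterised pixel counts reach the
    # target open fraction; a draw that would overshoot the +0.5 pp band is
    # redrawn. Placement then proceeds largest-first — large holes go into
    # the still-empty panel, which keeps dense packings feasible without
    # affecting which holes exist.
    if (fixed) {
      queue <- spec$hole_areas$areas
    } else {
      target_px <- target / 100 * nx * ny
      band_px <- 0.5 / 100 * nx * ny
      queue <- numeric(0)
      sum_px <- 0
      redraws <- 0
      while (sum_px < target_px) {
        a <- stats::rlnorm(1, spec$hole_areas$meanlog, spec$hole_areas$sdlog)
        a_px <- nrow(hole_footprint(a / ps^2, spec$shape))
        if (sum_px + a_px > target_px + band_px) {
          redraws <- redraws + 1
          cm_assert(redraws <= spec$max_attempts, "packing",
                    "cannot hit the target open fraction with this area distribution")
          next
        }
        queue <- c(queue, a)
        sum_px <- sum_px + a_px
      }
      queue <- sort(queue, decreasing = TRUE)
    }
    open_px <- 0
    holes <- list()
    i_hole <- 0
    while (i_hole < length(queue)) {
      area_nm2 <- queue[i_hole + 1]
      fp <- hole_footprint(area_nm2 / ps^2, spec$shape)
      placed <- FALSE
      attempts <- 0
      while (!placed) {
        attempts <- attempts + 1
        if (attempts > spec$max_attempts)
          cm_stop("packing", sprintf(
            "packing infeasible after %d attempts (achieved %.2f%% open)",
            attempts - 1, 100 * open_px * ps^2 / panel_area),
            data = list(achieved = 100 * open_px * ps^2 / panel_area))
        # keep >= 2 px clear of the border so holes are interior after dilation
        lo_x <- 2 - min(fp$dx); hi_x <- nx - 3 - max(fp$dx)
        lo_y <- 2 - min(fp$dy); hi_y <- ny - 3 - max(fp$dy)
        cm_assert(hi_x >= lo_x && hi_y >= lo_y, "packing",
                  "a sampled hole is larger than the panel interior")
        cx <- lo_x + sample.int(hi_x - lo_x + 1L, 1L) - 1L
        cy <- lo_y + sample.int(hi_y - lo_y + 1L, 1L) - 1L
        rows <- cy + fp$dy + 1L; cols <- cx + fp$dx + 1L
        if (any(blocked[cbind(rows, cols)])) next
        mask[cbind(rows, cols)] <- FALSE
        for (ddx in -1:1) for (ddy in -1:1)
          blocked[cbind(pmin(pmax(rows + ddy, 1), ny),
                        pmin(pmax(cols + ddx, 1), nx))] <- TRUE
        open_px <- open_px + nrow(fp)
        holes[[length(holes) + 1]] <- data.frame(
          cx = cx, cy = cy, area_px = nrow(fp), area_nm2 = nrow(fp) * ps^2)
        placed <- TRUE
      }
      i_hole <- i_hole + 1
    }
    cm_assert(length(holes) > 0, "packing", "no holes were placed")
    hole_df <- do.call(rbind, holes)
    panel <- membrane_panel(mask, ps, side, phase)
    truth <- new_hole_set(hole_df$area_nm2, panel_area, ps,
                          meta = list(holes = hole_df, side = side, phase = phase))
    list(panel = panel, truth = truth)
  })
}

#' Specification of a synthetic microtubule slab
#'
#' @param n_stopped,n_continuing trace counts per category.
#' @param stopped_angle_sd,continuing_angle_sd degrees; angles to the radial
#'   vector are drawn as `|Normal(0, sd)|`, resampled above 90.
#' @param slab_width nm between the interior and exterior edges.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(n_stopped = 20, n_continuing = 20,
                      stopped_angle_sd = 25, continuing_angle_sd = 8,
                      slab_width = 200) {
  cm_assert(n_stopped >= 0 && n_continuing >= 0, "spec", "counts must be >= 0")
  cm_assert(stopped_angle_sd > 0 && continuing_angle_sd > 0, "spec",
            "angle sds must be > 0")
  structure(list(n_stopped = n_stopped, n_continuing = n_continuing,
                 stopped_angle_sd = stopped_angle_sd,
                 continuing_angle_sd = continuing_angle_sd,
                 slab_width = slab_width),
            class = "slab_spec")
}

rhalfnorm_trunc <- function(n, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(stats::rnorm(n, sd = sd))
    out <- c(out, x[x < 90])
  }
  out[seq_len(n)]
}

#' Generate a microtubule slab with known categories and angles
#'
#' The interior edge runs along y = 0 and the exterior along
#' y = `slab_width` (nm), so the tangent is the x-axis and the radial vector
#' the y-axis. Every trace starts below the interior edge and crosses it;
#' stopped traces end uniformly within the slab, continuing traces cross the
#' exterior edge. The ground-truth angle of each trace to the radial vector
#' is stored exactly.
#'
#' @param spec a [slab_spec()].
#' @param seed RNG seed.
#' @param slab_id identifier attached to the traces.
#' @return list with `traces` (list of [mt_trace()]), `interior`/`exterior`
#'   ([boundary_line()]s) and `truth` (data frame of category and angle).
#' @export
make_slab <- function(spec, seed = NULL, slab_id = "slab1") {
  with_seed_if(seed, {
    w <- spec$slab_width
    n <- spec$n_stopped + spec$n_continuing
    category <- rep(c("stopped", "continuing"),
                    c(spec$n_stopped, spec$n_continuing))
    angle <- c(rhalfnorm_trunc(spec$n_stopped, spec$stopped_angle_sd),
               rhalfnorm_trunc(spec$n_continuing, spec$continuing_angle_sd))
    lateral <- sample(c(-1, 1), n, replace = TRUE)
    x0 <- stats::runif(n, 0, 5 * w)
    y0 <- -stats::runif(n, 0.05 * w, 0.5 * w)
    th <- angle * pi / 180
    dirx <- lateral * sin(th); diry <- cos(th)
    y_end <- ifelse(category == "stopped",
                    stats::runif(n, 0.05, 0.95) * w,
                    w + stats::runif(n, 0.05 * w, 0.5 * w))
    t_len <- (y_end - y0) / diry
    traces <- lapply(seq_len(n), function(i) mt_trace(
      start = c(x0[i], y0[i]),
      end = c(x0[i] + t_len[i] * dirx[i], y_end[i]),
      slab_id = slab_id
    ))
    list(
      traces = traces,
      interior = boundary_line(c(0, 0), c(1, 0), "interior_edge"),
      exterior = boundary_line(c(0, w), c(1, 0), "exterior_edge"),
      truth = data.frame(category = category, angle = angle)
    )
  })
}
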