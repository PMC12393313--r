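#' Intensity profile along a scan line
#'
#' Emulates drawing a wide line across the central focal plane of an annular
#' structure and reading its intensity profile: samples are taken every half
#' pixel along the line, and each sample is the mean of bilinearly
#' interpolated intensities across `line_width` perpendicular to the scan
#' direction.
#'
#' @param image a [calibrated_image()].
#' @param center `c(x, y)` scan-line midpoint, 0-based pixel coordinates.
#' @param angle scan direction in degrees (0 = +x, counter-clockwise).
#' @param length scan length in physical units.
#' @param line_width averaging width in physical units; widths at or below
#'   one sample spacing collapse to a single-line scan.
#' @return object of class `intensity_profile` with `positions` (physical
#'   distance from the scan start, uniformly spaced), `values` and
#'   `line_width`.
#' @export
line_scan <- function(image, center, angle, length, line_width = image$pixel_size) {
  ps <- image$pixel_size
  cm_assert(length > 0 && line_width >= 0, "geometry",
            "`length` and `line_width` must be positive")
  spacing <- 0.5 * ps
  t_phys <- seq(-length / 2, length / 2, by = spacing)
  cm_assert(length(t_phys) >= 16, "geometry",
            "scan too short: a profile needs at least 16 samples")
  th <- angle * pi / 180
  d <- c(cos(th), -sin(th))       # image y grows downward; keep angles CCW
  perp <- c(-d[2], d[1])
  n_off <- max(1L, round(line_width / spacing) + 1L)
  offs <- if (n_off == 1L) 0 else seq(-line_width / 2, line_width / 2,
                                      length.out = n_off)
  tx <- center[1] + outer(t_phys, offs * perp[1] / ps, function(t, o) t * d[1] / ps + o)
  ty <- center[2] + outer(t_phys, offs * perp[2] / ps, function(t, o) t * d[2] / ps + o)
  ny <- nrow(image$pixels); nx <- ncol(image$pixels)
  cm_assert(all(tx >= 0 & tx <= nx - 1 & ty >= 0 & ty <= ny - 1), "geometry",
            "scan line (or its width) extends outside the raster")
  vals <- matrix(bilinear(image$pixels, as.vector(tx), as.vector(ty)),
                 nrow = length(t_phys))
  structure(
    list(positions = t_phys + length / 2, values = rowMeans(vals),
         line_width = line_width, spacing = spacing, unit = image$unit),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples over %.4g %s (width %.4g)\n",
              length(x$positions), diff(range(x$positions)), x$unit, x$line_width))
  invisible(x)
}

# Local maxima with plateau handling: a run of equal values is a peak when
# both flanking runs are strictly lower; runs touching the profile ends are
# not peaks. Within a plateau the reported sample is the one farthest from
# the profile midpoint (deterministic stand-in for a manual cursor read).
profile_peaks <- function(profile) {
  v <- profile$values
  r <- rle(v)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- mean(range(profile$positions))
  out <- list()
  for (i in seq_len(k)) {
    if (i == 1 || i == k) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]) {
      run_idx <- starts[i]:ends[i]
      dist_mid <- abs(profile$positions[run_idx] - mid)
      idx <- run_idx[which.max(dist_mid)]
      out[[length(out) + 1]] <- c(idx = idx, pos = profile$positions[idx],
                                  value = v[idx])
    }
  }
  if (length(out) == 0)
    return(data.frame(idx = integer(), pos = numeric(), value = numeric()))
  as.data.frame(do.call(rbind, out))
}

# Highest local maximum on each side of the profile midpoint; ties broken
# toward the sample farthest from the midpoint. Errors (with the profile as
# diagnostic payload) when a side has no peak.
side_peaks <- function(profile) {
  pk <- profile_peaks(profile)
  mid <- mean(range(profile$positions))
  pick <- function(side) {
    p <- if (side == "left") pk[pk$pos < mid, , drop = FALSE]
         else pk[pk$pos > mid, , drop = FALSE]
    cm_assert(nrow(p) >= 1, "peak_detection",
              sprintf("no local maximum %s of the profile midpoint", side),
              data = list(profile = profile))
    p <- p[p$value == max(p$value), , drop = FALSE]
    p[which.max(abs(p$pos - mid)), ]
  }
  rbind(pick("left"), pick("right"))
}

#' Diameter from two perpendicular intensity profiles
#'
#' Each profile contributes one diameter: the distance between the highest
#' local maximum left of its midpoint and the highest right of it. The
#' average of the two, `(d1 + d2) / 2`, is the reported ring diameter. With
#' `refine = TRUE` (default) each isolated peak position is refined below the
#' sample spacing by fitting a parabola through the peak sample and its two
#' neighbours — the standard sub-sample localisation for sampled profiles;
#' plateau peaks (equal-valued neighbours) are left at the tie-broken sample.
#'
#' @param p1,p2 [line_scan()] profiles taken across the ring centre at
#'   perpendicular angles.
#' @param refine parabolic sub-sample refinement of peak positions.
#' @return object of class `diameter_measurement` with `d1`, `d2`, `average`.
#' @export
diameter_from_profiles <- function(p1, p2, refine = TRUE) {
  # Parabola through samples i-2, i, i+2: with half-pixel sampling these share
  # one interpolation class (on-pixel vs between-pixel), so the fit is not
  # biased by the alternating bilinear filter.
  refine_pos <- function(p, i) {
    v <- p$values
    if (i <= 2 || i >= length(v) - 1) return(p$positions[i])
    vl <- v[i - 2]; vc <- v[i]; vr <- v[i + 2]
    den <- vl - 2 * vc + vr
    if (den >= 0 || vl == vc || vr == vc) return(p$positions[i])  # plateau/flat
    off <- 0.5 * (vl - vr) / den
    p$positions[i] + max(-1, min(1, off)) * 2 * p$spacing
  }
  d_of <- function(p) {
    pk <- side_peaks(p)
    if (refine) refine_pos(p, pk$idx[2]) - refine_pos(p, pk$idx[1])
    else pk$pos[2] - pk$pos[1]
  }
  d1 <- d_of(p1); d2 <- d_of(p2)
  cm_log("diameter_from_profiles", d1 = d1, d2 = d2)
  structure(list(d1 = d1, d2 = d2, average = (d1 + d2) / 2, unit = p1$unit),
            class = "diameter_measurement")
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("<diameter> d1 %.4g, d2 %.4g, average %.4g %s\n",
              x$d1, x$d2, x$average, x$unit))
  invisible(x)
}

#' Circle-equivalent ring width from outer and void areas
#'
#' Both areas are converted to circle-equivalent radii, `R = sqrt(A / pi)`,
#' exactly as for a perfect circle even when the mask is not circular (a
#' documented bias of this estimator): `R1` from the area enclosed by the
#' ring's outer edge, `R2` from the inner void area. The width is `R1 - R2`.
#'
#' @param outer_area area enclosed by the outer edge (physical units^2).
#' @param void_area inner void area, same units; must not exceed `outer_area`.
#' @return object of class `ring_width` with `R1`, `R2`, `width_threshold`.
#' @export
ring_width_threshold <- function(outer_area, void_area) {
  cm_assert(outer_area >= 0 && void_area >= 0, "argument",
            "areas must be non-negative")
  cm_assert(outer_area >= void_area, "argument_order",
            "`outer_area` must be >= `void_area` (arguments swapped?)")
  R1 <- sqrt(outer_area / pi); R2 <- sqrt(void_area / pi)
  structure(list(R1 = R1, R2 = R2, width_threshold = R1 - R2),
            class = "ring_width")
}

# One peak's width at `frac` of its own maximum: linear interpolation of the
# two crossing coordinates around the peak sample.
peak_width_at_frac <- function(profile, peak_idx, frac) {
  v <- profile$values; x <- profile$positions
  level <- frac * v[peak_idx]
  cross_left <- function() {
    for (j in seq(peak_idx - 1, 1)) {
      if (v[j] < level)
        return(x[j] + (level - v[j]) / (v[j + 1] - v[j]) * (x[j + 1] - x[j]))
    }
    cm_stop("truncated_peak",
            sprintf("the %.0f%%-of-max level is never crossed left of the peak",
                    100 * frac), data = list(profile = profile))
  }
  cross_right <- function() {
    for (j in seq(peak_idx + 1, length(v))) {
      if (v[j] < level)
        return(x[j] - (v[j] - level) / (v[j] - v[j - 1]) * (x[j] - x[j - 1]))
    }
    cm_stop("truncated_peak",
            sprintf("the %.0f%%-of-max level is never crossed right of the peak",
                    100 * frac), data = list(profile = profile))
  }
  cm_assert(peak_idx > 1 && peak_idx < length(v), "truncated_peak",
            "peak lies on the profile boundary")
  cross_right() - cross_left()
}

#' Ring width from 90%-of-max peak widths on two line scans
#'
#' Each perpendicular profile crosses the ring twice, giving four peaks in
#' total. Every peak is normalised to its own maximum (100%), the two
#' x-coordinates where it crosses 90% of that maximum are found by linear
#' interpolation between samples, and their distance is that peak's width.
#' The ring width is the mean of the four peak widths.
#'
#' @param p1,p2 perpendicular [line_scan()] profiles across the ring centre.
#' @param frac fraction of each peak's maximum at which widths are read
#'   (default 0.9; the minimum between ring peaks must stay below this level).
#' @return object of class `ring_width` with `peak_widths` (length 4) and
#'   `width_linescan` (their mean).
#' @export
ring_width_linescan <- function(p1, p2, frac = 0.9) {
  widths <- unlist(lapply(list(p1, p2), function(p) {
    pk <- side_peaks(p)
    vapply(pk$idx, function(i) peak_width_at_frac(p, i, frac), numeric(1))
  }))
  structure(list(peak_widths = widths, width_linescan = mean(widths),
                 frac = frac, unit = p1$unit),
            class = "ring_width")
}

#' @export
print.ring_width <- function(x, ...) {
  cat("<ring_width>")
  if (!is.null(x$width_threshold))
    cat(sprintf(" threshold method: R1 %.4g, R2 %.4g, width %.4g;",
                x$R1, x$R2, x$width_threshold))
  if (!is.null(x$width_linescan))
    cat(sprintf(" line-scan method: width %.4g (peaks %s)",
                x$width_linescan, paste(signif(x$peak_widths, 4), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Gap area between the membrane void and the PCM
#'
#' The gap statistic is the centriculum void area minus the area occupied by
#' the PCM (SPD-5 signal). Negative values are permitted — they arise when
#' the thresholded PCM signal overlaps the membrane signal — and are flagged.
#'
#' @param void_area centriculum void area (physical units^2).
#' @param pcm_area PCM area, same units.
#' @return object of class `gap_area` with `void_area`, `pcm_area`,
#'   `gap = void_area - pcm_area` and logical `overlap` (`gap < 0`).
#' @export
gap_area <- function(void_area, pcm_area) {
  cm_assert(void_area >= 0 && pcm_area >= 0, "argument",
            "areas must be non-negative")
  g <- void_area - pcm_area
  structure(list(void_area = void_area, pcm_area = pcm_area, gap = g,
                 overlap = g < 0),
            class = "gap_area")
}

#' @export
print.gap_area <- function(x, ...) {
  cat(sprintf("<gap_area> void %.4g - pcm %.4g = %.4g%s\n",
              x$void_area, x$pcm_area, x$gap,
              if (x$overlap) " (overlap)" else ""))
  invisible(x)
}
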