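#' Boundary line of the reticulum slab
#'
#' The curved membrane edge is approximated, at trace scale, by a straight
#' line given as a point and a direction. The interior-edge line doubles as
#' the local tangent when computing angles to the radial vector.
#'
#' @param point `c(x, y)` on the line.
#' @param direction `c(dx, dy)` along the line (normalised internally).
#' @param role `"interior_edge"` or `"exterior_edge"`.
#' @return object of class `boundary_line`.
#' @export
boundary_line <- function(point, direction, role = c("interior_edge", "exterior_edge")) {
  role <- match.arg(role)
  nrm <- sqrt(sum(direction^2))
  cm_assert(is.finite(nrm) && nrm > 0, "geometry",
            "line direction must be non-zero")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm, role = role),
            class = "boundary_line")
}

#' Microtubule trace
#'
#' A straight-line trace of a microtubule crossing the reticulum's interior
#' edge. `present_above` / `present_below` record whether the same
#' microtubule is visible in the slice sets above or below the analysed slab
#' — a data-preparation fact supplied with the trace, used to exclude
#' apparent terminations that merely leave the imaging plane.
#'
#' @param start,end `c(x, y)` endpoints; must differ.
#' @param slab_id identifier of the slab the trace belongs to.
#' @param present_above,present_below logicals, see above.
#' @return object of class `mt_trace`.
#' @export
mt_trace <- function(start, end, slab_id = "", present_above = FALSE,
                     present_below = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  cm_assert(all(is.finite(c(start, end))), "geometry",
            "trace endpoints must be finite")
  cm_assert(!all(start == end), "geometry", "trace endpoints coincide")
  structure(list(start = start, end = end, slab_id = as.character(slab_id),
                 present_above = isTRUE(present_above),
                 present_below = isTRUE(present_below)),
            class = "mt_trace")
}

# Signed perpendicular offset of point p from a boundary line.
line_side <- function(line, p) {
  d <- line$direction
  d[1] * (p[2] - line$point[2]) - d[2] * (p[1] - line$point[1])
}

#' Classify a trace as stopped, continuing or excluded
#'
#' A trace that crosses the interior edge is *continuing* when it reaches or
#' crosses the exterior edge on the far side (an endpoint exactly on the
#' exterior line, within `tol`, counts as continuing — "continued beyond"
#' read inclusively); *excluded* when it terminates inside the slab but is
#' present in an adjacent slice set (it continues in another plane);
#' *stopped* when it terminates strictly between the lines and is absent
#' above and below. Traces that never cross the interior edge are
#' ineligible.
#'
#' @param trace an [mt_trace()].
#' @param interior,exterior [boundary_line()]s of one slab.
#' @param tol tolerance for on-line endpoint tests, in coordinate units.
#' @return `"stopped"`, `"continuing"` or `"excluded"`.
#' @export
classify_trace <- function(trace, interior, exterior, tol = 1e-9) {
  s_int <- c(line_side(interior, trace$start), line_side(interior, trace$end))
  crosses_interior <- (min(s_int) <= tol && max(s_int) >= -tol) &&
    !(all(abs(s_int) <= tol))
  cm_assert(crosses_interior, "ineligible_trace",
            "trace does not cross the interior edge")
  far_sign <- -sign(line_side(exterior, interior$point))
  cm_assert(far_sign != 0, "geometry",
            "interior and exterior edges are identical")
  s_ext <- c(line_side(exterior, trace$start), line_side(exterior, trace$end))
  reaches_exterior <- any(abs(s_ext) <= tol | sign(s_ext) == far_sign)
  if (reaches_exterior) return("continuing")
  if (trace$present_above || trace$present_below) return("excluded")
  "stopped"
}

#' Angle between a microtubule and the radial vector
#'
#' The acute angle between the trace and the tangent line is measured and
#' subtracted from 90 degrees, giving the angle to the perpendicular of the
#' tangent (the radial vector, i.e. the local membrane normal). 0 means the
#' microtubule takes the shortest path through the reticulum; 90 means it
#' runs parallel to the membrane. Invariant to reversing either direction.
#'
#' @param trace an [mt_trace()].
#' @param tangent a [boundary_line()] serving as the local tangent (normally
#'   the interior edge).
#' @return angle in degrees, in \[0, 90\].
#' @export
angle_to_radial <- function(trace, tangent) {
  u <- trace$end - trace$start
  len <- sqrt(sum(u^2))
  cm_assert(len > 0, "geometry", "zero-length trace")
  cosang <- abs(sum(u * tangent$direction)) / len
  theta_t <- acos(min(1, max(0, cosang))) * 180 / pi
  90 - theta_t
}

#' Summarise stopped vs continuing microtubule angles
#'
#' Per-category mean, standard deviation and count of the angles to the
#' radial vector, plus a two-group comparison (stopped vs continuing) via
#' [compare_two()]. Excluded traces are omitted throughout.
#'
#' @param classifications data frame with columns `category` and
#'   `angle_to_radial` (e.g. from [measure_slab()]).
#' @param test passed to [compare_two()] (default `"auto"`).
#' @return list with `summary` (one row per category) and `comparison` (a
#'   [compare_two()] result).
#' @export
angle_summary <- function(classifications, test = "auto") {
  cl <- classifications[classifications$category != "excluded", , drop = FALSE]
  groups <- split(cl$angle_to_radial, cl$category)
  for (cat in c("stopped", "continuing"))
    cm_assert(length(groups[[cat]]) >= 2, "insufficient_data",
              sprintf("need >= 2 '%s' traces to compare", cat))
  summ <- do.call(rbind, lapply(names(groups), function(g) data.frame(
    category = g, n = length(groups[[g]]), mean = mean(groups[[g]]),
    sd = stats::sd(groups[[g]])
  )))
  cmp <- compare_two(group_sample("stopped", groups$stopped),
                     group_sample("continuing", groups$continuing),
                     test = test)
  list(summary = summ, comparison = cmp)
}

#' Run the full classification + angle pipeline on a slab
#'
#' @param traces list of [mt_trace()]s.
#' @param interior,exterior [boundary_line()]s of the slab.
#' @return data frame with one row per trace: `slab_id`, `category`,
#'   `angle_to_radial` (degrees, also provided rounded to 0.1 degree as
#'   `angle_reported`).
#' @export
measure_slab <- function(traces, interior, exterior) {
  rows <- lapply(traces, function(tr) {
    data.frame(slab_id = tr$slab_id,
               category = classify_trace(tr, interior, exterior),
               angle_to_radial = angle_to_radial(tr, interior))
  })
  out <- do.call(rbind, rows)
  out$angle_reported <- round(out$angle_to_radial, 1)
  out
}
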