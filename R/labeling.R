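#' Connected-component labelling of a binary raster
#'
#' Breadth-first labelling with selectable connectivity. The measurement
#' conventions in this package pair complementary connectivities so that a
#' closed 8-connected foreground ring always separates 4-connected background
#' regions (and vice versa), avoiding the topological paradox where a ring
#' both closes and leaks.
#'
#' @param mask logical matrix; `TRUE` pixels are labelled.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return integer matrix of the same dimensions; 0 for background,
#'   components numbered from 1 in first-encounter (column-major) order.
#' @export
label_components <- function(mask, connectivity = 4) {
  cm_assert(is.matrix(mask) && is.logical(mask), "labeling",
            "`mask` must be a logical matrix")
  cm_assert(connectivity %in% c(4, 8), "labeling", "connectivity must be 4 or 8")
  ny <- nrow(mask); nx <- ncol(mask); n <- ny * nx
  labels <- integer(n)
  visited <- !as.vector(mask)
  starts <- which(!visited)
  lab <- 0L
  for (s in starts) {
    if (visited[s]) next
    lab <- lab + 1L
    frontier <- s
    visited[s] <- TRUE
    labels[s] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% ny + 1L
      up    <- frontier[r > 1L] - 1L
      down  <- frontier[r < ny] + 1L
      left  <- frontier - ny
      right <- frontier + ny
      nb <- c(up, down, left[left >= 1L], right[right <= n])
      if (connectivity == 8) {
        ul <- frontier[r > 1L] - ny - 1L
        dl <- frontier[r < ny] - ny + 1L
        ur <- frontier[r > 1L] + ny - 1L
        dr <- frontier[r < ny] + ny + 1L
        nb <- c(nb, ul[ul >= 1L], dl[dl >= 1L], ur[ur <= n], dr[dr <= n])
      }
      nb <- unique(nb[!visited[nb]])
      visited[nb] <- TRUE
      labels[nb] <- lab
      frontier <- nb
    }
  }
  matrix(labels, ny, nx)
}

#' Connected component containing a seed pixel
#'
#' @param mask logical matrix.
#' @param seed `c(x, y)` 0-based pixel coordinates (fractions are rounded).
#' @param connectivity 4 or 8.
#' @return logical matrix: the component of `mask` containing `seed`, or an
#'   error if the seed pixel is not in `mask`.
#' @export
component_at <- function(mask, seed, connectivity = 4) {
  col <- round(seed[1]) + 1L; row <- round(seed[2]) + 1L
  cm_assert(row >= 1 && row <= nrow(mask) && col >= 1 && col <= ncol(mask),
            "geometry", "seed lies outside the raster")
  cm_assert(isTRUE(mask[row, col]), "geometry",
            sprintf("seed pixel (%g, %g) is not in the mask", seed[1], seed[2]))
  lab <- label_components(mask, connectivity)
  lab == lab[row, col]
}

# Does any TRUE pixel of a mask touch the raster border?
touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}
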