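# Shared fixtures and independent oracles for the test suite.

# Ray-casting point-in-polygon (even-odd rule), independent of the package's
# pracma-based membership test. Boundary handling is undefined, so oracle
# comparisons use polygons whose edges avoid pixel centres.
pip_raycast <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Exhaustive region statistics by looping over every pixel centre.
brute_region_stats <- function(pixels, vx, vy) {
  vals <- c()
  for (row in seq_len(nrow(pixels))) for (col in seq_len(ncol(pixels))) {
    if (pip_raycast(col - 1, row - 1, vx, vy))
      vals <- c(vals, pixels[row, col])
  }
  list(mean = mean(vals), min = min(vals), max = max(vals), n = length(vals))
}

# Recursive-free flood fill oracle for connected-component labelling.
brute_label <- function(mask, connectivity = 4) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
        else cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  for (r in seq_len(ny)) for (cl in seq_len(nx)) {
    if (!mask[r, cl] || lab[r, cl] != 0) next
    cur <- cur + 1L
    stack <- list(c(r, cl))
    lab[r, cl] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx &&
            mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Multiset of component sizes, for label-map comparisons up to renumbering.
component_sizes <- function(lab) sort(tabulate(lab[lab > 0]))

# Binary annulus mask: TRUE where r_inner <= r <= r_outer (pixel units).
annulus_mask <- function(size, center, r_inner, r_outer) {
  dx <- (0:(size - 1)) - center[1]
  dy <- (0:(size - 1)) - center[2]
  r <- sqrt(outer(dy^2, dx^2, "+"))
  r >= r_inner & r <= r_outer
}

# A synthetic intensity profile object for estimator unit tests.
make_profile <- function(positions, values, line_width = 0.1) {
  structure(list(positions = positions, values = values,
                 line_width = line_width,
                 spacing = positions[2] - positions[1], unit = "um"),
            class = "intensity_profile")
}
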