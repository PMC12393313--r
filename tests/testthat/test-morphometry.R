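test_that("line_scan: constant field, stripe plateau, geometry errors", {
  img <- calibrated_image(matrix(7, 48, 48), 0.1)
  p <- line_scan(img, c(23.5, 23.5), 37, 3, 0.5)
  expect_true(all(p$values == 7))
  expect_equal(diff(p$positions), rep(0.05, length(p$positions) - 1))

  # vertical stripe of value 10, width 6 px = 0.6 um, horizontal scan
  px <- matrix(0, 48, 48); px[, 21:26] <- 10
  imgs <- calibrated_image(px, 0.1)
  p2 <- line_scan(imgs, c(23.5, 23.5), 0, 4, 0.1)
  # full-value plateau spans the stripe minus its half-pixel edge ramps;
  # the half-maximum extent recovers the stripe width to within one sample
  plateau <- range(p2$positions[p2$values >= 5])
  expect_equal(diff(plateau), 0.6, tolerance = 0.051)
  expect_true(all(p2$values[p2$values > 0 & p2$values < 10] <= 10))

  expect_error(line_scan(img, c(2, 2), 0, 4, 0.1), class = "centmorph_geometry")
  expect_error(line_scan(img, c(23.5, 23.5), 0, 0.3, 0.1),
               class = "centmorph_geometry")  # < 16 samples
})

test_that("line_scan is equivariant under joint 90-degree rotation", {
  set.seed(5)
  n <- 33
  px <- outer(1:n, 1:n, function(r, cl) 10 + 5 * sin(r / 4) + 3 * cos(cl / 3) + 0.2 * r)
  rot <- matrix(0, n, n)
  for (r in 1:n) for (cl in 1:n) rot[r, cl] <- px[cl, n + 1 - r]
  c0 <- c((n - 1) / 2, (n - 1) / 2)
  p <- line_scan(calibrated_image(px, 0.1), c0, 20, 2, 0.3)
  pr <- line_scan(calibrated_image(rot, 0.1), c0, 110, 2, 0.3)
  expect_equal(pr$values, p$values, tolerance = 1e-6)
})

test_that("diameter_from_profiles: constructed peaks and synthetic annuli", {
  # two unit-height triangular peaks centred at +-1.5 um around midpoint 0
  pos <- seq(-4, 4, by = 0.05)
  tri <- function(x, c0) pmax(0, 1 - abs(x - c0) / 0.3)
  p1 <- make_profile(pos, tri(pos, -1.5) + tri(pos, 1.5))
  p2 <- make_profile(pos, tri(pos, -2.5) + tri(pos, 2.5))
  d <- diameter_from_profiles(p1, p2)
  expect_equal(d$d1, 3)
  expect_equal(d$d2, 5)
  expect_equal(d$average, 4)

  for (D in c(2, 3, 4)) {
    ri <- make_ring_image(ring_spec(D, "gaussian", 0.15),
                          image_size = 96, pixel_size = 0.1)
    q1 <- line_scan(ri$image, ri$truth$center, 0, 8, 0.3)
    q2 <- line_scan(ri$image, ri$truth$center, 90, 8, 0.3)
    dd <- diameter_from_profiles(q1, q2)
    expect_lt(abs(dd$average - D), 0.1)  # within one pixel
  }

  flat <- make_profile(pos, rep(1, length(pos)))
  expect_error(diameter_from_profiles(flat, flat),
               class = "centmorph_peak_detection")
})

test_that("torus threshold implements (mean+min)/2 with Maxthr upper bound", {
  # torus with min 10, mean 30, max 90: 8 boundary px of known values
  px <- matrix(10, 16, 16)
  px[6:11, 6:11] <- 90   # inner square (will be excluded)
  # torus region = ring between the two squares: set controlled values
  px[5, 5:12] <- c(10, 10, 30, 30, 30, 30, 90, 90)
  img <- calibrated_image(px, 1)
  outer <- polygon_roi(rbind(c(4.6, 4.6), c(12.4, 4.6), c(12.4, 12.4), c(4.6, 12.4)))
  inner <- polygon_roi(rbind(c(5.6, 5.6), c(11.4, 5.6), c(11.4, 11.4), c(5.6, 11.4)))
  tm <- torus_threshold(img, outer, inner)
  reg <- roi_mask(outer, dim(px)) & !roi_mask(inner, dim(px))
  st <- list(mean = mean(px[reg]), min = min(px[reg]), max = max(px[reg]))
  expect_equal(tm$lower, (st$mean + st$min) / 2)
  expect_equal(tm$upper, st$max)
  # mask equals brute-force per-pixel application of the rule
  expect_equal(tm$mask, reg & px >= tm$lower & px <= tm$upper)

  # degenerate uniform torus: lower = v, everything selected
  u <- calibrated_image(matrix(5, 16, 16), 1)
  tmu <- torus_threshold(u, outer, inner)
  expect_equal(tmu$lower, 5)
  expect_equal(sum(tmu$mask), sum(reg))
})

test_that("void threshold uses (mean+max)/2; pcm threshold uses mean+max sum", {
  px <- matrix(0, 16, 16)
  px[3:6, 3:6] <- 30; px[4, 4] <- 90
  img <- calibrated_image(px, 1)
  roi <- polygon_roi(rbind(c(2.6, 2.6), c(5.4, 2.6), c(5.4, 5.4), c(2.6, 5.4)))
  vt <- void_threshold(img, roi)
  reg <- roi_mask(roi, dim(px))
  expect_equal(vt$lower, (mean(px[reg]) + 90) / 2)
  expect_equal(vt$upper, 90)
  expect_equal(vt$mask, reg & px >= vt$lower & px <= vt$upper)

  # pcm: background mean 5, max 12 -> lower 17; disk of 100 on background 5
  px2 <- matrix(5, 32, 32); px2[2, 2] <- 12
  dx <- (0:31) - 16; r <- sqrt(outer(dx^2, dx^2, "+"))
  px2[r <= 6] <- 100
  img2 <- calibrated_image(px2, 1)
  bg <- polygon_roi(rbind(c(0.6, 0.6), c(3.4, 0.6), c(3.4, 3.4), c(0.6, 3.4)),
                    kind = "background")
  pm <- pcm_threshold(img2, bg)
  expect_equal(pm$lower, mean(px2[roi_mask(bg, dim(px2))]) + 12)
  expect_equal(pm$mask, r <= 6)   # the disk exactly

  # background brighter than object -> threshold inversion
  dim_img <- calibrated_image(matrix(c(rep(60, 512), rep(50, 512)), 32, 32), 1)
  expect_error(pcm_threshold(dim_img, bg), class = "centmorph_threshold_inversion")
})

test_that("void_area counts the enclosed 4-connected region and detects open rings", {
  ring <- annulus_mask(64, c(31.5, 31.5), 10, 14)
  a <- void_area(ring, c(31.5, 31.5), pixel_size = 1)
  inner_count <- sum(!ring & annulus_mask(64, c(31.5, 31.5), 0, 9.999))
  expect_equal(a, inner_count)
  expect_lt(abs(a - pi * 100) / (pi * 100), 0.02)

  # 90-degree arc removed -> the void leaks to the border
  dx <- (0:63) - 31.5
  theta <- atan2(outer(dx, rep(1, 64)), outer(rep(1, 64), dx))
  broken <- ring & !(theta > 0 & theta < pi / 2)
  expect_error(void_area(broken, c(31.5, 31.5), pixel_size = 1),
               class = "centmorph_open_ring")
})

test_that("area_intensity: enumerable case, linearity, exhaustive oracle", {
  px <- matrix(0, 16, 16); px[2:6, 3] <- 7; px[2:6, 4] <- 7
  mask <- px > 0
  img <- calibrated_image(px, 1)
  ai <- area_intensity(mask, img)
  expect_equal(ai$area, 10)
  expect_equal(ai$total_intensity, 70)
  expect_equal(ai$density, 7)

  img2 <- calibrated_image(2 * px, 1)
  ai2 <- area_intensity(mask, img2)
  expect_equal(ai2$total_intensity, 2 * ai$total_intensity)
  expect_equal(ai2$density, 2 * ai$density)
  expect_equal(ai2$area, ai$area)

  set.seed(3)
  rpx <- matrix(runif(256, 0, 50), 16, 16)
  rmask <- matrix(runif(256) < 0.4, 16, 16)
  rai <- area_intensity(rmask, calibrated_image(rpx, 0.2))
  expect_equal(rai$total_intensity, sum(rpx * rmask))
  expect_equal(rai$area, sum(rmask) * 0.04)
  expect_error(area_intensity(matrix(FALSE, 16, 16), img),
               class = "centmorph_empty_region")
})

test_that("intensity_within_outline measures the co-registered channel", {
  px <- matrix(0, 24, 24); px[8:13, 8:13] <- 3
  other <- calibrated_image(px, 0.5, channel = "GFP::TBA-2")
  outline <- polygon_roi(rbind(c(7.5, 7.5), c(12.5, 7.5), c(12.5, 12.5), c(7.5, 12.5)))
  ai <- intensity_within_outline(outline, other)   # centres 8..12 -> 25 px
  expect_equal(ai$total_intensity, 25 * 3)
  expect_equal(ai$area, 25 * 0.25)
  empty <- polygon_roi(rbind(c(17.5, 17.5), c(22.5, 17.5), c(22.5, 22.5), c(17.5, 22.5)))
  expect_equal(intensity_within_outline(empty, other)$total_intensity, 0)
  out <- polygon_roi(rbind(c(-5, -5), c(30, -5), c(30, 30), c(-5, 30)))
  expect_error(intensity_within_outline(out, other), class = "centmorph_geometry")

  set.seed(8)
  rpx <- matrix(runif(24 * 24, 0, 9), 24, 24)
  rimg <- calibrated_image(rpx, 0.5)
  vx <- c(4.4, 18.7, 20.2, 9.5); vy <- c(5.2, 3.8, 17.6, 19.3)
  oracle <- 0
  for (r in 1:24) for (cl in 1:24)
    if (pip_raycast(cl - 1, r - 1, vx, vy)) oracle <- oracle + rpx[r, cl]
  expect_equal(intensity_within_outline(polygon_roi(cbind(vx, vy)), rimg)$total_intensity,
               oracle)
})

test_that("mt_ring_area reconstructs the outer disk across an excluded wedge", {
  ri <- make_ring_image(ring_spec(3, "rectangular", 0.5),
                        image_size = 96, pixel_size = 0.05)
  tr <- ri$truth
  outer <- circle_roi(tr$center, tr$r_outer / 0.05 + 3, kind = "torus_outer")
  inner <- circle_roi(tr$center, tr$r_inner / 0.05 - 3, kind = "torus_inner")
  no_excl <- mt_ring_area(ri$image, outer, inner)
  disk_truth <- pi * tr$r_outer^2
  expect_lt(abs(no_excl$area - disk_truth) / disk_truth, 0.03)

  wedge <- polygon_roi(rbind(tr$center, tr$center + c(60, 0), tr$center + c(60, 60)),
                       kind = "spindle_exclusion")
  with_excl <- mt_ring_area(ri$image, outer, inner, spindle_exclusion = wedge)
  expect_lt(abs(with_excl$area - disk_truth) / disk_truth, 0.03)
  expect_lt(sum(with_excl$mask), sum(no_excl$mask))

  all_excl <- polygon_roi(rbind(c(0, 0), c(95, 0), c(95, 95), c(0, 95)),
                          kind = "spindle_exclusion")
  expect_error(mt_ring_area(ri$image, outer, inner, spindle_exclusion = all_excl),
               class = "centmorph_empty_region")
})

test_that("ring_width_threshold applies exact circle equivalence", {
  rw <- ring_width_threshold(4 * pi, pi)
  expect_equal(rw$R1, 2)
  expect_equal(rw$R2, 1)
  expect_equal(rw$width_threshold, 1)
  expect_equal(ring_width_threshold(pi, pi)$width_threshold, 0)
  expect_error(ring_width_threshold(1, 2), class = "centmorph_argument_order")
})

test_that("90%-of-max peak widths: rectangular and Gaussian closed forms", {
  pos <- seq(0, 10, by = 0.02)
  # rectangular peaks of width 0.8 at 2.5 and 7.5
  rect <- ifelse(abs(pos - 2.5) <= 0.4 | abs(pos - 7.5) <= 0.4, 10, 0)
  p <- make_profile(pos, rect)
  rw <- ring_width_linescan(p, p)
  expect_length(rw$peak_widths, 4)
  expect_equal(rw$width_linescan, 0.8, tolerance = 0.021)

  # Gaussian peaks, sd 0.3: width at 90% = 2 * sd * sqrt(2 * ln(10/9))
  gauss <- exp(-(pos - 2.5)^2 / (2 * 0.3^2)) + exp(-(pos - 7.5)^2 / (2 * 0.3^2))
  pg <- make_profile(pos, gauss)
  rwg <- ring_width_linescan(pg, pg)
  expect_equal(rwg$width_linescan, 2 * 0.3 * sqrt(2 * log(10 / 9)),
               tolerance = 1e-3)
  # four identical peaks -> the mean equals each width
  expect_equal(rwg$width_linescan, rwg$peak_widths[1], tolerance = 1e-9)

  # truncated peak: level never crossed on the right
  trunc_v <- exp(-(pos - 9.9)^2 / (2 * 0.3^2)) + exp(-(pos - 2)^2 / (2 * 0.3^2))
  expect_error(ring_width_linescan(make_profile(pos, trunc_v),
                                   make_profile(pos, trunc_v)),
               class = "centmorph_truncated_peak")
})

test_that("width estimators agree on an ideal annulus (inner 1.0, outer 1.5 um)", {
  ri <- make_ring_image(ring_spec(2.5, "rectangular", 0.5),
                        image_size = 96, pixel_size = 0.05)
  tr <- ri$truth
  outer <- circle_roi(tr$center, tr$r_outer / 0.05 + 3, kind = "torus_outer")
  inner <- circle_roi(tr$center, tr$r_inner / 0.05 - 3, kind = "torus_inner")
  void <- circle_roi(tr$center, (tr$r_inner + 0.125) / 0.05)
  rw <- measure_ring_width(ri$image, outer, inner, void, tr$center,
                           line_width = 0.05)
  expect_lt(abs(rw$width_threshold - 0.5), 0.05)
  expect_lt(abs(rw$width_linescan - rw$width_threshold), 2 * 0.05)

  # on a Gaussian cross-section the 90%-max width is narrower than the
  # threshold (full-extent) width
  rg <- make_ring_image(ring_spec(2.5, "gaussian", 0.25),
                        image_size = 96, pixel_size = 0.05)
  g1 <- line_scan(rg$image, rg$truth$center, 0, 4, 0.05)
  g2 <- line_scan(rg$image, rg$truth$center, 90, 4, 0.05)
  expect_lt(ring_width_linescan(g1, g2)$width_linescan, 0.5)
})

test_that("gap_area subtracts PCM from void and flags overlap", {
  expect_equal(gap_area(10, 7)$gap, 3)
  expect_equal(gap_area(5, 5)$gap, 0)
  g <- gap_area(4, 6)
  expect_equal(g$gap, -2)
  expect_true(g$overlap)
  # antisymmetric under swapping
  expect_equal(gap_area(4, 6)$gap, -gap_area(6, 4)$gap)
})

test_that("physical outputs are stable under resampling and intensity scaling", {
  coarse <- make_ring_image(ring_spec(3, "gaussian", 0.15),
                            image_size = 96, pixel_size = 0.1)
  fine <- make_ring_image(ring_spec(3, "gaussian", 0.15),
                          image_size = 192, pixel_size = 0.05)
  d_of <- function(ri, w) {
    p1 <- line_scan(ri$image, ri$truth$center, 0, 8, w)
    p2 <- line_scan(ri$image, ri$truth$center, 90, 8, w)
    diameter_from_profiles(p1, p2)$average
  }
  expect_lt(abs(d_of(coarse, 0.3) - d_of(fine, 0.3)), 0.1)

  bright <- coarse$image
  bright$pixels <- bright$pixels * 3
  p1 <- line_scan(coarse$image, coarse$truth$center, 0, 8, 0.3)
  q1 <- line_scan(bright, coarse$truth$center, 0, 8, 0.3)
  expect_equal(q1$values, 3 * p1$values)
  expect_equal(d_of(list(image = bright, truth = coarse$truth), 0.3),
               d_of(coarse, 0.3))
})
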