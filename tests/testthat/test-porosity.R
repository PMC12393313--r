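test_that("extract_holes: enumerable panel, border policy, labeling oracle", {
  # 100x100 panel, one 10x10 opening, 10 nm/px -> one 10,000 nm^2 hole, 1% open
  m <- matrix(TRUE, 100, 100)
  m[41:50, 41:50] <- FALSE
  hs <- extract_holes(membrane_panel(m, 10))
  expect_length(hs$areas, 1)
  expect_equal(hs$areas, 10000)
  expect_equal(hs$open_fraction, 1)

  # background only at the border -> excluded by default, kept with include
  m2 <- matrix(TRUE, 50, 50)
  m2[1, 10:14] <- FALSE
  expect_length(extract_holes(membrane_panel(m2, 10))$areas, 0)
  expect_equal(extract_holes(membrane_panel(m2, 10), "include")$areas, 500)

  # random panels: per-hole areas match the flood-fill oracle
  set.seed(21)
  for (i in 1:3) {
    mr <- matrix(runif(60 * 60) > 0.2, 60, 60)
    hs <- extract_holes(membrane_panel(mr, 5), "include")
    oracle <- component_sizes(brute_label(!mr, 4)) * 25
    expect_equal(sort(hs$areas), sort(oracle))
  }

  expect_error(membrane_panel(matrix(TRUE, 20, 20), 10),
               class = "centmorph_degenerate_panel")
})

test_that("min_passable_area gives 490 nm^2 for a 25 nm microtubule", {
  expect_equal(min_passable_area(25), pi * 12.5^2)
  expect_equal(min_passable_area(25, as_printed = TRUE), 490)
  expect_equal(min_passable_area(2), pi)
  expect_equal(min_passable_area(50), 4 * min_passable_area(25))
})

test_that("passable_holes filters at the cutoff and recomputes the fraction", {
  hs <- structure(list(areas = c(300, 490, 491, 5000), panel_area = 1e6,
                       open_fraction = 100 * 6281 / 1e6, pixel_size = 10,
                       meta = list()), class = "hole_set")
  expect_equal(passable_holes(hs, 0)$areas, hs$areas)
  kept <- passable_holes(hs, min_passable_area(25))
  expect_equal(kept$areas, c(491, 5000))
  expect_equal(kept$open_fraction, 100 * 5491 / 1e6)
  none <- passable_holes(hs, 1e5)
  expect_length(none$areas, 0)
  expect_equal(none$open_fraction, 0)
  # monotonicity in the cutoff
  cuts <- c(0, 100, 490.87, 1000, 6000)
  ns <- sapply(cuts, function(ct) length(passable_holes(hs, ct)$areas))
  opens <- sapply(cuts, function(ct) passable_holes(hs, ct)$open_fraction)
  expect_true(all(diff(ns) <= 0) && all(diff(opens) <= 0))
})

test_that("bin_distribution uses the 500/1000 nm^2 scheme and conserves totals", {
  hs <- structure(list(areas = c(300, 700, 1500, 12000), panel_area = 1e6,
                       open_fraction = 1.45, pixel_size = 10, meta = list()),
                  class = "hole_set")
  bd <- bin_distribution(hs)
  expect_equal(bd$lower, c(0, 500, 1000, seq(2000, 9000, 1000), 10000))
  expect_equal(bd$counts_percent[c(1, 2, 3, 12)], rep(25, 4))
  expect_equal(sum(bd$count), 4)
  expect_equal(sum(bd$area_nm2), sum(hs$areas))
  expect_equal(sum(bd$counts_percent), 100, tolerance = 1e-9)
  expect_equal(sum(bd$area_percent), 100, tolerance = 1e-9)

  one_bin <- structure(list(areas = c(2500, 2600), panel_area = 1e6,
                            open_fraction = 0.51, pixel_size = 10,
                            meta = list()), class = "hole_set")
  bo <- bin_distribution(one_bin)
  expect_equal(bo$counts_percent[bo$lower == 2000], 100)
  expect_equal(sum(bo$counts_percent != 0), 1)

  # edges are right-closed: a 500 nm^2 hole belongs to (0, 500]
  edge <- structure(list(areas = c(500, 500.0001), panel_area = 1e6,
                         open_fraction = 0.1, pixel_size = 10, meta = list()),
                    class = "hole_set")
  be <- bin_distribution(edge)
  expect_equal(be$count[1:2], c(1, 1))

  # larger sample vs an independent histogram
  set.seed(31)
  areas <- rlnorm(1000, 6, 1.1)
  hsr <- structure(list(areas = areas, panel_area = 1e9,
                        open_fraction = 100 * sum(areas) / 1e9, pixel_size = 10,
                        meta = list()), class = "hole_set")
  bdr <- bin_distribution(hsr)
  oracle <- hist(areas, breaks = c(hole_bin_edges()[-13], max(areas) + 1),
                 plot = FALSE, right = TRUE)$counts
  expect_equal(bdr$count, oracle)
  expect_equal(sum(bdr$counts_percent), 100, tolerance = 1e-9)
  expect_equal(sum(bdr$area_percent), 100, tolerance = 1e-9)
})

test_that("viewing_angle measures line-to-plane angle against the 30-degree limit", {
  va <- viewing_angle(c(0, 0, 0), c(5, 3, 0), c(0, 0, 1))
  expect_equal(va$angle, 0)
  expect_true(va$pass)
  va2 <- viewing_angle(c(0, 0, 0), c(4, 0, 3), c(0, 0, 1))
  expect_equal(va2$angle, atan(3 / 4) * 180 / pi)
  expect_false(va2$pass)
  va3 <- viewing_angle(c(1, 1, 1), c(1, 1, 4), c(0, 0, 1))
  expect_equal(va3$angle, 90)
  expect_false(va3$pass)
  expect_error(viewing_angle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               class = "centmorph_geometry")
})

test_that("hole areas are resolution-stable under 2x upsampling", {
  pn <- make_panel(panel_spec(target_open_fraction = 8), seed = 55)
  hs <- extract_holes(pn$panel)
  up <- membrane_panel(kronecker(pn$panel$mask, matrix(TRUE, 2, 2)),
                       pn$panel$pixel_size / 2)
  hs2 <- extract_holes(up)
  expect_equal(length(hs2$areas), length(hs$areas))
  expect_equal(sort(hs2$areas), sort(hs$areas), tolerance = 1e-12)
})
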