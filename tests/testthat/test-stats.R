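test_that("compare_two matches closed-form t and exact Mann-Whitney oracles", {
  a <- group_sample("a", c(1, 2, 3))
  b <- group_sample("b", c(101, 102, 103))
  res <- compare_two(a, b, "unpaired_t")
  # pooled-variance t with 4 df, computed from first principles
  sp2 <- (2 * var(a$values) + 2 * var(b$values)) / 4
  t_oracle <- (mean(a$values) - mean(b$values)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_oracle)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), df = 4))
  expect_lt(res$p, 0.001)

  # exact Mann-Whitney by full enumeration of group assignments
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(4.3, 6.2, 7.9, 8.8, 0.7)
  res_mw <- compare_two(group_sample("x", x), group_sample("y", y), "mann_whitney")
  pooled <- c(x, y)
  combos <- combn(9, 4)
  w_obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
  w_all <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - 10)
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(res_mw$statistic, w_obs)
  expect_equal(res_mw$p, p_exact)
})

test_that("identical groups give p = 1 and auto mode dispatches on normality", {
  same <- group_sample("g", rep(4.2, 6))
  res <- compare_two(same, same)
  expect_equal(res$p, 1)
  expect_equal(res$test, "mann_whitney")

  set.seed(2)
  norm_a <- group_sample("a", rnorm(20))
  norm_b <- group_sample("b", rnorm(20))
  expect_equal(compare_two(norm_a, norm_b)$test, "unpaired_t")
  skew_a <- group_sample("a", rlnorm(20, 0, 1.5))
  skew_b <- group_sample("b", rlnorm(20, 0, 1.5))
  expect_equal(compare_two(skew_a, skew_b)$test, "mann_whitney")

  expect_error(compare_two(group_sample("a", 1), norm_b),
               class = "centmorph_insufficient_data")
  # summaries report mean and sd per group
  expect_equal(compare_two(norm_a, norm_b)$summary$mean[1], mean(norm_a$values))
  expect_equal(compare_two(norm_a, norm_b)$summary$sd[2], sd(norm_b$values))
})

test_that("auto test holds its nominal type-I error on Gaussian nulls", {
  set.seed(1234)
  rej <- mean(vapply(1:400, function(i) {
    compare_two(group_sample("a", rnorm(15)), group_sample("b", rnorm(15)))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("compare_many: omnibus, separation pattern, correction monotonicity", {
  g <- function(l, v) group_sample(l, v)
  same <- c(5.1, 4.9, 5.0, 5.2, 4.8)
  res <- compare_many(list(g("a", same), g("b", same), g("c", same)))
  expect_gt(res$p, 0.95)

  set.seed(3)
  res2 <- compare_many(list(g("a", rnorm(10)), g("b", rnorm(10)),
                            g("c", rnorm(10, 50))))
  pw <- res2$pairwise
  sig <- pw$p_adj < 0.05
  involving_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(sig[involving_c]))
  expect_false(any(sig[!involving_c]))
  expect_true(all(pw$p_adj >= pw$p))

  expect_error(compare_many(list(g("a", 1:3), g("b", 1:3))),
               class = "centmorph_insufficient_data")
})

test_that("Dunn z for two groups squares to the Kruskal-Wallis statistic", {
  # with k = 2 and no ties, H = z^2; exercises the rank-variance formula
  set.seed(4)
  x <- rnorm(8); y <- rnorm(10, 1)
  values <- c(x, y)
  groups <- factor(rep(c("x", "y"), c(8, 10)))
  pw <- centmorph:::dunn_pairwise(values, groups)
  H <- kruskal.test(values, groups)$statistic
  expect_equal(pw$z^2, unname(H), tolerance = 1e-10)

  # hand-computed fixed vector with ties
  v <- c(1, 2, 2, 3, 5, 5, 5, 9)
  gr <- factor(rep(c("a", "b"), each = 4))
  pw2 <- centmorph:::dunn_pairwise(v, gr)
  rk <- rank(v)
  tie_term <- sum(sapply(table(v), function(t) t^3 - t)) / (12 * 7)
  se <- sqrt((8 * 9 / 12 - tie_term) * (1 / 4 + 1 / 4))
  z_hand <- (mean(rk[1:4]) - mean(rk[5:8])) / se
  expect_equal(pw2$z, z_hand)
  expect_equal(pw2$p, 2 * pnorm(-abs(z_hand)))
})

test_that("regress matches the normal-equation oracle to 1e-10", {
  x <- c(1, 2, 3, 4, 5)
  r <- regress(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  rc <- regress(x, rep(3, 5))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)

  set.seed(5)
  xs <- runif(40); ys <- 1.5 * xs + rnorm(40, sd = 0.3)
  rr <- regress(xs, ys)
  X <- cbind(1, xs)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  resid <- ys - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((ys - mean(ys))^2)
  expect_equal(rr$intercept, beta[1], tolerance = 1e-10)
  expect_equal(rr$slope, beta[2], tolerance = 1e-10)
  expect_equal(rr$r_squared, r2, tolerance = 1e-10)
  # slope p from first principles
  se_slope <- sqrt(sum(resid^2) / 38 * solve(t(X) %*% X)[2, 2])
  expect_equal(rr$p_slope, 2 * pt(-abs(beta[2] / se_slope), 38), tolerance = 1e-10)

  expect_error(regress(rep(1, 5), 1:5), class = "centmorph_degenerate_regressor")
  expect_error(regress(1:2, 1:2), class = "centmorph_insufficient_data")
})

test_that("build_report writes tables that regenerate idempotently", {
  dir <- withr::local_tempdir()
  meas <- list(ring = data.frame(group = rep(c("ctrl", "rnai"), each = 4),
                                 value = c(3.1, 3.3, 2.9, 3.2, 4.0, 4.2, 4.1, 3.9)))
  cmp <- list(ring = compare_two(group_sample("ctrl", meas$ring$value[1:4]),
                                 group_sample("rnai", meas$ring$value[5:8])))
  hs <- structure(list(areas = c(300, 700, 1500, 12000), panel_area = 1e6,
                       open_fraction = 1.45, pixel_size = 10, meta = list()),
                  class = "hole_set")
  files <- build_report(meas, cmp, list(holes = bin_distribution(hs)),
                        out_dir = dir, plots = FALSE)
  expect_true(all(file.exists(files)))
  ring_csv <- file.path(dir, "ring.csv")
  first <- readLines(ring_csv)
  # regenerate from the saved CSV: identical output
  build_report(list(ring = read.csv(ring_csv)), cmp,
               list(holes = bin_distribution(hs)), out_dir = dir, plots = FALSE)
  expect_identical(readLines(ring_csv), first)
  bin_csv <- read.csv(file.path(dir, "holes_binned.csv"))
  expect_equal(sum(bin_csv$counts_percent), 100, tolerance = 1e-9)
  expect_equal(sum(bin_csv$area_percent), 100, tolerance = 1e-9)
  expect_error(build_report(list()), class = "centmorph_report")
})
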