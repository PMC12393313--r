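#' A labelled sample of measurements
#'
#' @param label group label, e.g. `"control"` or `"klp-7 RNAi"`.
#' @param values numeric measurements (finite).
#' @return object of class `group_sample`.
#' @export
group_sample <- function(label, values) {
  values <- as.numeric(values)
  cm_assert(all(is.finite(values)), "sample", "values must be finite")
  structure(list(label = as.character(label), values = values,
                 n = length(values)),
            class = "group_sample")
}

group_summary <- function(...) {
  gs <- list(...)
  do.call(rbind, lapply(gs, function(g) data.frame(
    label = g$label, n = g$n, mean = mean(g$values),
    sd = stats::sd(g$values))))
}

#' Two-group comparison with automatic test dispatch
#'
#' In `"auto"` mode both groups are screened with a Shapiro-Wilk normality
#' test (alpha = 0.05; groups of n < 3 cannot be screened and are treated as
#' non-normal): if both pass, a classical unpaired two-sample t-test (equal
#' variances) is used, otherwise a two-tailed Mann-Whitney test. The
#' Mann-Whitney test uses the exact distribution when the combined n is at
#' most 20 and there are no ties, and the tie-corrected normal approximation
#' otherwise; when every value in both groups is identical the comparison is
#' degenerate and p = 1 is returned by convention.
#'
#' @param a,b [group_sample()]s with n >= 2 each.
#' @param test `"auto"`, `"unpaired_t"` or `"mann_whitney"`.
#' @return object of class `comparison_result`: `test` (the test actually
#'   run), `statistic`, `p`, and `summary` (mean ± sd per group).
#' @export
compare_two <- function(a, b, test = c("auto", "unpaired_t", "mann_whitney")) {
  test <- match.arg(test)
  cm_assert(a$n >= 2 && b$n >= 2, "insufficient_data",
            "each group needs at least 2 values")
  if (test == "auto") {
    normal <- function(g) {
      g$n >= 3 && diff(range(g$values)) > 0 &&
        stats::shapiro.test(g$values)$p.value > 0.05
    }
    test <- if (all(diff(range(c(a$values, b$values))) == 0)) "mann_whitney"
            else if (normal(a) && normal(b)) "unpaired_t" else "mann_whitney"
  }
  if (test == "unpaired_t") {
    ht <- stats::t.test(a$values, b$values, var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (diff(range(c(a$values, b$values))) == 0) {
      stat <- a$n * b$n / 2; p <- 1   # fully tied: no evidence of a shift
    } else {
      exact <- (a$n + b$n) <= 20 && !any(duplicated(c(a$values, b$values)))
      ht <- suppressWarnings(stats::wilcox.test(a$values, b$values,
                                                exact = exact, correct = TRUE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  structure(list(test = test, statistic = stat, p = p,
                 summary = group_summary(a, b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: statistic %.4g, p = %.4g\n", x$test,
              x$statistic, x$p))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.4g ± %.4g (n = %d)\n", x$summary$label[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  invisible(x)
}

# Dunn (1964) post-hoc z-tests on the joint Kruskal-Wallis ranks, with the
# standard tie correction; two-sided p per pair.
dunn_pairwise <- function(values, groups) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  labs <- names(mean_rank)
  pairs <- utils::combn(labs, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p)
}

#' Multi-group comparison: Kruskal-Wallis with corrected pairwise tests
#'
#' Kruskal-Wallis omnibus test over three or more groups, followed by
#' Dunn-style pairwise z-tests on the joint ranks with multiplicity
#' correction (Holm by default; any method of [stats::p.adjust()] may be
#' selected).
#'
#' @param groups list of three or more [group_sample()]s, each n >= 2.
#' @param p_adjust multiplicity-correction method (see [stats::p.adjust()]).
#' @return object of class `comparison_result` with the omnibus `statistic`
#'   and `p`, the per-group `summary`, and `pairwise` (data frame with `z`,
#'   raw `p` and corrected `p_adj` per pair).
#' @export
compare_many <- function(groups, p_adjust = "holm") {
  cm_assert(length(groups) >= 3, "insufficient_data",
            "need >= 3 groups (use compare_two for two)")
  for (g in groups)
    cm_assert(g$n >= 2, "insufficient_data",
              sprintf("group '%s' has fewer than 2 values", g$label))
  values <- unlist(lapply(groups, `[[`, "values"))
  labels <- factor(rep(vapply(groups, `[[`, "", "label"),
                       vapply(groups, `[[`, 0L, "n")),
                   levels = vapply(groups, `[[`, "", "label"))
  kw <- stats::kruskal.test(values, labels)
  pw <- dunn_pairwise(values, labels)
  pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)
  structure(list(test = "kruskal_wallis", statistic = unname(kw$statistic),
                 p = kw$p.value, summary = do.call(group_summary, groups),
                 pairwise = pw),
            class = "comparison_result")
}

#' Ordinary least-squares regression with slope test
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be constant.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared` and `p_slope` (two-sided test of slope = 0).
#' @export
regress <- function(x, y) {
  cm_assert(length(x) == length(y) && length(x) >= 3, "insufficient_data",
            "need >= 3 paired observations")
  cm_assert(diff(range(x)) > 0, "degenerate_regressor", "`x` is constant")
  if (diff(range(y)) == 0)   # flat response: slope 0, nothing explained
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_slope = 1),
                     class = "regression_result"))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  p_slope <- if (nrow(sm$coefficients) < 2 || is.nan(sm$coefficients[2, 4])) 1
             else sm$coefficients[2, 4]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, p_slope = p_slope),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope %.4g (p = %.4g), intercept %.4g, R^2 %.4g\n",
              x$slope, x$p_slope, x$intercept, x$r_squared))
  invisible(x)
}

comparison_df <- function(cmp, name) {
  data.frame(comparison = name, test = cmp$test,
             statistic = cmp$statistic, p = cmp$p)
}

#' Assemble a tabular + graphical report bundle
#'
#' Writes one CSV per measurement table (one row per centrosome, panel or
#' trace), one CSV per binned distribution, a summary CSV of all statistical
#' comparisons, and — when `plots = TRUE` — a scatter-with-mean-±-sd plot per
#' measurement table that has `group`/`value` columns and a bar chart per
#' binned distribution. Regenerating a report from its own saved CSVs yields
#' identical files.
#'
#' @param measurements named list of data frames.
#' @param comparisons named list of `comparison_result`s (may be empty).
#' @param distributions named list of [bin_distribution()] outputs (may be
#'   empty).
#' @param out_dir output directory (created if needed).
#' @param plots write PDF plots under `out_dir/plots`.
#' @return invisible manifest: character vector of files written.
#' @export
build_report <- function(measurements, comparisons = list(),
                         distributions = list(), out_dir = "report",
                         plots = TRUE) {
  cm_assert(length(measurements) >= 1, "report",
            "at least one measurement table is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  for (nm in names(measurements)) wr(measurements[[nm]], nm)
  for (nm in names(distributions)) wr(as.data.frame(distributions[[nm]]),
                                      paste0(nm, "_binned"))
  if (length(comparisons) > 0) {
    wr(do.call(rbind, Map(comparison_df, comparisons, names(comparisons))),
       "comparisons")
  }
  if (plots) {
    pdir <- file.path(out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (nm in names(measurements)) {
      df <- measurements[[nm]]
      if (!all(c("group", "value") %in% names(df))) next
      ms <- do.call(rbind, lapply(split(df$value, df$group), function(v)
        data.frame(mean = mean(v), sd = stats::sd(v))))
      ms$group <- rownames(ms)
      p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
        ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
        ggplot2::geom_pointrange(
          data = ms, ggplot2::aes(y = mean, ymin = mean - sd, ymax = mean + sd),
          colour = "firebrick") +
        ggplot2::labs(title = nm, y = "value") +
        ggplot2::theme_classic()
      f <- file.path(pdir, paste0(nm, ".pdf"))
      ggplot2::ggsave(f, p, width = 4, height = 3.5)
      written <- c(written, f)
    }
    for (nm in names(distributions)) {
      df <- as.data.frame(distributions[[nm]])
      df$bin <- factor(df$bin, levels = df$bin)
      p <- ggplot2::ggplot(df, ggplot2::aes(x = bin, y = counts_percent)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(title = nm, x = "hole area (nm^2)", y = "% of holes") +
        ggplot2::theme_classic() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
      f <- file.path(pdir, paste0(nm, "_binned.pdf"))
      ggplot2::ggsave(f, p, width = 5, height = 3.5)
      written <- c(written, f)
    }
  }
  invisible(written)
}
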