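# Statistical comparison and summary helpers mirroring the evaluation
# figures: Mann-Whitney U with significance stars, curve mean/sd bands,
# boxplot five-number summaries with outlier fences.

#' Significance label from a p value
#'
#' Thresholds: ns for p > 0.05, * for p <= 0.05, ** for p <= 0.01,
#' *** for p <= 0.001.
#'
#' @param p p value in [0, 1].
#' @return one of "ns", "*", "**", "***".
#' @export
significance_label <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Two-sided Mann-Whitney U test
#'
#' The U statistic is computed from rank sums with midrank tie handling.
#' The two-sided p value is exact (by enumeration over rank assignments)
#' for small untied samples (n1 + n2 <= 12) and uses the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return a \code{stat_test_result}: \code{U} (for \code{x}),
#'   \code{p_value}, \code{n1}, \code{n2}, \code{method},
#'   \code{label}.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))                       # midranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (n1 + n2) <= 12
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- min(1, wt$p.value)
  # fully tied samples (zero variance in both groups) degenerate to NaN
  # in the normal approximation: no evidence of separation
  if (is.na(p)) p <- 1
  structure(list(U = unname(U), p_value = p, n1 = n1, n2 = n2,
                 method = if (exact) "exact" else "normal approximation",
                 label = significance_label(p)),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g (%s) [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method, x$label))
  invisible(x)
}

#' Mean and standard deviation of repeated perturbation curves
#'
#' Pointwise mean and sample standard deviation over repeats; for a single
#' repeat the sd is reported absent (NA), not 0.
#'
#' @param curves a \code{perturbation_curve} data.frame (columns
#'   \code{step}, \code{n_residues_randomized}, \code{rep}, \code{count})
#'   or a repeats-by-steps numeric matrix.
#' @return data.frame with \code{step}, \code{n_residues_randomized}
#'   (when available), \code{mean}, \code{sd}.
#' @export
summarize_curve <- function(curves) {
  if (is.matrix(curves)) {
    curves <- data.frame(step = rep(seq_len(ncol(curves)) - 1L, each = nrow(curves)),
                         n_residues_randomized = NA_integer_,
                         rep = rep(seq_len(nrow(curves)), ncol(curves)),
                         count = as.vector(curves))
  }
  stopifnot(all(c("step", "rep", "count") %in% names(curves)))
  grids <- split(curves$step, curves$rep)
  if (length(unique(lapply(grids, sort))) != 1)
    stop("repeats disagree on the step grid")
  agg <- lapply(split(curves, curves$step), function(d) {
    data.frame(step = d$step[1],
               n_residues_randomized = d$n_residues_randomized[1],
               mean = mean(d$count),
               sd = if (nrow(d) > 1) stats::sd(d$count) else NA_real_)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$step), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Boxplot summary statistics
#'
#' Quartiles by linear interpolation; whiskers reach the most extreme data
#' points within 1.5 interquartile ranges of the quartiles; points beyond
#' the fences are listed as outliers.
#'
#' @param values numeric vector with at least one value.
#' @return a \code{boxplot_summary}: \code{q1}, \code{median}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers}.
#' @export
boxplot_stats <- function(values) {
  stopifnot(length(values) >= 1, is.numeric(values))
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(list(q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(values[values < lo_fence | values > hi_fence])),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf("box: Q1 %.3g | median %.3g | Q3 %.3g; whiskers [%.3g, %.3g]; %d outliers\n",
              x$q1, x$median, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Plot a perturbation curve with mean and sd band
#'
#' Base graphics rendering of the reproduction-versus-randomization curve.
#'
#' @param x a \code{perturbation_curve}.
#' @param add add to an existing plot.
#' @param col line/band color.
#' @param ... passed to \code{plot}.
#' @export
plot.perturbation_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  s <- summarize_curve(x)
  if (!add) {
    plot(s$n_residues_randomized, s$mean, type = "n",
         xlab = "n residues randomized", ylab = "n_uq_repro compounds",
         ylim = c(0, max(s$mean + ifelse(is.na(s$sd), 0, s$sd))), ...)
  }
  band <- ifelse(is.na(s$sd), 0, s$sd)
  graphics::polygon(c(s$n_residues_randomized, rev(s$n_residues_randomized)),
                    c(s$mean - band, rev(s$mean + band)),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(s$n_residues_randomized, s$mean, col = col, lwd = 2)
  invisible(s)
}
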