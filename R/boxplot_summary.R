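#' Five-number boxplot summary with Tukey-fence outliers
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the default of mainstream statistics
#' stacks). Outliers are values strictly below `q1 - 1.5 * IQR` or
#' strictly above `q3 + 1.5 * IQR`; whiskers are the extreme data values
#' inside those fences (the minimum and maximum without outliers).
#'
#' @param values Numeric vector with at least one finite value.
#' @return An object of class `boxplot_summary`: list with `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @examples
#' s <- boxplot_summary(c(1, 2, 3, 4, 100))
#' s$outliers       # 100
#' s$whisker_high   # 4
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("need at least one finite value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inside <- values[values >= lo & values <= hi]
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(out), n = length(values)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot summary (n = %d): whiskers [%g, %g], box [%g, %g], median %g",
    x$n, x$whisker_low, x$whisker_high, x$q1, x$q3, x$median))
  cat(sprintf(", %d outlier(s)\n", length(x$outliers)))
  invisible(x)
}

#' @rdname boxplot_summary
#' @param x A `boxplot_summary`.
#' @param ... Unused.
#' @export
as.data.frame.boxplot_summary <- function(x, ...) {
  data.frame(n = x$n, whisker_low = x$whisker_low, q1 = x$q1,
             median = x$median, q3 = x$q3, whisker_high = x$whisker_high,
             n_outliers = length(x$outliers))
}
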