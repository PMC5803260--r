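#' Mann-Whitney U comparison of cut versus uncut site signal
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the windowed signal
#' at cut sites against uncut sites. The statistic is the U of the cut
#' group (rank sum minus its minimum). When both groups have at most 8
#' observations the p-value is computed by exact enumeration of all label
#' assignments (valid under ties, using midranks); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' `direction` reports which group has the larger median.
#'
#' Cut and uncut populations are different site sets, so the unpaired test
#' is the appropriate one; for before/after comparisons at the *same*
#' sites, use [compare_conditions_paired()].
#'
#' @param quants A `site_quant` table from [quantify_sites()] with a
#'   logical `cut` column, or any data.frame with `cut` and the signal
#'   column.
#' @param column Name of the signal column to compare.
#' @return An object of class `cut_uncut_test`: list with `n_cut`,
#'   `n_uncut`, `statistic` (U), `p_value`, `direction`, `method`.
#' @examples
#' q <- data.frame(cut = rep(c(TRUE, FALSE), each = 3),
#'                 signal = c(10, 12, 14, 1, 2, 3))
#' compare_cut_uncut(q)$p_value   # exact: 0.1
#' @export
compare_cut_uncut <- function(quants, column = "signal") {
  if (!column %in% names(quants)) stop("no column '", column, "'")
  if (!"cut" %in% names(quants)) stop("quants need a logical 'cut' column")
  x <- quants[[column]][quants$cut %in% TRUE]
  y <- quants[[column]][quants$cut %in% FALSE]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty (n_cut = ", length(x),
         ", n_uncut = ", length(y), ")")
  }
  u <- u_statistic(x, y)
  n1 <- length(x); n2 <- length(y)
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    p <- exact_u_pvalue(x, y, u)
    method <- "exact enumeration"
  } else {
    p <- normal_u_pvalue(x, y, u)
    method <- "normal approximation with tie and continuity correction"
  }
  med_x <- median(x); med_y <- median(y)
  structure(list(
    n_cut = n1, n_uncut = n2, statistic = u, p_value = p,
    direction = if (med_x > med_y) "cut" else if (med_x < med_y) "uncut"
                else "none",
    method = method
  ), class = "cut_uncut_test")
}

# U statistic of group x via midranks
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# exact two-sided p by enumerating all choose(n1+n2, n1) group assignments;
# the permutation distribution of U is symmetric about n1*n2/2 even under
# ties, so two-sided mass is |U - mu| >= |U_obs - mu|
exact_u_pvalue <- function(x, y, u_obs) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * length(y) / 2
  combs <- combn(length(pooled), n1)
  us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

normal_u_pvalue <- function(x, y, u_obs) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' @export
print.cut_uncut_test <- function(x, ...) {
  cat("Mann-Whitney U test, cut vs uncut sites\n")
  cat(sprintf("  n_cut = %d, n_uncut = %d\n", x$n_cut, x$n_uncut))
  cat(sprintf("  U = %g, p = %.4g (%s)\n", x$statistic, x$p_value,
              x$method))
  cat(sprintf("  larger median: %s\n", x$direction))
  invisible(x)
}

#' Paired comparison of two conditions at the same sites
#'
#' Wilcoxon signed-rank test (two-sided) of the per-site signal before
#' versus after treatment, for tables quantified at the same sites. Rows
#' are matched by `site_id`.
#'
#' @param quants_a,quants_b `site_quant` tables covering the same sites.
#' @param column Signal column name.
#' @return The `htest` object from [stats::wilcox.test()], augmented with
#'   `n` (number of pairs).
#' @export
compare_conditions_paired <- function(quants_a, quants_b,
                                      column = "signal") {
  stopifnot(column %in% names(quants_a), column %in% names(quants_b))
  m <- match(quants_a$site_id, quants_b$site_id)
  if (any(is.na(m))) stop("site ids of the two tables do not match")
  a <- quants_a[[column]]
  b <- quants_b[[column]][m]
  ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
  ht$n <- length(a)
  ht
}
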