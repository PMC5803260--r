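#' Site-centered binned signal matrix (heatmap input)
#'
#' For every site, computes the mean signal in fixed-width bins tiling the
#' window `[position - halfwidth, position + halfwidth)` (default: 500 bp
#' bins over a 10 kb window, i.e. 20 bins). Bases beyond a chromosome end
#' count as 0 with the full bin width as denominator, so each row's
#' bin means times the bin width sum exactly to the site's window sum.
#' Rows are ordered by decreasing cleavage efficiency (`"cleavage_desc"`)
#' or by a supplied score (`"score_desc"`), ties broken by site id.
#'
#' @param track A [coverage_track()].
#' @param sites Site table (see [quantify_sites()]).
#' @param halfwidth Window half-width in bp; `2 * halfwidth` must be
#'   divisible by `bin_width`.
#' @param bin_width Bin width in bp.
#' @param ordering Row ordering rule.
#' @param score Numeric vector (length `nrow(sites)`) used when
#'   `ordering = "score_desc"`.
#' @return An object of class `signal_matrix`: list with `matrix` (sites x
#'   bins, rownames = site ids), `bin_starts` (bp offsets of bin starts
#'   from the site center), `bin_width`, `halfwidth`, `ordering`.
#' @export
heatmap_matrix <- function(track, sites, halfwidth = 5000, bin_width = 500,
                           ordering = c("cleavage_desc", "score_desc"),
                           score = NULL) {
  ordering <- match.arg(ordering)
  if ((2 * halfwidth) %% bin_width != 0) {
    stop("2 * halfwidth (", 2 * halfwidth,
         ") must be divisible by bin_width (", bin_width, ")")
  }
  if (nrow(sites) == 0) stop("sites must be non-empty")
  n_bins <- as.integer(2 * halfwidth / bin_width)
  key <- switch(ordering,
                cleavage_desc = {
                  if (!"efficiency" %in% names(sites)) {
                    stop("ordering 'cleavage_desc' needs an efficiency ",
                         "column")
                  }
                  sites$efficiency
                },
                score_desc = {
                  if (is.null(score) || length(score) != nrow(sites)) {
                    stop("ordering 'score_desc' needs a score vector of ",
                         "length nrow(sites)")
                  }
                  score
                })
  ord <- order(-key, sites$site_id)
  sites <- sites[ord, , drop = FALSE]

  m <- matrix(0, nrow = nrow(sites), ncol = n_bins,
              dimnames = list(sites$site_id, NULL))
  for (i in seq_len(nrow(sites))) {
    L <- track_length(track, sites$chrom[i])
    a0 <- sites$position[i] - halfwidth
    for (j in seq_len(n_bins)) {
      a <- max(a0 + (j - 1) * bin_width, 0)
      b <- min(a0 + j * bin_width, L)
      s <- if (a < b) sum(track$values[[sites$chrom[i]]][(a + 1):b]) else 0
      m[i, j] <- s / bin_width
    }
  }
  structure(list(matrix = m,
                 bin_starts = seq(-halfwidth, halfwidth - bin_width,
                                  by = bin_width),
                 bin_width = bin_width, halfwidth = halfwidth,
                 ordering = ordering),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d sites x %d bins (%g bp), ±%g bp, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_width, x$halfwidth,
              x$ordering))
  invisible(x)
}

#' Averaged site-centered signal profile
#'
#' Position-wise mean signal across sites at each offset (or
#' `resolution`-bp offset bin) relative to the site center, over
#' `[-halfwidth, +halfwidth)`. Sites whose window is truncated by a
#' chromosome end contribute only their covered offsets: per-offset
#' denominators are tracked, so truncation does not bias the average.
#'
#' @param track A [coverage_track()].
#' @param sites Site table.
#' @param halfwidth Window half-width in bp.
#' @param resolution Offset bin width in bp (1 = per-base).
#' @return A data.frame with `offset` (bin start relative to the center),
#'   `mean_signal` and `n_sites` (per-offset denominator).
#' @export
average_profile <- function(track, sites, halfwidth, resolution = 1) {
  if (nrow(sites) == 0) stop("sites must be non-empty")
  if ((2 * halfwidth) %% resolution != 0) {
    stop("2 * halfwidth must be divisible by resolution")
  }
  n_off <- as.integer(2 * halfwidth / resolution)
  acc <- numeric(n_off)
  cnt <- numeric(n_off)
  for (i in seq_len(nrow(sites))) {
    L <- track_length(track, sites$chrom[i])
    a0 <- sites$position[i] - halfwidth
    for (j in seq_len(n_off)) {
      a <- max(a0 + (j - 1) * resolution, 0)
      b <- min(a0 + j * resolution, L)
      if (a < b) {
        acc[j] <- acc[j] +
          sum(track$values[[sites$chrom[i]]][(a + 1):b]) / (b - a)
        cnt[j] <- cnt[j] + 1
      }
    }
  }
  data.frame(offset = seq(-halfwidth, halfwidth - resolution,
                          by = resolution),
             mean_signal = ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_),
             n_sites = cnt)
}

#' Metagene profile with scaled gene bodies and fixed-width flanks
#'
#' Computes the mean coverage profile over a gene set on a common axis:
#' `flank / flank_bin` fixed-width bins upstream of the TSS (default 15
#' bins of 200 bp over 3 kb), `n_body_bins` bins spanning the gene body as
#' a percentage of gene length (default 100), and the same number of
#' fixed-width bins downstream of the TTS. Bins are computed in genomic
#' coordinates and the whole profile is reversed for minus-strand genes,
#' so bin 1 is always the 5'-most flank bin. Body bin `b` of a plus-strand
#' gene of length `L` covers gene bases `[floor((b-1)L/B), floor(bL/B))`.
#'
#' Genes shorter than `n_body_bins`, and genes whose flanked span extends
#' beyond a chromosome end, are excluded; the exclusion count is reported
#' via `message()` and in the result's attributes. Per-bin values are mean
#' coverage; genes are aggregated with equal weight by default.
#'
#' @param track A [coverage_track()].
#' @param genes Gene table with `chrom, start, end, strand` (0-based
#'   half-open; strand `+`/`-`, anything else treated as `+`).
#' @param flank Flank length in bp; must be divisible by `flank_bin`.
#' @param flank_bin Flank bin width in bp.
#' @param n_body_bins Number of scaled gene-body bins.
#' @param weight `"equal"` (each gene counts once) or `"length"`
#'   (genes weighted by their length).
#' @return An object of class `metagene_profile`: data.frame with
#'   `region` (`upstream`, `body`, `downstream`), `bin` (1-based within
#'   the full profile), `mean_signal`; attributes `n_genes`, `n_excluded`.
#' @export
metagene_profile <- function(track, genes, flank = 3000, flank_bin = 200,
                             n_body_bins = 100, weight = c("equal",
                                                           "length")) {
  weight <- match.arg(weight)
  if (flank %% flank_bin != 0) {
    stop("flank must be divisible by flank_bin")
  }
  n_flank <- as.integer(flank / flank_bin)
  n_tot <- 2L * n_flank + as.integer(n_body_bins)

  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    L <- track_length(track, genes$chrom[i])
    len <- genes$end[i] - genes$start[i]
    keep[i] <- len >= n_body_bins &&
      genes$start[i] - flank >= 0 && genes$end[i] + flank <= L
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " gene(s) excluded (shorter than ", n_body_bins,
            " bp or flank outside chromosome)")
  }
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) stop("no genes left after filtering")

  acc <- numeric(n_tot)
  wsum <- 0
  for (i in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[i]]]
    prof <- gene_profile_bins(v, genes$start[i], genes$end[i], flank,
                              flank_bin, n_body_bins)
    if (identical(genes$strand[i], "-")) prof <- rev(prof)
    w <- if (weight == "length") genes$end[i] - genes$start[i] else 1
    acc <- acc + w * prof
    wsum <- wsum + w
  }
  out <- data.frame(
    region = rep(c("upstream", "body", "downstream"),
                 c(n_flank, n_body_bins, n_flank)),
    bin = seq_len(n_tot),
    mean_signal = acc / wsum
  )
  attr(out, "n_genes") <- nrow(genes)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "flank") <- flank
  attr(out, "flank_bin") <- flank_bin
  attr(out, "n_body_bins") <- n_body_bins
  class(out) <- c("metagene_profile", "data.frame")
  out
}

# per-gene bin means in genomic (left-to-right) order
gene_profile_bins <- function(v, start, end, flank, flank_bin,
                              n_body_bins) {
  n_flank <- flank / flank_bin
  L <- end - start
  up <- vapply(seq_len(n_flank), function(j) {
    a <- start - flank + (j - 1) * flank_bin
    mean(v[(a + 1):(a + flank_bin)])
  }, numeric(1))
  body <- vapply(seq_len(n_body_bins), function(b) {
    a <- start + floor((b - 1) * L / n_body_bins)
    bnd <- start + floor(b * L / n_body_bins)
    mean(v[(a + 1):bnd])
  }, numeric(1))
  down <- vapply(seq_len(n_flank), function(j) {
    a <- end + (j - 1) * flank_bin
    mean(v[(a + 1):(a + flank_bin)])
  }, numeric(1))
  c(up, body, down)
}

#' Select genes damaged by or near a cut site
#'
#' A gene is selected if a cut site falls inside it, or if the distance
#' between the site and the gene's nearest edge is strictly smaller than
#' `max_distance` (the "< 1 kb" rule). Uncut sites are ignored.
#'
#' @param genes Gene table with `chrom, start, end`.
#' @param sites Site table with `chrom, position, cut`.
#' @param max_distance Distance threshold in bp (strict inequality).
#' @return The selected subset of `genes`.
#' @export
genes_near_dsb <- function(genes, sites, max_distance = 1000) {
  cut <- sites[sites$cut %in% TRUE, , drop = FALSE]
  if (nrow(cut) == 0 || nrow(genes) == 0) {
    return(genes[integer(0), , drop = FALSE])
  }
  sel <- vapply(seq_len(nrow(genes)), function(i) {
    s <- cut[cut$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(s) == 0) return(FALSE)
    d <- ifelse(s$position < genes$start[i],
                genes$start[i] - s$position,
                ifelse(s$position >= genes$end[i],
                       s$position - genes$end[i] + 1, 0))
    any(d < max_distance)
  }, logical(1))
  genes[sel, , drop = FALSE]
}
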