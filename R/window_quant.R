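#' Windowed signal statistic around a genomic position
#'
#' Computes the sum or mean of per-base coverage over the 0-based half-open
#' window `[center - halfwidth, center + halfwidth)`, truncated at
#' chromosome ends. The mean uses the truncated width as denominator. A
#' window lying entirely off the chromosome is an error.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name.
#' @param center Window center, 0-based bp.
#' @param halfwidth Window half-width in bp (> 0).
#' @param statistic `"sum"` or `"mean"`.
#' @return A single number.
#' @examples
#' tr <- coverage_track(list(chr1 = rep(1, 100)), library_size = 1e6)
#' window_count(tr, "chr1", 50, 10)        # 20
#' window_count(tr, "chr1", 5, 10)         # truncated to [0, 15): 15
#' @export
window_count <- function(track, chrom, center, halfwidth,
                         statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  L <- track_length(track, chrom)
  a <- max(center - halfwidth, 0)
  b <- min(center + halfwidth, L)
  if (a >= b) {
    stop("window [", center - halfwidth, ", ", center + halfwidth,
         ") lies entirely outside ", chrom, " (length ", L, ")")
  }
  s <- sum(track$values[[chrom]][(a + 1):b])
  if (statistic == "sum") s else s / (b - a)
}

#' Windowed quantification over a site table
#'
#' Applies [window_count()] to every site, carrying the cut flag and
#' cleavage efficiency through, and producing one signal column per track.
#'
#' @param track A [coverage_track()], or a named list of them (one signal
#'   column per element).
#' @param sites Site table: data.frame with columns `site_id, chrom,
#'   position` and optionally `cut`, `efficiency` (as produced by
#'   [simulate_genome()] or read from a sites BED via [sites_from_bed()]).
#' @param halfwidth Window half-width in bp.
#' @param statistic `"sum"` or `"mean"`.
#' @return A `site_quant` data.frame: one row per site, signal columns
#'   named after the tracks (or `signal` for a single track), with
#'   attributes `halfwidth` and `statistic`.
#' @export
quantify_sites <- function(track, sites, halfwidth,
                           statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(sites) || nrow(sites) == 0) {
    stop("sites must be a non-empty data.frame")
  }
  req <- c("site_id", "chrom", "position")
  if (!all(req %in% names(sites))) {
    stop("sites need columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site ids: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "))
  }
  tracks <- if (inherits(track, "coverage_track")) {
    list(signal = track)
  } else {
    stopifnot(is.list(track), !is.null(names(track)))
    track
  }
  out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    position = sites$position, stringsAsFactors = FALSE)
  out$cut <- if ("cut" %in% names(sites)) sites$cut else NA
  out$efficiency <- if ("efficiency" %in% names(sites)) sites$efficiency
                    else NA_real_
  for (nm in names(tracks)) {
    out[[nm]] <- vapply(seq_len(nrow(sites)), function(i) {
      tryCatch(
        window_count(tracks[[nm]], sites$chrom[i], sites$position[i],
                     halfwidth, statistic),
        error = function(e) {
          stop("site ", sites$site_id[i], ": ", conditionMessage(e),
               call. = FALSE)
        }
      )
    }, numeric(1))
  }
  attr(out, "halfwidth") <- halfwidth
  attr(out, "statistic") <- statistic
  class(out) <- c("site_quant", "data.frame")
  out
}

#' Convert a sites BED interval table into a site table
#'
#' Interprets each BED record as a recognition interval: the site position
#' is the interval midpoint rounded down, the name column is the site id,
#' and a positive score (cleavage efficiency x 1000, as written by
#' [write_genome()]) marks the site as cut.
#'
#' @param bed Interval data.frame from [read_bed()].
#' @return A site table data.frame.
#' @export
sites_from_bed <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  score <- if ("score" %in% names(bed)) ifelse(is.na(bed$score), 0,
                                               bed$score) else 0
  data.frame(
    site_id = if ("name" %in% names(bed)) bed$name
              else sprintf("site_%04d", seq_len(nrow(bed))),
    chrom = bed$chrom,
    position = floor((bed$start + bed$end) / 2),
    cut = score > 0,
    efficiency = score / 1000,
    stringsAsFactors = FALSE
  )
}

#' Convert a genes BED table into the gene table used by profiles
#'
#' @param bed Interval data.frame from [read_bed()]; an optional seventh
#'   column read separately can supply expression, otherwise the score
#'   column is used.
#' @return A gene table with `chrom, start, end, name, expression, strand`.
#' @export
genes_from_bed <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    name = if ("name" %in% names(bed)) bed$name
           else sprintf("gene_%04d", seq_len(nrow(bed))),
    expression = if ("score" %in% names(bed)) {
      ifelse(is.na(bed$score), 0, bed$score)
    } else 0,
    strand = if ("strand" %in% names(bed)) bed$strand else ".",
    stringsAsFactors = FALSE
  )
}
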