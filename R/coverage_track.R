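#' Base-resolution coverage track
#'
#' Container for per-chromosome signal vectors at base resolution, with the
#' library size used for read-depth normalization. Coordinates are 0-based:
#' the value at base `b` of chromosome `ch` is `values[[ch]][b + 1]`.
#'
#' @param values Named list of nonnegative numeric vectors, one per
#'   chromosome.
#' @param library_size Total read count for the sample. When `NULL`, the
#'   total signal of the track is used, with a warning (useful when no
#'   sidecar metadata is available).
#' @param label Free-text label (typically assay + condition).
#' @return An object of class `coverage_track`.
#' @examples
#' tr <- coverage_track(list(chr1 = c(0, 1, 2, 1)), library_size = 1e6)
#' track_length(tr, "chr1")
#' @export
coverage_track <- function(values, library_size = NULL, label = "") {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  for (ch in names(values)) {
    v <- values[[ch]]
    if (!is.numeric(v)) stop("values for ", ch, " must be numeric")
    if (any(v < 0)) stop("coverage values must be >= 0 (chromosome ", ch, ")")
    storage.mode(values[[ch]]) <- "double"
  }
  if (is.null(library_size)) {
    library_size <- sum(vapply(values, sum, numeric(1)))
    warning("library_size not supplied; defaulting to total track signal (",
            format(library_size), ")")
  }
  if (!is.finite(library_size) || library_size <= 0) {
    stop("library_size must be a positive finite number")
  }
  structure(list(values = values, library_size = as.numeric(library_size),
                 label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", if (nzchar(x$label)) paste0(" '", x$label, "'"),
      "\n", sep = "")
  for (ch in names(x$values)) {
    cat(sprintf("  %s: %s bp, total signal %.4g\n", ch,
                format(length(x$values[[ch]]), big.mark = ","),
                sum(x$values[[ch]])))
  }
  cat(sprintf("  library_size: %.6g\n", x$library_size))
  invisible(x)
}

#' @rdname coverage_track
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @export
track_length <- function(track, chrom) {
  stopifnot(inherits(track, "coverage_track"))
  if (!chrom %in% names(track$values)) {
    stop("unknown chromosome '", chrom, "' in track '", track$label, "'")
  }
  length(track$values[[chrom]])
}

#' Library-size normalization of a coverage track
#'
#' Rescales every value by `1e6 / library_size` (signal per million reads),
#' the standard total-read-count normalization. The output's library size is
#' set to 1e6 so that normalization is idempotent.
#'
#' @param track A [coverage_track()].
#' @param scale Normalization scheme; only `"per_million"` is defined.
#' @return A normalized `coverage_track`.
#' @examples
#' tr <- coverage_track(list(chr1 = c(10, 0)), library_size = 2e6)
#' normalize_track(tr)$values$chr1   # 5, 0
#' @export
normalize_track <- function(track, scale = "per_million") {
  stopifnot(inherits(track, "coverage_track"))
  scale <- match.arg(scale, "per_million")
  if (!is.finite(track$library_size) || track$library_size <= 0) {
    stop("library_size must be positive to normalize")
  }
  f <- 1e6 / track$library_size
  track$values <- lapply(track$values, function(v) v * f)
  track$library_size <- 1e6
  track
}
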