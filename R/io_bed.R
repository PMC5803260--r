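#' Read a BED file into an interval table
#'
#' Parses BED3/BED6(+) into a data.frame of 0-based half-open intervals with
#' columns `chrom, start, end, name, score, strand` (missing optional
#' columns filled with `"."`/`NA`/`"."`). Records are validated one by one;
#' a violation (start >= end, negative coordinate, or a chromosome absent
#' from `genome` when one is attached) raises an error naming the offending
#' line.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @param genome Optional named vector of chromosome lengths for coordinate
#'   validation (exact chromosome-name matching, no "chr" aliasing).
#' @return A data.frame of intervals.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tx\t0\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  bad <- which(ncol < 3)
  if (length(bad) > 0) {
    stop("line ", idx[bad[1]], ": BED records need >= 3 columns")
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default,
           character(1))
  }
  chrom <- get(1, "")
  start <- suppressWarnings(as.numeric(get(2, "")))
  end <- suppressWarnings(as.numeric(get(3, "")))
  name <- get(4, ".")
  score <- suppressWarnings(as.numeric(get(5, NA_character_)))
  strand <- get(6, ".")

  for (i in seq_along(idx)) {
    line <- idx[i]
    if (is.na(start[i]) || is.na(end[i])) {
      stop("line ", line, ": non-numeric coordinates")
    }
    if (start[i] < 0) stop("line ", line, ": negative start coordinate")
    if (start[i] >= end[i]) {
      stop("line ", line, ": start (", start[i],
           ") must be < end (", end[i], ")")
    }
    if (!strand[i] %in% c("+", "-", ".")) {
      stop("line ", line, ": invalid strand '", strand[i], "'")
    }
    if (!is.null(genome)) {
      if (!chrom[i] %in% names(genome)) {
        stop("line ", line, ": unknown chromosome '", chrom[i], "'")
      }
      if (end[i] > genome[[chrom[i]]]) {
        stop("line ", line, ": interval end ", end[i],
             " exceeds length of ", chrom[i], " (", genome[[chrom[i]]], ")")
      }
    }
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = strand, stringsAsFactors = FALSE)
}

#' Write an interval table as BED
#'
#' Emits sorted BED6 (or BED3 when name/score/strand are absent). The
#' round-trip `read_bed(write_bed(x))` is the identity on canonical
#' interval tables.
#'
#' @param intervals Data.frame with at least `chrom, start, end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals))) {
    stop("intervals need columns chrom, start, end")
  }
  x <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                 drop = FALSE]
  has6 <- all(c("name", "score", "strand") %in% names(x))
  df <- if (has6 && nrow(x) > 0) {
    score <- ifelse(is.na(x$score), "0", formatC(x$score, format = "g",
                                                 digits = 17))
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
               x$name, score, x$strand)
  } else {
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a chromosome-sizes file (UCSC chrom.sizes dialect)
#'
#' @param path Two-column tab-separated text: chromosome name, length.
#' @return `read_chrom_sizes`: a named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome names")
  setNames(df$length, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0))
  ord <- order(names(sizes))
  write.table(data.frame(names(sizes)[ord], format_coord(sizes[ord])),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
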