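#' Read a bedGraph file into a coverage track
#'
#' Expands a bedGraph (0-based, half-open intervals with a value column)
#' into base-resolution vectors over the chromosomes of `genome`. Records
#' may arrive unsorted; bases not covered by any record get value 0.
#' Overlapping records are rejected with an error naming the first
#' conflicting position and the two values involved.
#'
#' @param path Path to a bedGraph file.
#' @param genome Named numeric vector of chromosome lengths (the full
#'   chromosome set of the track).
#' @param library_size Library size for the track; when `NULL` the total
#'   signal is used, with a warning.
#' @param label Track label.
#' @return A [coverage_track()].
#' @examples
#' f <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t10\t2.5", f)
#' tr <- read_bedgraph(f, c(chr1 = 20), library_size = 1e6)
#' tr$values$chr1[10:11]   # 2.5 then 0
#' @export
read_bedgraph <- function(path, genome, library_size = NULL, label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(!is.null(names(genome)), all(genome > 0))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  vals <- lapply(genome, function(L) numeric(L))
  idx <- which(keep)
  if (length(idx) > 0) {
    df <- read.table(text = lines[idx], sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "value"),
                     colClasses = c("character", "numeric", "numeric",
                                    "numeric"))
    for (i in seq_len(nrow(df))) {
      line <- idx[i]
      ch <- df$chrom[i]
      if (!ch %in% names(genome)) {
        stop("line ", line, ": unknown chromosome '", ch, "'")
      }
      if (df$start[i] < 0 || df$start[i] >= df$end[i] ||
          df$end[i] > genome[[ch]]) {
        stop("line ", line, ": invalid interval [", df$start[i], ", ",
             df$end[i], ") on ", ch)
      }
      if (df$value[i] < 0) {
        stop("line ", line, ": negative coverage value ", df$value[i])
      }
    }
    # overlap detection per chromosome after sorting
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1) {
        ov <- which(d$start[-1] < d$end[-nrow(d)])
        if (length(ov) > 0) {
          k <- ov[1]
          stop("overlapping bedGraph records on ", ch, " at base ",
               format_coord(d$start[k + 1]), ": values ", d$value[k],
               " and ", d$value[k + 1])
        }
      }
      for (i in seq_len(nrow(d))) {
        vals[[ch]][(d$start[i] + 1):d$end[i]] <- d$value[i]
      }
    }
  }
  coverage_track(vals, library_size = library_size, label = label)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes each chromosome and writes one record per constant
#' run, omitting zero runs (which read back as 0). Values are printed with
#' full precision so that `read_bedgraph(write_bedgraph(x))` preserves
#' every per-base value exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in sort(names(track$values))) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (!any(nz)) next
    writeLines(paste(ch, format_coord(starts[nz]), format_coord(ends[nz]),
                     formatC(r$values[nz], format = "g", digits = 17),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read or write a qPCR cycle-threshold table
#'
#' The schema is tab-delimited text with a header line and columns
#' `sample, target, condition, replicate, ct`. Cts must be finite and
#' positive; the key `(sample, target, condition, replicate)` must be
#' unique.
#'
#' @param path Path to the table.
#' @return `read_ct_table`: a validated data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  validate_ct_table(df)
}

#' @rdname read_ct_table
#' @param ct A Ct table data.frame.
#' @export
write_ct_table <- function(ct, path) {
  ct <- validate_ct_table(ct)
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_ct_table <- function(df) {
  req <- c("sample", "target", "condition", "replicate", "ct")
  if (!all(req %in% names(df))) {
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  key <- paste(df$sample, df$target, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (sample, target, condition, replicate) records")
  }
  df[req]
}
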