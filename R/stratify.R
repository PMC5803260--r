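#' Stratify sites into transcription-level classes
#'
#' Orders sites by a transcription score (e.g. RNA PolII window signal) and
#' splits them into `n_classes` contiguous groups of near-equal size,
#' labeled from low to high. When the site count is not divisible by
#' `n_classes`, the extra sites go to the lowest classes (80 sites in 4
#' classes gives exactly 20 per class; 81 gives 21, 20, 20, 20). Score ties
#' are broken by site id, so the partition is deterministic.
#'
#' @param quants A `site_quant` table (or any data.frame with `site_id`).
#' @param score_column Name of the numeric score column to order by.
#' @param n_classes Number of classes (>= 2).
#' @param labels Optional class labels, low to high; defaults to
#'   `low, medium_low, medium_high, high` for 4 classes, `class_1..k`
#'   otherwise.
#' @return The input with an added ordered factor column
#'   `transcription_class`.
#' @examples
#' q <- data.frame(site_id = sprintf("s%02d", 1:8), score = 8:1)
#' table(stratify_by_transcription(q, "score")$transcription_class)
#' @export
stratify_by_transcription <- function(quants, score_column,
                                      n_classes = 4L, labels = NULL) {
  if (!score_column %in% names(quants)) {
    stop("no column '", score_column, "'")
  }
  score <- quants[[score_column]]
  if (!is.numeric(score)) stop("score column must be numeric")
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  n <- nrow(quants)
  if (n < n_classes) {
    stop("need at least n_classes (", n_classes, ") sites, got ", n)
  }
  if (is.null(labels)) {
    labels <- if (n_classes == 4L) {
      c("low", "medium_low", "medium_high", "high")
    } else {
      sprintf("class_%d", seq_len(n_classes))
    }
  }
  stopifnot(length(labels) == n_classes)
  ord <- order(score, quants$site_id)
  sizes <- split_count(n, n_classes)  # remainder goes to the lowest classes
  cls <- rep(labels, times = sizes)
  out <- quants
  out$transcription_class <- factor(NA, levels = labels, ordered = TRUE)
  out$transcription_class[ord] <- cls
  out
}
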