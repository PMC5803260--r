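#' Simulate qPCR cycle thresholds from true template quantities
#'
#' Uses the standard amplification model `Ct = reference_ct -
#' log(quantity) / log(efficiency) + noise`: with perfect efficiency (2,
#' i.e. doubling per cycle) and no noise, doubling the template lowers the
#' Ct by exactly one cycle.
#'
#' @param quantities Positive numeric vector of true template quantities
#'   (relative units; quantity 1 amplifies at `reference_ct`).
#' @param reference_ct Ct of a unit quantity, in cycles.
#' @param efficiency Fold amplification per cycle, in `(1, 2]`.
#' @param noise_sd Gaussian noise on the Ct, in cycles.
#' @param seed Optional integer seed for the noise draws.
#' @param sample,target,condition,replicate Label columns recycled across
#'   wells, forming the Ct-table schema.
#' @return A data.frame in the Ct-table schema
#'   (`sample, target, condition, replicate, ct`).
#' @examples
#' simulate_qpcr(c(1, 2), noise_sd = 0)$ct   # second Ct is 1 cycle lower
#' @export
simulate_qpcr <- function(quantities, reference_ct = 30, efficiency = 2,
                          noise_sd = 0, seed = NULL,
                          sample = "S", target = "T", condition = "cond",
                          replicate = seq_along(quantities)) {
  if (any(!is.finite(quantities)) || any(quantities <= 0)) {
    stop("quantities must be positive (Ct undefined for zero template)")
  }
  if (efficiency <= 1 || efficiency > 2) {
    stop("efficiency must lie in (1, 2] (fold amplification per cycle)")
  }
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  n <- length(quantities)
  ct <- reference_ct - log(quantities) / log(efficiency)
  if (noise_sd > 0) ct <- ct + rnorm(n, 0, noise_sd)
  data.frame(sample = rep_len(as.character(sample), n),
             target = rep_len(as.character(target), n),
             condition = rep_len(as.character(condition), n),
             replicate = rep_len(replicate, n),
             ct = ct, stringsAsFactors = FALSE)
}

#' Simulate a resection-assay qPCR measurement
#'
#' Produces the (digested, undigested) Ct pair that a restriction-digest
#' resection assay would yield for a locus where a fraction
#' `true_ssdna_fraction` of molecules is single-stranded (and therefore
#' digestion-resistant). The pair is constructed by inverting the assay's
#' quantification equation, so at zero noise feeding it back through
#' [ssdna_percent()] recovers `100 * true_ssdna_fraction` exactly:
#' `Ct_digested - Ct_undigested = 1 + log2(1/fraction - 1/2)`.
#'
#' @param true_ssdna_fraction Fraction of single-stranded molecules, in
#'   `(0, 1]`.
#' @param noise_sd Gaussian Ct noise in cycles, added independently to both
#'   wells.
#' @param base_ct Ct of the undigested well before noise.
#' @param seed Optional integer seed.
#' @return A one-row data.frame with `ct_digested`, `ct_undigested` and
#'   `true_fraction`.
#' @examples
#' m <- simulate_resection_experiment(2 / 3)
#' m$ct_digested - m$ct_undigested   # exactly 1 cycle
#' @export
simulate_resection_experiment <- function(true_ssdna_fraction,
                                          noise_sd = 0, base_ct = 25,
                                          seed = NULL) {
  f <- true_ssdna_fraction
  if (length(f) != 1 || !is.finite(f) || f <= 0 || f > 1) {
    stop("true_ssdna_fraction must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  dct <- 1 + log2(1 / f - 0.5)
  noise <- if (noise_sd > 0) rnorm(2, 0, noise_sd) else c(0, 0)
  data.frame(ct_digested = base_ct + dct + noise[1],
             ct_undigested = base_ct + noise[2],
             true_fraction = f)
}
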