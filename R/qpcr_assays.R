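#' Percent single-stranded DNA from a restriction-digest qPCR pair
#'
#' Quantifies resection from the differential qPCR of restriction-digested
#' versus undigested genomic DNA:
#' `ssDNA% = 1 / (2^(Ct_digested - Ct_undigested - 1) + 0.5) * 100`.
#' Double-stranded molecules are cut and lost from the digested well, so
#' the Ct difference grows as the single-stranded fraction shrinks; the
#' formula is strictly decreasing in the Ct difference. The raw value
#' ranges over (0, 200) (it exceeds 100 when the digested well amplifies
#' *earlier* than the undigested one); values are clamped to `[0, 100]` by
#' default, with `clamp = FALSE` returning the raw value.
#'
#' @param ct_digested,ct_undigested Cycle thresholds (finite numerics,
#'   vectorized).
#' @param clamp Clamp the result to `[0, 100]`?
#' @return Percent single-stranded DNA.
#' @examples
#' ssdna_percent(25, 25)   # delta Ct 0 -> 100
#' ssdna_percent(26, 25)   # delta Ct 1 -> 66.67
#' @export
ssdna_percent <- function(ct_digested, ct_undigested, clamp = TRUE) {
  if (any(!is.finite(ct_digested)) || any(!is.finite(ct_undigested))) {
    stop("Ct values must be finite")
  }
  dct <- ct_digested - ct_undigested
  raw <- 1 / (2^(dct - 1) + 0.5) * 100
  if (clamp) pmin(pmax(raw, 0), 100) else raw
}

#' Normalize a resection measurement to an undamaged control
#'
#' @param sample_pct ssDNA percent of the sample of interest.
#' @param control_pct ssDNA percent of the undamaged control (> 0).
#' @return Fold change `sample_pct / control_pct`.
#' @examples
#' resection_normalized(40, 20)   # 2
#' @export
resection_normalized <- function(sample_pct, control_pct) {
  if (any(!is.finite(control_pct)) || any(control_pct <= 0)) {
    stop("control ssDNA percent must be > 0")
  }
  sample_pct / control_pct
}

#' Percent of sites remaining broken (repair kinetics)
#'
#' Input-normalized pulldown signal at time `t` relative to the reference
#' time point (damage induction, before repair is allowed):
#' `s(t) = 2^(Ct_input_t - Ct_pulldown_t)` and the result is
#' `100 * s(t) / s(ref)`. By construction the reference time point reads
#' 100. Values above 100 (pulldown stronger than at reference) are
#' returned as-is so they can be flagged downstream.
#'
#' @param ct_pulldown_t,ct_input_t Cts of the pulldown and its input at
#'   time `t`.
#' @param ct_pulldown_ref,ct_input_ref Cts at the reference time point.
#' @return Percent of sites still broken.
#' @examples
#' percent_broken(21, 20, 20, 20)   # 50: one extra pulldown cycle
#' @export
percent_broken <- function(ct_pulldown_t, ct_input_t,
                           ct_pulldown_ref, ct_input_ref) {
  cts <- c(ct_pulldown_t, ct_input_t, ct_pulldown_ref, ct_input_ref)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  s_t <- 2^(ct_input_t - ct_pulldown_t)
  s_ref <- 2^(ct_input_ref - ct_pulldown_ref)
  100 * s_t / s_ref
}

#' Delta-delta-Ct relative frequency with two control amplicons
#'
#' Relative quantification of a junction (or any target amplicon) between
#' a condition and a reference condition, normalized to control regions:
#' the per-condition control Ct is the arithmetic mean of the control
#' amplicon Cts (equivalently the geometric mean of their quantities),
#' `dCt = Ct_target - mean(Ct_controls)` per condition, and the result is
#' `2^-(dCt_condition - dCt_reference)`. Equals 1 when condition and
#' reference coincide.
#'
#' @param ct_target Target Ct in the condition of interest.
#' @param ct_controls Numeric vector of control-amplicon Cts in the
#'   condition of interest (two controls in the standard design). Missing
#'   (`NA`) controls are an error naming the amplicon.
#' @param ct_target_ref,ct_controls_ref Same quantities in the reference
#'   condition.
#' @return Fold change relative to the reference condition.
#' @examples
#' ddct_frequency(24, c(20, 22), 25, c(20, 22))   # target 1 cycle lower: 2
#' @export
ddct_frequency <- function(ct_target, ct_controls,
                           ct_target_ref, ct_controls_ref) {
  check_controls <- function(x, what) {
    if (length(x) == 0) stop("no ", what, " control Cts supplied")
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      nm <- names(x)[bad[1]]
      stop("missing control amplicon ",
           if (!is.null(nm) && nzchar(nm)) paste0("'", nm, "' ") else "",
           "in ", what, " condition")
    }
  }
  check_controls(ct_controls, "target")
  check_controls(ct_controls_ref, "reference")
  if (!is.finite(ct_target) || !is.finite(ct_target_ref)) {
    stop("target Cts must be finite")
  }
  dct <- ct_target - mean(ct_controls)
  dct_ref <- ct_target_ref - mean(ct_controls_ref)
  2^(-(dct - dct_ref))
}

#' DRIP-qPCR percent input
#'
#' Immunoprecipitated signal expressed as percent of input, correcting for
#' the fraction of material reserved as input:
#' `100 * input_fraction * 2^(Ct_input - Ct_ip)`.
#'
#' @param ct_ip,ct_input Cts of the IP and input wells.
#' @param input_fraction Fraction of the sample used as input, in (0, 1).
#' @return Percent input.
#' @examples
#' drip_percent_input(25, 25, 0.1)   # 10
#' @export
drip_percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(!is.finite(c(ct_ip, ct_input)))) stop("Ct values must be finite")
  if (any(input_fraction <= 0) || any(input_fraction >= 1)) {
    stop("input_fraction must lie strictly in (0, 1)")
  }
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Summarize biological replicates of an assay value
#'
#' @param values Per-replicate assay values (n >= 1).
#' @param assay,target,condition Optional labels carried into the result.
#' @return An object of class `assay_result`: list with `values`, `n`,
#'   `mean`, `sem` (sample sd over sqrt(n); `NA` with
#'   `sem_undefined = TRUE` when n = 1) and the labels.
#' @examples
#' summarize_replicates(c(2, 4, 6))$sem   # 2/sqrt(3)
#' @export
summarize_replicates <- function(values, assay = NA_character_,
                                 target = NA_character_,
                                 condition = NA_character_) {
  if (length(values) == 0) stop("need at least one replicate value")
  n <- length(values)
  sem <- if (n == 1) NA_real_ else sd(values) / sqrt(n)
  structure(list(assay = assay, target = target, condition = condition,
                 values = values, n = n, mean = mean(values), sem = sem,
                 sem_undefined = n == 1),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  lab <- paste(na.omit(c(x$assay, x$target, x$condition)), collapse = " / ")
  cat(sprintf("assay result%s: mean %.4g, sem %s (n = %d)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              x$mean,
              if (x$sem_undefined) "undefined (single replicate)"
              else sprintf("%.4g", x$sem),
              x$n))
  invisible(x)
}

#' @export
as.data.frame.assay_result <- function(x, ...) {
  data.frame(assay = x$assay, target = x$target, condition = x$condition,
             n = x$n, mean = x$mean, sem = x$sem,
             stringsAsFactors = FALSE)
}
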