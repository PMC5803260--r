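#' Assay quantification over a Ct table
#'
#' Table-level drivers for the qPCR assays, operating on the tab-delimited
#' Ct schema (`sample, target, condition, replicate, ct`; see
#' [read_ct_table()]). Each assay is computed per biological replicate
#' first, then replicates are aggregated with [summarize_replicates()]
#' (mean and s.e.m. of per-replicate values, never of pooled Cts).
#'
#' * `assay_resection`: expects `sample` in `digested` / `undigested`;
#'   computes [ssdna_percent()] per (target, condition, replicate) and
#'   normalizes each value to the mean ssDNA% of `control_condition`
#'   for the same target.
#' * `assay_repair`: expects `sample` in `pulldown` / `input`; computes
#'   [percent_broken()] per (target, condition, replicate) against the
#'   matching replicate of `reference_condition`.
#' * `assay_translocation`: computes [ddct_frequency()] of `target`
#'   against the two `control_targets`, per replicate, relative to
#'   `reference_condition`.
#' * `assay_drip`: expects `sample` in `ip` / `input`; computes
#'   [drip_percent_input()] per (target, condition, replicate).
#'
#' @param ct Ct table data.frame.
#' @param control_condition,reference_condition Condition label used as
#'   the normalization reference.
#' @param target Target amplicon (translocation junction) label.
#' @param control_targets Character vector of the two control amplicons.
#' @param input_fraction Input fraction for the DRIP assay.
#' @return A data.frame with one row per (target, condition): `assay`,
#'   `target`, `condition`, `n`, `mean`, `sem`.
#' @name assay_tables
NULL

ct_lookup <- function(ct, sample, target, condition, replicate) {
  v <- ct$ct[ct$sample == sample & ct$target == target &
               ct$condition == condition & ct$replicate == replicate]
  if (length(v) != 1) {
    stop("expected exactly one Ct for (", sample, ", ", target, ", ",
         condition, ", ", replicate, "), found ", length(v))
  }
  v
}

assay_grid <- function(ct) {
  unique(ct[c("target", "condition")])
}

bind_results <- function(results) {
  do.call(rbind, lapply(results, as.data.frame))
}

#' @rdname assay_tables
#' @export
assay_resection <- function(ct, control_condition) {
  ct <- validate_ct_table(ct)
  pct <- function(target, condition) {
    reps <- unique(ct$replicate[ct$target == target &
                                  ct$condition == condition])
    vapply(reps, function(r) {
      ssdna_percent(ct_lookup(ct, "digested", target, condition, r),
                    ct_lookup(ct, "undigested", target, condition, r))
    }, numeric(1))
  }
  grid <- assay_grid(ct)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ctrl <- mean(pct(grid$target[i], control_condition))
    vals <- resection_normalized(pct(grid$target[i], grid$condition[i]),
                                 ctrl)
    summarize_replicates(vals, assay = "resection",
                         target = grid$target[i],
                         condition = grid$condition[i])
  })
  bind_results(res)
}

#' @rdname assay_tables
#' @export
assay_repair <- function(ct, reference_condition) {
  ct <- validate_ct_table(ct)
  grid <- assay_grid(ct)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tg <- grid$target[i]; cond <- grid$condition[i]
    reps <- unique(ct$replicate[ct$target == tg & ct$condition == cond])
    vals <- vapply(reps, function(r) {
      percent_broken(
        ct_lookup(ct, "pulldown", tg, cond, r),
        ct_lookup(ct, "input", tg, cond, r),
        ct_lookup(ct, "pulldown", tg, reference_condition, r),
        ct_lookup(ct, "input", tg, reference_condition, r)
      )
    }, numeric(1))
    summarize_replicates(vals, assay = "repair", target = tg,
                         condition = cond)
  })
  out <- bind_results(res)
  if (any(out$mean > 100 + 1e-9)) {
    message("repair assay: ", sum(out$mean > 100 + 1e-9),
            " condition(s) read above 100% broken")
  }
  out
}

#' @rdname assay_tables
#' @export
assay_translocation <- function(ct, target, control_targets,
                                reference_condition) {
  ct <- validate_ct_table(ct)
  if (length(control_targets) != 2) {
    stop("two control amplicons are required")
  }
  conds <- unique(ct$condition[ct$target == target])
  ctrl_cts <- function(condition, replicate) {
    setNames(vapply(control_targets, function(tg) {
      ct_lookup(ct, unique(ct$sample)[1], tg, condition, replicate)
    }, numeric(1)), control_targets)
  }
  res <- lapply(conds, function(cond) {
    reps <- unique(ct$replicate[ct$target == target &
                                  ct$condition == cond])
    vals <- vapply(reps, function(r) {
      ddct_frequency(
        ct_lookup(ct, unique(ct$sample)[1], target, cond, r),
        ctrl_cts(cond, r),
        ct_lookup(ct, unique(ct$sample)[1], target, reference_condition,
                  r),
        ctrl_cts(reference_condition, r)
      )
    }, numeric(1))
    summarize_replicates(vals, assay = "translocation", target = target,
                         condition = cond)
  })
  bind_results(res)
}

#' @rdname assay_tables
#' @export
assay_drip <- function(ct, input_fraction) {
  ct <- validate_ct_table(ct)
  grid <- assay_grid(ct)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tg <- grid$target[i]; cond <- grid$condition[i]
    reps <- unique(ct$replicate[ct$target == tg & ct$condition == cond])
    vals <- vapply(reps, function(r) {
      drip_percent_input(ct_lookup(ct, "ip", tg, cond, r),
                         ct_lookup(ct, "input", tg, cond, r),
                         input_fraction)
    }, numeric(1))
    summarize_replicates(vals, assay = "drip", target = tg,
                         condition = cond)
  })
  bind_results(res)
}
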