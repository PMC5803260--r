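#' Simulate a ChIP-seq-like coverage track
#'
#' Builds the deterministic mean signal implied by the genome model and the
#' assay, then applies the configured noise model:
#'
#' * `senataxin`, damaged condition: a boxcar peak of half-width
#'   `enrichment_halfwidth` at every cut site lying in an expressed gene,
#'   with height `enrichment_amplitude * efficiency * expression /
#'   ref_expression` on top of the background. Intergenic or silent cut
#'   sites get no peak (recruitment requires local transcription).
#' * `senataxin`, undamaged: background only.
#' * `polII_total` / `polII_S2P`: gene-body signal `polII_scale *
#'   expression`, independent of condition (transcription state precedes
#'   damage).
#' * `generic`: background only.
#'
#' Noise is Poisson per base (counts with the mean signal as rate),
#' Gaussian (truncated at 0), or absent. The library size recorded is the
#' total signal of the track.
#'
#' @param genome A [simulate_genome()] result.
#' @param assay One of `"senataxin"`, `"polII_total"`, `"polII_S2P"`,
#'   `"generic"`.
#' @param condition `"undamaged"` (-4OHT) or `"damaged"` (+4OHT).
#' @param seed Integer seed for the noise draws; defaults to a stream
#'   derived from the genome's master seed and the assay/condition labels.
#' @return A [coverage_track()].
#' @examples
#' gm <- simulate_genome(sim_config(seed = 1, chrom_length = 2e5,
#'                                  n_genes = 6, n_sites = 12, n_cut = 4))
#' tr <- simulate_chip_coverage(gm, "senataxin", "damaged")
#' @export
simulate_chip_coverage <- function(genome,
                                   assay = c("senataxin", "polII_total",
                                             "polII_S2P", "generic"),
                                   condition = c("undamaged", "damaged"),
                                   seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  assay <- match.arg(assay)
  condition <- match.arg(condition)
  cfg <- genome$config
  if (is.null(seed)) {
    seed <- stage_seed(cfg$seed, paste("coverage", assay, condition,
                                       sep = "/"))
  }
  means <- lapply(names(genome$chrom_sizes), function(ch) {
    L <- genome$chrom_sizes[[ch]]
    m <- rep(cfg$background_rate, L)
    if (assay %in% c("polII_total", "polII_S2P")) {
      g <- genome$genes[genome$genes$chrom == ch &
                          genome$genes$expression > 0, , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        m <- add_boxcar(m, g$start[i], g$end[i],
                        cfg$polII_scale * g$expression[i])
      }
    }
    if (assay == "senataxin" && condition == "damaged") {
      s <- genome$sites[genome$sites$chrom == ch & genome$sites$cut &
                          genome$sites$host_expression > 0, , drop = FALSE]
      for (i in seq_len(nrow(s))) {
        amp <- cfg$enrichment_amplitude * s$efficiency[i] *
          s$host_expression[i] / genome$ref_expression
        m <- add_boxcar(m, s$position[i] - cfg$enrichment_halfwidth,
                        s$position[i] + cfg$enrichment_halfwidth, amp)
      }
    }
    m
  })
  names(means) <- names(genome$chrom_sizes)
  finish_track(means, cfg, seed, label = paste(assay, condition, sep = "_"))
}

#' Simulate a DRIP-seq-like coverage track
#'
#' The undamaged mean signal carries, on every expressed gene, a gene-body
#' level proportional to expression with stronger boxcar peaks at the TSS
#' and TTS (R-loop hotspots of active transcription units). In the damaged
#' condition each cut site additionally receives, in order:
#'
#' 1. damping of the host gene's body contribution by `body_damping`
#'    (transcriptional shutdown of the broken gene),
#' 2. a multiplicative gain `drip_gain` over `±dsb_gain_halfwidth`
#'    (hybrid accumulation on break-flanking chromatin); silent or
#'    intergenic cut sites receive it only if flagged `drip_responsive`,
#'    and then scaled down by `silent_gain_scale`,
#' 3. for cut sites in expressed genes, a central multiplicative depletion
#'    `1 - senataxin_activity * depletion_strength` over
#'    `±depletion_halfwidth` (helicase-mediated hybrid removal at the
#'    break; vanishes when `senataxin_activity = 0`, emulating knockdown).
#'
#' @inheritParams simulate_chip_coverage
#' @param senataxin_activity Overrides `config$senataxin_activity` when not
#'   `NULL`.
#' @return A [coverage_track()].
#' @export
simulate_drip_coverage <- function(genome,
                                   condition = c("undamaged", "damaged"),
                                   senataxin_activity = NULL,
                                   seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  condition <- match.arg(condition)
  cfg <- genome$config
  activity <- if (is.null(senataxin_activity)) cfg$senataxin_activity
              else senataxin_activity
  if (is.null(seed)) {
    seed <- stage_seed(cfg$seed, paste("drip", condition, activity,
                                       sep = "/"))
  }
  damaged_genes <- unique(genome$sites$host_gene[genome$sites$cut])
  means <- lapply(names(genome$chrom_sizes), function(ch) {
    L <- genome$chrom_sizes[[ch]]
    m <- rep(cfg$background_rate, L)
    g <- genome$genes[genome$genes$chrom == ch &
                        genome$genes$expression > 0, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      body <- cfg$drip_body_scale * g$expression[i]
      if (condition == "damaged" && g$name[i] %in% damaged_genes) {
        body <- body * cfg$body_damping
      }
      m <- add_boxcar(m, g$start[i], g$end[i], body)
      tss <- if (g$strand[i] == "+") g$start[i] else g$end[i] - 1
      tts <- if (g$strand[i] == "+") g$end[i] - 1 else g$start[i]
      m <- add_boxcar(m, tss - cfg$tss_peak_halfwidth,
                      tss + cfg$tss_peak_halfwidth, 2 * body)
      m <- add_boxcar(m, tts - cfg$tss_peak_halfwidth,
                      tts + cfg$tss_peak_halfwidth, 2 * body)
    }
    if (condition == "damaged") {
      s <- genome$sites[genome$sites$chrom == ch & genome$sites$cut, ,
                        drop = FALSE]
      for (i in seq_len(nrow(s))) {
        expressed <- s$host_expression[i] > 0
        gain <- if (expressed) cfg$drip_gain
                else if (s$drip_responsive[i])
                  1 + (cfg$drip_gain - 1) * cfg$silent_gain_scale
                else 1
        m <- mul_boxcar(m, s$position[i] - cfg$dsb_gain_halfwidth,
                        s$position[i] + cfg$dsb_gain_halfwidth, gain)
        if (expressed) {
          dip <- max(0, 1 - activity * cfg$depletion_strength)
          m <- mul_boxcar(m, s$position[i] - cfg$depletion_halfwidth,
                          s$position[i] + cfg$depletion_halfwidth, dip)
        }
      }
    }
    m
  })
  names(means) <- names(genome$chrom_sizes)
  finish_track(means, cfg, seed, label = paste0("drip_", condition))
}

# additive / multiplicative boxcar over the 0-based half-open [a, b),
# truncated at chromosome ends
add_boxcar <- function(m, a, b, height) {
  a <- max(a, 0); b <- min(b, length(m))
  if (a < b) m[(a + 1):b] <- m[(a + 1):b] + height
  m
}

mul_boxcar <- function(m, a, b, factor) {
  a <- max(a, 0); b <- min(b, length(m))
  if (a < b) m[(a + 1):b] <- m[(a + 1):b] * factor
  m
}

finish_track <- function(means, cfg, seed, label) {
  set.seed(seed, kind = "Mersenne-Twister")
  vals <- lapply(means, function(m) {
    switch(cfg$noise_model,
           poisson = as.numeric(rpois(length(m), m)),
           gaussian = pmax(0, m + rnorm(length(m), 0, cfg$gaussian_sd)),
           none = m)
  })
  total <- sum(vapply(vals, sum, numeric(1)))
  # an all-zero track (e.g. zero background, no noise) keeps a unit library
  # size so that normalization stays defined
  coverage_track(vals, library_size = if (total > 0) total else 1,
                 label = label)
}
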