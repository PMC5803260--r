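# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package implementation: per-base loops and
# explicit bin assignment, so agreement is meaningful.

ctrack <- function(v, chrom = "chr1", lib = 1e6, label = "") {
  coverage_track(setNames(list(as.numeric(v)), chrom),
                 library_size = lib, label = label)
}

rand_track_values <- function(len) {
  round(runif(len, 0, 10), 3)
}

# per-base window statistic by explicit loop
oracle_window <- function(v, center, halfwidth, statistic = "sum") {
  total <- 0
  n <- 0
  for (b in seq(center - halfwidth, center + halfwidth - 1)) {
    if (b >= 0 && b < length(v)) {
      total <- total + v[b + 1]
      n <- n + 1
    }
  }
  if (statistic == "sum") total else total / n
}

# per-site bin means with zero-padding outside the chromosome
oracle_heatmap_row <- function(v, center, halfwidth, bin_width) {
  n_bins <- 2 * halfwidth / bin_width
  sapply(seq_len(n_bins), function(j) {
    s <- 0
    for (b in seq(center - halfwidth + (j - 1) * bin_width,
                  center - halfwidth + j * bin_width - 1)) {
      if (b >= 0 && b < length(v)) s <- s + v[b + 1]
    }
    s / bin_width
  })
}

# metagene bins for one gene via explicit base-to-bin assignment
oracle_metagene_gene <- function(v, start, end, strand, flank, flank_bin,
                                 n_body_bins) {
  n_flank <- flank / flank_bin
  up <- sapply(seq_len(n_flank), function(j) {
    bases <- seq(start - flank + (j - 1) * flank_bin,
                 length.out = flank_bin)
    mean(v[bases + 1])
  })
  L <- end - start
  bounds <- floor((0:n_body_bins) * L / n_body_bins)
  gene_bases <- seq(start, end - 1)
  bin_of <- findInterval(gene_bases - start, bounds,
                         rightmost.closed = FALSE)
  body <- as.numeric(tapply(v[gene_bases + 1], bin_of, mean))
  down <- sapply(seq_len(n_flank), function(j) {
    bases <- seq(end + (j - 1) * flank_bin, length.out = flank_bin)
    mean(v[bases + 1])
  })
  prof <- c(up, body, down)
  if (identical(strand, "-")) rev(prof) else prof
}

site_table <- function(position, chrom = "chr1", cut = TRUE,
                       efficiency = 1) {
  n <- length(position)
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             chrom = rep_len(chrom, n), position = position,
             cut = rep_len(cut, n),
             efficiency = rep_len(efficiency, n),
             stringsAsFactors = FALSE)
}

# small, fast simulator configuration for statistical tests; enough genes
# that the default genic fraction of cut sites (0.75) is attainable;
# arguments override the reduced defaults
small_config <- function(...) {
  args <- list(chrom_length = 3e5, n_genes = 30,
               gene_length_range = c(3000, 8000),
               n_sites = 40, n_cut = 10, background_rate = 2,
               min_site_spacing = 3000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
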