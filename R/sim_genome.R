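#' Simulate a genome model with genes and annotated break sites
#'
#' Generates a small genome with non-overlapping genes (each with an
#' expression level) and a set of annotated break sites of which exactly
#' `n_cut` are flagged as cleaved. A configured fraction of cut sites is
#' placed inside expressed genes, the remainder in intergenic or silent
#' regions, emulating the genomic distribution of restriction-enzyme break
#' sites relative to transcription. Cut sites receive a cleavage efficiency
#' drawn from `cleavage_efficiency_range`; uncut sites get 0.
#'
#' The result is deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genome_model`: a list with
#'   - `chrom_sizes`: named numeric vector of chromosome lengths,
#'   - `genes`: data.frame `chrom, start, end, name, expression, strand`
#'     (0-based half-open coordinates),
#'   - `sites`: data.frame `site_id, chrom, position, cut, efficiency,
#'     host_gene, host_expression, drip_responsive`,
#'   - `ref_expression`: scale constant (median positive expression) used
#'     to express peak amplitudes in relative-expression units,
#'   - `config`: the configuration used.
#' @examples
#' gm <- simulate_genome(sim_config(seed = 1))
#' sum(gm$sites$cut)
#' @export
simulate_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"), kind = "Mersenne-Twister")

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- setNames(rep(config$chrom_length, length(chroms)), chroms)

  genes <- place_genes(config, chroms)
  genes$expression <- draw_expression(config, nrow(genes))

  sites <- place_sites(config, genes, chrom_sizes)

  structure(
    list(chrom_sizes = chrom_sizes,
         genes = genes,
         sites = sites,
         ref_expression = ref_expression(genes$expression),
         config = config),
    class = "genome_model"
  )
}

ref_expression <- function(expr) {
  pos <- expr[expr > 0]
  if (length(pos) == 0) 1 else stats::median(pos)
}

# Sequential layout with random gaps: guarantees non-overlap and containment.
place_genes <- function(config, chroms) {
  counts <- split_count(config$n_genes, length(chroms))
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    n <- counts[i]
    if (n == 0) next
    len <- floor(runif(n, config$gene_length_range[1],
                       config$gene_length_range[2] + 1))
    total <- sum(len)
    if (total >= config$chrom_length) {
      stop("total gene length (", total, ") exceeds chromosome length (",
           config$chrom_length, ") on ", chroms[i])
    }
    w <- runif(n + 1)
    gaps <- floor(w / sum(w) * (config$chrom_length - total))
    starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(len[-n]))
    out[[i]] <- data.frame(
      chrom = chroms[i],
      start = starts,
      end = starts + len,
      name = NA_character_,
      expression = NA_real_,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, out)
  if (is.null(genes)) {
    genes <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character(),
                        expression = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
  } else {
    genes$name <- sprintf("gene_%04d", seq_len(nrow(genes)))
  }
  rownames(genes) <- NULL
  genes
}

draw_expression <- function(config, n) {
  if (n == 0) return(numeric())
  e <- config$expression
  if (is.numeric(e)) return(as.numeric(e))
  silent <- runif(n) < e$silent_fraction
  expr <- rlnorm(n, meanlog = e$meanlog, sdlog = e$sdlog)
  expr[silent] <- 0
  expr
}

split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

place_sites <- function(config, genes, chrom_sizes) {
  n_cut <- config$n_cut
  n_genic <- round(config$frac_cut_genic * n_cut)
  expressed <- genes[genes$expression > 0, , drop = FALSE]
  if (n_genic > nrow(expressed)) {
    message("only ", nrow(expressed), " expressed genes available for ",
            n_genic, " genic cut sites; placing the remainder intergenic")
    n_genic <- nrow(expressed)
  }

  pos <- numeric(0)
  chrom <- character(0)
  host <- character(0)
  ok_spacing <- function(p, ch) {
    same <- chrom == ch
    !any(same & abs(pos[same] - p) < config$min_site_spacing)
  }

  # cut sites inside expressed genes (one per gene, central 60%); genes
  # are tried in random order with a few positional retries each, so a
  # spacing conflict moves the site to another gene instead of dropping it
  if (n_genic > 0) {
    order_idx <- sample(nrow(expressed))
    placed <- 0
    for (j in order_idx) {
      if (placed >= n_genic) break
      g <- expressed[j, ]
      for (try in 1:5) {
        p <- g$start + floor((g$end - g$start) * (0.2 + 0.6 * runif(1)))
        if (ok_spacing(p, g$chrom)) {
          pos <- c(pos, p); chrom <- c(chrom, g$chrom)
          host <- c(host, g$name)
          placed <- placed + 1
          break
        }
      }
    }
    if (placed < n_genic) {
      message("placed only ", placed, " of ", n_genic,
              " genic cut sites; the remainder will be intergenic")
    }
  }

  # remaining cut sites + uncut sites: uniform positions outside expressed
  # genes (for cut-intergenic) or anywhere (uncut), spacing enforced
  draw_position <- function(avoid_expressed) {
    for (it in seq_len(20000)) {
      ch <- sample(names(chrom_sizes), 1)
      p <- floor(runif(1, config$min_site_spacing,
                       chrom_sizes[[ch]] - config$min_site_spacing))
      if (avoid_expressed) {
        eg <- genes[genes$chrom == ch & genes$expression > 0, , drop = FALSE]
        if (nrow(eg) > 0 && any(p >= eg$start & p < eg$end)) next
      }
      if (ok_spacing(p, ch)) return(list(chrom = ch, pos = p))
    }
    stop("could not place break sites with min_site_spacing = ",
         config$min_site_spacing, "; reduce n_sites or the spacing")
  }

  while (length(pos) < n_cut) {
    d <- draw_position(avoid_expressed = TRUE)
    pos <- c(pos, d$pos); chrom <- c(chrom, d$chrom)
    host <- c(host, NA_character_)
  }
  cut <- rep(c(TRUE, FALSE), c(n_cut, config$n_sites - n_cut))
  while (length(pos) < config$n_sites) {
    d <- draw_position(avoid_expressed = FALSE)
    pos <- c(pos, d$pos); chrom <- c(chrom, d$chrom)
    host <- c(host, NA_character_)
  }

  # host gene lookup for sites placed without an explicit host
  for (i in seq_along(pos)) {
    if (is.na(host[i])) {
      g <- genes[genes$chrom == chrom[i] &
                   genes$start <= pos[i] & pos[i] < genes$end, , drop = FALSE]
      if (nrow(g) > 0) host[i] <- g$name[1]
    }
  }
  host_expr <- ifelse(is.na(host), 0,
                      genes$expression[match(host, genes$name)])

  eff <- numeric(config$n_sites)
  eff[cut] <- runif(n_cut, config$cleavage_efficiency_range[1],
                    config$cleavage_efficiency_range[2])

  # minority of silent/intergenic cut sites that still gain DRIP signal
  responsive <- host_expr > 0
  silent_cut <- which(cut & !responsive)
  responsive[silent_cut] <-
    runif(length(silent_cut)) < config$silent_gain_fraction

  sites <- data.frame(
    site_id = NA_character_,
    chrom = chrom,
    position = pos,
    cut = cut,
    efficiency = eff,
    host_gene = host,
    host_expression = host_expr,
    drip_responsive = responsive,
    stringsAsFactors = FALSE
  )
  sites <- sites[order(sites$chrom, sites$position), ]
  sites$site_id <- sprintf("DSB_%04d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  stopifnot(sum(sites$cut) == n_cut,
            !anyDuplicated(sites[c("chrom", "position")]))
  sites
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  %d chromosome(s), total %s bp\n", length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  cat(sprintf("  %d genes (%d expressed), %d sites (%d cut)\n",
              nrow(x$genes), sum(x$genes$expression > 0),
              nrow(x$sites), sum(x$sites$cut)))
  invisible(x)
}

#' Write a genome model to standard text formats
#'
#' Emits three files into `dir`: `chrom.sizes` (two-column UCSC dialect),
#' `genes.bed` (BED6 plus a seventh expression column; the BED score column
#' holds the rounded expression) and `sites.bed` (BED6 over the 8 bp
#' recognition interval centered on each site; score = cleavage efficiency
#' x 1000, name = site id). All writers emit coordinate-sorted records.
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "genome_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.bed"),
    sites = file.path(dir, "sites.bed")
  )
  write_chrom_sizes(genome$chrom_sizes, paths["chrom_sizes"])

  g <- genome$genes[order(genome$genes$chrom, genome$genes$start), ]
  write.table(
    data.frame(g$chrom, format_coord(g$start), format_coord(g$end), g$name,
               round(g$expression, 3), g$strand, g$expression),
    paths["genes"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  s <- genome$sites
  write.table(
    data.frame(s$chrom, format_coord(s$position - 4),
               format_coord(s$position + 4), s$site_id,
               round(s$efficiency * 1000), "."),
    paths["sites"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(paths)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
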