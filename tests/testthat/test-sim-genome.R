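test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(n_sites = 10, n_cut = 20), "n_cut")
  expect_error(sim_config(enrichment_halfwidth = 2e6), "halfwidth")
  expect_error(sim_config(n_genes = 500, chrom_length = 1e5,
                          gene_length_range = c(5000, 10000)),
               "gene length")
  expect_error(sim_config(expression = c(1, 2)), "length n_genes")
  expect_error(sim_config(cleavage_efficiency_range = c(-0.5, 1)),
               "\\[0, 1\\]")
})

test_that("presets carry the annotated-site geometries", {
  p80 <- sim_config(preset = "dsb80")
  expect_identical(p80$n_cut, 80L)
  full <- sim_config(preset = "asisi")
  expect_identical(full$n_sites, 1211L)
  expect_identical(full$n_cut, 80L)
})

test_that("stage seeds are deterministic, stage-specific and 32-bit", {
  s1 <- stage_seed(1, "genome")
  expect_identical(s1, stage_seed(1, "genome"))
  expect_false(s1 == stage_seed(1, "qpcr"))
  expect_false(s1 == stage_seed(2, "genome"))
  expect_true(is.integer(s1) && s1 >= 0 && s1 < 2^31)
})

test_that("simulated genome honors the requested cut-site count", {
  gm <- simulate_genome(small_config(seed = 3))
  expect_identical(sum(gm$sites$cut), 10L)
  gm0 <- simulate_genome(small_config(seed = 3, n_cut = 0))
  expect_identical(sum(gm0$sites$cut), 0L)
  expect_true(all(gm0$sites$efficiency == 0))
})

test_that("genome simulation is deterministic given the seed", {
  a <- simulate_genome(small_config(seed = 11))
  b <- simulate_genome(small_config(seed = 11))
  expect_identical(a$genes, b$genes)
  expect_identical(a$sites, b$sites)
  c <- simulate_genome(small_config(seed = 12))
  expect_false(identical(a$sites$position, c$sites$position))
})

test_that("genes are non-overlapping and contained in their chromosome", {
  gm <- simulate_genome(sim_config(seed = 5))
  for (ch in names(gm$chrom_sizes)) {
    g <- gm$genes[gm$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start >= 0))
    expect_true(all(g$end <= gm$chrom_sizes[[ch]]))
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("site positions are unique and cut sites split genic/intergenic", {
  gm <- simulate_genome(sim_config(seed = 5))
  expect_false(any(duplicated(gm$sites[c("chrom", "position")])))
  cut <- gm$sites[gm$sites$cut, ]
  # default frac_cut_genic = 0.75 of 20 cut sites have an expressed host
  expect_identical(sum(cut$host_expression > 0), 15L)
  # host gene annotation is consistent with gene intervals
  genic <- cut[!is.na(cut$host_gene), ]
  for (i in seq_len(nrow(genic))) {
    g <- gm$genes[gm$genes$name == genic$host_gene[i], ]
    expect_true(g$start <= genic$position[i] &&
                  genic$position[i] < g$end)
  }
})

test_that("written genome files round-trip through the BED readers", {
  gm <- simulate_genome(small_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_genome(gm, dir)
  sizes <- read_chrom_sizes(paths[["chrom_sizes"]])
  expect_equal(sizes, gm$chrom_sizes)
  sites <- sites_from_bed(read_bed(paths[["sites"]], sizes))
  expect_identical(sites$site_id, gm$sites$site_id)
  expect_identical(sites$position, gm$sites$position)
  expect_identical(sites$cut, gm$sites$cut)
  expect_equal(sites$efficiency, gm$sites$efficiency, tolerance = 1e-3)
  genes <- genes_from_bed(read_bed(paths[["genes"]], sizes))
  expect_identical(genes$start, gm$genes$start[order(gm$genes$start)])
})
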