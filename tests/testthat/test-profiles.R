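test_that("heatmap bins have the stated geometry and values", {
  tr <- ctrack(rep(2, 20000))
  sites <- site_table(10000)
  hm <- heatmap_matrix(tr, sites, halfwidth = 5000, bin_width = 500)
  expect_equal(ncol(hm$matrix), 20)
  expect_true(all(hm$matrix == 2))
  expect_equal(hm$bin_starts[1], -5000)
  expect_error(heatmap_matrix(tr, sites, halfwidth = 5000,
                              bin_width = 333), "divisible")
})

test_that("heatmap rows conserve the window sum and match the oracle", {
  set.seed(stage_seed(1, "heatmap-oracle"))
  for (rep in 1:100) {
    len <- sample(200:600, 1)
    v <- rand_track_values(len)
    tr <- ctrack(v)
    pos <- sample(0:(len - 1), 3)
    sites <- site_table(pos, efficiency = runif(3))
    hw <- sample(2:10, 1) * 10
    bw <- 10
    hm <- heatmap_matrix(tr, sites, halfwidth = hw, bin_width = bw)
    for (id in rownames(hm$matrix)) {
      i <- match(id, sites$site_id)
      expect_equal(unname(hm$matrix[id, ]),
                   oracle_heatmap_row(v, sites$position[i], hw, bw),
                   tolerance = 1e-12)
      expect_equal(sum(hm$matrix[id, ]) * bw,
                   window_count(tr, "chr1", sites$position[i], hw, "sum"),
                   tolerance = 1e-9)
    }
  }
})

test_that("heatmap rows order by decreasing cleavage efficiency", {
  tr <- ctrack(rep(1, 1000))
  sites <- site_table(c(100, 300, 500), efficiency = c(0.2, 0.9, 0.2))
  hm <- heatmap_matrix(tr, sites, halfwidth = 50, bin_width = 10)
  expect_identical(rownames(hm$matrix), c("S002", "S001", "S003"))
  hm2 <- heatmap_matrix(tr, sites, halfwidth = 50, bin_width = 10,
                        ordering = "score_desc", score = c(1, 2, 3))
  expect_identical(rownames(hm2$matrix), c("S003", "S002", "S001"))
})

test_that("single-site average profile reproduces the window values", {
  set.seed(stage_seed(1, "avg-single"))
  v <- rand_track_values(400)
  tr <- ctrack(v)
  p <- average_profile(tr, site_table(200), halfwidth = 50)
  expect_equal(p$mean_signal, v[151:250])
  expect_true(all(p$n_sites == 1))
})

test_that("mirrored sites give a symmetric average profile", {
  v <- c(rep(0, 100), 1:50, rep(0, 100))   # asymmetric bump
  tr1 <- ctrack(c(v, rev(v)), lib = 1e6)
  sites <- site_table(c(125, 375))
  p <- average_profile(tr1, sites, halfwidth = 100)
  expect_equal(p$mean_signal, rev(p$mean_signal), tolerance = 1e-12)
})

test_that("truncated windows contribute only covered offsets", {
  tr <- ctrack(rep(1, 200))
  p <- average_profile(tr, site_table(c(10, 100)), halfwidth = 50)
  # offsets below -10 are covered by one site only
  expect_equal(p$n_sites[p$offset < -10], rep(1, 40))
  expect_equal(p$n_sites[p$offset >= -10], rep(2, 60))
  expect_true(all(p$mean_signal == 1))
})

test_that("metagene geometry is 15 + 100 + 15 bins", {
  tr <- ctrack(rep(3, 60000))
  genes <- data.frame(chrom = "chr1", start = c(10000, 30000),
                      end = c(15000, 42000), name = c("a", "b"),
                      expression = 1, strand = c("+", "-"))
  mg <- metagene_profile(tr, genes)
  expect_equal(nrow(mg), 130)
  expect_equal(as.integer(table(mg$region)[c("upstream", "body",
                                         "downstream")]),
               c(15L, 100L, 15L))
  expect_true(all(mg$mean_signal == 3))
})

test_that("metagene body bins follow the floor partition rule", {
  v <- numeric(20000)
  v[(5000 + 1):(5000 + 500)] <- 1   # first half of a 1000 bp gene
  tr <- ctrack(v)
  genes <- data.frame(chrom = "chr1", start = 5000, end = 6000,
                      name = "g", expression = 1, strand = "+")
  mg <- metagene_profile(tr, genes)
  body <- mg$mean_signal[mg$region == "body"]
  expect_equal(body[1:50], rep(1, 50))
  expect_equal(body[51:100], rep(0, 50))
})

test_that("minus-strand genes mirror the body profile", {
  set.seed(stage_seed(1, "metagene-strand"))
  v <- rand_track_values(20000)
  tr <- ctrack(v)
  plus <- data.frame(chrom = "chr1", start = 5000, end = 6100,
                     name = "g", expression = 1, strand = "+")
  minus <- plus
  minus$strand <- "-"
  mp <- metagene_profile(tr, plus)$mean_signal
  mm <- metagene_profile(tr, minus)$mean_signal
  expect_equal(mm, rev(mp), tolerance = 1e-12)
})

test_that("metagene profile matches the per-base oracle", {
  set.seed(stage_seed(1, "metagene-oracle"))
  for (rep in 1:50) {
    len <- 4000
    v <- rand_track_values(len)
    tr <- ctrack(v)
    start <- sample(600:1500, 1)
    glen <- sample(150:1500, 1)
    strand <- sample(c("+", "-"), 1)
    genes <- data.frame(chrom = "chr1", start = start,
                        end = start + glen, name = "g", expression = 1,
                        strand = strand)
    mg <- metagene_profile(tr, genes, flank = 500, flank_bin = 100,
                           n_body_bins = 100)
    expect_equal(mg$mean_signal,
                 oracle_metagene_gene(v, start, start + glen, strand,
                                      500, 100, 100),
                 tolerance = 1e-12)
  }
})

test_that("metagene filtering excludes short and edge genes", {
  tr <- ctrack(rep(1, 10000))
  genes <- data.frame(chrom = "chr1",
                      start = c(5000, 6000, 100),
                      end = c(5050, 7000, 400),   # 50 bp gene; edge gene
                      name = c("short", "ok", "edge"),
                      expression = 1, strand = "+")
  expect_message(mg <- metagene_profile(tr, genes), "2 gene")
  expect_equal(attr(mg, "n_genes"), 1)
  bad <- genes[1, , drop = FALSE]
  expect_error(suppressMessages(metagene_profile(tr, bad)), "no genes")
})

test_that("genes near cut sites are selected by the strict distance rule", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 10000, 20000),
                      end = c(2000, 11000, 21000),
                      name = c("hit", "near", "far"),
                      expression = 1, strand = "+")
  sites <- data.frame(chrom = "chr1",
                      position = c(1500, 11998, 22000, 20500),
                      cut = c(TRUE, TRUE, TRUE, FALSE))
  # gene 2 edge at base 10999; site 11998 is 999 away -> selected
  sel <- genes_near_dsb(genes, sites, max_distance = 1000)
  expect_setequal(sel$name, c("hit", "near"))
  # exactly 1000 away: excluded
  sites2 <- data.frame(chrom = "chr1", position = 11999, cut = TRUE)
  expect_equal(nrow(genes_near_dsb(genes, sites2, 1000)), 0)
  # uncut sites never select
  sites3 <- data.frame(chrom = "chr1", position = 1500, cut = FALSE)
  expect_equal(nrow(genes_near_dsb(genes, sites3, 1000)), 0)
})
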