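test_that("coverage simulation is deterministic and nonnegative", {
  gm <- simulate_genome(small_config(seed = 2))
  for (assay in c("senataxin", "polII_total", "generic")) {
    a <- simulate_chip_coverage(gm, assay, "damaged")
    b <- simulate_chip_coverage(gm, assay, "damaged")
    expect_identical(a$values, b$values)
    expect_true(all(a$values$chr1 >= 0))
  }
  d1 <- simulate_drip_coverage(gm, "damaged")
  d2 <- simulate_drip_coverage(gm, "damaged")
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values$chr1 >= 0))
  expect_error(simulate_chip_coverage(gm, "not_an_assay", "damaged"))
})

test_that("silent genomes produce no site-correlated protein enrichment", {
  cfg <- small_config(seed = 4, expression = rep(0, 30),
                      noise_model = "poisson")
  gm <- simulate_genome(cfg)
  tr <- simulate_chip_coverage(gm, "senataxin", "damaged")
  q <- quantify_sites(tr, gm$sites, 1000, "mean")
  cut_mean <- mean(q$signal[q$cut])
  uncut_mean <- mean(q$signal[!q$cut])
  # both are background-only; sampling error on a Poisson(2) mean over
  # 2000-base windows is tiny
  expect_equal(cut_mean, uncut_mean, tolerance = 0.1)
})

test_that("noise-free peak integral matches the configured amplitude", {
  cfg <- small_config(seed = 6, noise_model = "none", n_cut = 5,
                      frac_cut_genic = 1)
  gm <- simulate_genome(cfg)
  tr <- simulate_chip_coverage(gm, "senataxin", "damaged")
  s <- gm$sites[gm$sites$cut & gm$sites$host_expression > 0, ]
  expect_gt(nrow(s), 0)
  hw <- cfg$enrichment_halfwidth
  for (i in seq_len(nrow(s))) {
    w <- window_count(tr, s$chrom[i], s$position[i], hw, "sum")
    expected_amp <- cfg$enrichment_amplitude * s$efficiency[i] *
      s$host_expression[i] / gm$ref_expression
    expect_equal(w - cfg$background_rate * 2 * hw, expected_amp * 2 * hw,
                 tolerance = 1e-10)
  }
})

test_that("damage induces protein signal at cut sites only after treatment", {
  gm <- simulate_genome(sim_config(seed = 8))
  und <- normalize_track(simulate_chip_coverage(gm, "senataxin",
                                                "undamaged"))
  dam <- normalize_track(simulate_chip_coverage(gm, "senataxin",
                                                "damaged"))
  q <- quantify_sites(list(undamaged = und, damaged = dam),
                      gm$sites, 5000, "sum")
  cut <- q[q$cut, ]
  expect_gt(median(cut$damaged), median(cut$undamaged))
  expect_lt(compare_cut_uncut(q, "damaged")$p_value, 0.01)
  expect_gt(compare_cut_uncut(q, "undamaged")$p_value, 0.05)
})

test_that("configured enrichment amplitude is recovered from windows", {
  cfg <- sim_config(seed = 21)
  gm <- simulate_genome(cfg)
  tr <- simulate_chip_coverage(gm, "senataxin", "damaged")
  s <- gm$sites[gm$sites$cut & gm$sites$host_expression > 0, ]
  hw <- cfg$enrichment_halfwidth
  est <- vapply(seq_len(nrow(s)), function(i) {
    w <- window_count(tr, s$chrom[i], s$position[i], hw, "sum")
    (w - cfg$background_rate * 2 * hw) /
      (2 * hw * s$efficiency[i] * s$host_expression[i] /
         gm$ref_expression)
  }, numeric(1))
  expect_equal(mean(est), cfg$enrichment_amplitude, tolerance = 0.1)
})

test_that("noise-free DRIP flanking gain equals the configured factor", {
  cfg <- small_config(seed = 10, noise_model = "none", n_cut = 1,
                      frac_cut_genic = 1, depletion_strength = 0,
                      body_damping = 1)
  gm <- simulate_genome(cfg)
  und <- simulate_drip_coverage(gm, "undamaged")
  dam <- simulate_drip_coverage(gm, "damaged")
  s <- gm$sites[gm$sites$cut, ]
  hw <- cfg$dsb_gain_halfwidth
  r <- window_count(dam, s$chrom, s$position, hw, "sum") /
    window_count(und, s$chrom, s$position, hw, "sum")
  expect_equal(r, cfg$drip_gain, tolerance = 1e-12)
})

test_that("undamaged DRIP shows no site-anchored gain", {
  # cut sites are deliberately placed in active genes, so raw undamaged
  # DRIP differs between cut and uncut sites through baseline R-loops
  # alone; the zero-effect contract is that *damage* adds nothing, which
  # is exchangeable once the transcription structure is removed
  cfg <- small_config(seed = 13, expression = rep(0, 30))
  gm <- simulate_genome(cfg)
  und <- simulate_drip_coverage(gm, "undamaged")
  q <- quantify_sites(und, gm$sites, 5000, "sum")
  expect_gt(compare_cut_uncut(q, "signal")$p_value, 0.05)
  # with transcription present, the site-anchored *gain* (damaged over
  # undamaged) is still confined to cut sites
  gm2 <- simulate_genome(sim_config(seed = 13))
  und2 <- normalize_track(simulate_drip_coverage(gm2, "undamaged"))
  dam2 <- normalize_track(simulate_drip_coverage(gm2, "damaged"))
  q2 <- quantify_sites(list(und = und2, dam = dam2), gm2$sites, 5000,
                       "sum")
  q2$gain <- q2$dam / pmax(q2$und, 1e-9)
  expect_gt(median(q2$gain[q2$cut]), median(q2$gain[!q2$cut]))
  expect_lt(compare_cut_uncut(q2, "gain")$p_value, 0.01)
})

test_that("helicase knockdown abolishes the central DRIP depletion", {
  gm <- simulate_genome(sim_config(seed = 14))
  active <- normalize_track(simulate_drip_coverage(gm, "damaged",
                                                   senataxin_activity = 1))
  kd <- normalize_track(simulate_drip_coverage(gm, "damaged",
                                               senataxin_activity = 0))
  s <- gm$sites[gm$sites$cut & gm$sites$host_expression > 0, ]
  hw <- gm$config$depletion_halfwidth
  central <- function(tr) {
    vapply(seq_len(nrow(s)), function(i) {
      window_count(tr, s$chrom[i], s$position[i], hw, "mean")
    }, numeric(1))
  }
  expect_gt(median(central(kd)), median(central(active)))
})

test_that("gaussian noise model also yields nonnegative tracks", {
  cfg <- small_config(seed = 15, noise_model = "gaussian",
                      gaussian_sd = 2)
  gm <- simulate_genome(cfg)
  tr <- simulate_chip_coverage(gm, "generic", "undamaged")
  expect_true(all(tr$values$chr1 >= 0))
})
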