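test_that("ssDNA percent evaluates the assay equation", {
  expect_equal(ssdna_percent(25, 25), 100)
  expect_equal(ssdna_percent(26, 25), 100 / 1.5)
  expect_equal(ssdna_percent(28, 25), 100 / 4.5)
  expect_error(ssdna_percent(Inf, 25), "finite")
})

test_that("ssDNA percent is strictly decreasing with known limits", {
  dct <- seq(-10, 10, by = 0.25)
  v <- ssdna_percent(25 + dct, 25, clamp = FALSE)
  expect_true(all(diff(v) < 0))
  expect_lt(ssdna_percent(40, 25), 1e-2)
  # raw value approaches 200 as the digested well amplifies much earlier
  expect_equal(ssdna_percent(5, 25, clamp = FALSE), 200, tolerance = 1e-4)
  expect_equal(ssdna_percent(5, 25), 100)   # clamped
})

test_that("resection normalization is a guarded ratio", {
  expect_equal(resection_normalized(20, 20), 1)
  expect_equal(resection_normalized(40, 20), 2)
  expect_error(resection_normalized(40, 0), "> 0")
})

test_that("percent broken is self-normalized at the reference", {
  expect_equal(percent_broken(20, 20, 20, 20), 100)
  expect_equal(percent_broken(21, 20, 20, 20), 50)
  expect_equal(percent_broken(19, 20, 20, 20), 200)
  expect_error(percent_broken(NA, 20, 20, 20), "finite")
})

test_that("delta-delta-Ct uses the mean of two control amplicons", {
  expect_equal(ddct_frequency(24, c(20, 22), 24, c(20, 22)), 1)
  expect_equal(ddct_frequency(23, c(20, 22), 24, c(20, 22)), 2)
  # controls (20, 22) act exactly like a single control at 21
  expect_equal(ddct_frequency(23, c(20, 22), 24, c(21, 21)),
               ddct_frequency(23, c(21, 21), 24, c(21, 21)))
  expect_error(ddct_frequency(23, c(a = 20, b = NA), 24, c(20, 22)),
               "'b'")
})

test_that("DRIP percent input corrects for the input fraction", {
  expect_equal(drip_percent_input(25, 25, 0.1), 10)
  expect_equal(drip_percent_input(26, 25, 0.1), 5)
  expect_error(drip_percent_input(25, 25, 1), "\\(0, 1\\)")
  expect_error(drip_percent_input(25, 25, 0), "\\(0, 1\\)")
})

test_that("assay quantities are scale-free in absolute Ct", {
  for (shift in c(-5, 3, 11)) {
    expect_equal(ssdna_percent(26 + shift, 25 + shift),
                 ssdna_percent(26, 25))
    expect_equal(percent_broken(21 + shift, 20 + shift, 20 + shift,
                                20 + shift),
                 percent_broken(21, 20, 20, 20))
    expect_equal(ddct_frequency(23 + shift, c(20, 22) + shift,
                                24 + shift, c(20, 22) + shift),
                 ddct_frequency(23, c(20, 22), 24, c(20, 22)))
    expect_equal(drip_percent_input(26 + shift, 25 + shift, 0.1),
                 drip_percent_input(26, 25, 0.1))
  }
})

test_that("replicate summaries report mean and sem", {
  s <- summarize_replicates(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  one <- summarize_replicates(5)
  expect_equal(one$mean, 5)
  expect_true(one$sem_undefined)
  expect_equal(summarize_replicates(rep(3, 4))$sem, 0)
  expect_error(summarize_replicates(numeric(0)), "at least one")
})
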