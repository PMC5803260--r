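# noise-free Ct tables constructed from known truth: the table-level
# drivers must recover the truth exactly

test_that("resection driver recovers the normalized ssDNA fold", {
  rows <- list()
  truth <- c(ctrl_undamaged = 0.1, damaged = 0.4)
  k <- 0
  for (cond in names(truth)) {
    for (r in 1:3) {
      m <- simulate_resection_experiment(truth[[cond]])
      k <- k + 1
      rows[[k]] <- data.frame(sample = c("digested", "undigested"),
                              target = "locus1", condition = cond,
                              replicate = r,
                              ct = c(m$ct_digested, m$ct_undigested))
    }
  }
  res <- assay_resection(do.call(rbind, rows),
                         control_condition = "ctrl_undamaged")
  expect_equal(res$mean[res$condition == "ctrl_undamaged"], 1)
  expect_equal(res$mean[res$condition == "damaged"], 4)
  expect_equal(res$sem, c(0, 0))
})

test_that("repair driver recovers the broken fraction time course", {
  broken <- c(t0 = 1, t60 = 0.25)
  rows <- list(); k <- 0
  for (cond in names(broken)) {
    for (r in 1:2) {
      k <- k + 1
      rows[[k]] <- simulate_qpcr(c(0.05 * broken[[cond]], 1),
                                 sample = c("pulldown", "input"),
                                 target = "DSB1", condition = cond,
                                 replicate = r)
    }
  }
  res <- assay_repair(do.call(rbind, rows), reference_condition = "t0")
  expect_equal(res$mean[res$condition == "t0"], 100)
  expect_equal(res$mean[res$condition == "t60"], 25)
})

test_that("translocation driver recovers relative junction frequency", {
  freq <- c(control = 1, setx_kd = 4)
  rows <- list(); k <- 0
  for (cond in names(freq)) {
    for (r in 1:3) {
      k <- k + 1
      rows[[k]] <- simulate_qpcr(c(1e-4 * freq[[cond]], 1, 2),
                                 sample = "gDNA",
                                 target = c("junction", "ctrlA", "ctrlB"),
                                 condition = cond, replicate = r)
    }
  }
  res <- assay_translocation(do.call(rbind, rows), target = "junction",
                             control_targets = c("ctrlA", "ctrlB"),
                             reference_condition = "control")
  expect_equal(res$mean[res$condition == "control"], 1)
  expect_equal(res$mean[res$condition == "setx_kd"], 4)
  expect_error(
    assay_translocation(do.call(rbind, rows), target = "junction",
                        control_targets = "ctrlA",
                        reference_condition = "control"),
    "two control")
})

test_that("DRIP driver computes percent input per replicate", {
  rows <- list(); k <- 0
  for (r in 1:3) {
    k <- k + 1
    rows[[k]] <- simulate_qpcr(c(0.05, 0.5), sample = c("ip", "input"),
                               target = "locus", condition = "damaged",
                               replicate = r)
  }
  res <- assay_drip(do.call(rbind, rows), input_fraction = 0.1)
  # IP holds 0.05 of the total, input well holds 0.5 representing a 0.1
  # fraction: percent input = 100 * 0.1 * (0.05 / 0.5) = 1
  expect_equal(res$mean, 1)
})

test_that("missing wells are reported with their key", {
  ct <- simulate_qpcr(1, sample = "pulldown", target = "DSB1",
                      condition = "t0", replicate = 1)
  expect_error(assay_repair(ct, reference_condition = "t0"),
               "input, DSB1, t0")
})
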