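test_that("noiseless assays reproduce the reference-normalized model exactly", {
  nominal <- nominal_run()
  scen <- scenario_run("Fig6A_combined")
  for (assay in names(assay_specs())) {
    spec <- assay_specs()[[assay]]
    ds <- generate_assay(nominal, scen, assay = assay, cv = 0, seed = 1)
    ref <- observable(nominal, spec$observable)
    ref_v <- ref$value[ref$time == spec$reference_time]
    for (tp in spec$times) {
      expect_equal(unique(ds$control$value[ds$control$time_min == tp]),
                   ref$value[ref$time == tp] / ref_v, tolerance = 1e-15)
      sc <- observable(scen, spec$observable)
      expect_equal(unique(ds$scenario$value[ds$scenario$time_min == tp]),
                   sc$value[sc$time == tp] / ref_v, tolerance = 1e-15)
    }
  }
})

test_that("the control mean at the reference time is one by construction", {
  ds <- generate_assay(nominal_run(), scenario_run("Fig6A_combined"),
                       assay = "p65", cv = 0.15, seed = 42)
  ref_t <- assay_specs()$p65$reference_time
  expect_equal(mean(ds$control$value[ds$control$time_min == ref_t]), 1.0)
  expect_equal(nrow(ds$control), 6 * length(assay_specs()$p65$times))
  expect_true(all(ds$control$value >= 0))
})

test_that("replicate noise follows the stated lognormal moments", {
  cv <- 0.3
  n <- 4000
  ds <- generate_assay(nominal_run(), nominal_run(), assay = "IKK",
                       cv = cv, n = n, seed = 9)
  spec <- assay_specs()$IKK
  ref <- observable(nominal_run(), spec$observable)
  # ratio of two sample means of lognormal replicates: the exp(sdlog^2/2)
  # mean factor cancels between numerator and reference
  for (tp in c(2.5, 10)) {
    got <- mean(ds$control$value[ds$control$time_min == tp])
    want <- ref$value[ref$time == tp] / ref$value[ref$time == spec$reference_time]
    expect_lt(abs(got / want - 1), 3 * cv * sqrt(2 / n))
  }
})

test_that("assay generation is seed-stable and validates its inputs", {
  a <- generate_assay(nominal_run(), nominal_run(), assay = "p65", seed = 5)
  b <- generate_assay(nominal_run(), nominal_run(), assay = "p65", seed = 5)
  expect_identical(a, b)
  short <- simulate_scenario(NULL, t_end = 10, grid = seq(0, 10, 0.5))
  expect_error(generate_assay(short, short, assay = "p65"), "not on trajectory grid")
})

test_that("qPCR Ct tables encode transcript levels on the log2 scale", {
  st <- matrix(0, 2, length(species_names()),
               dimnames = list(NULL, species_names()))
  st[, "IkBat"] <- c(0.001, 0.002)  # exact doubling
  st[, "A20t"] <- c(0.004, 0.001)
  traj <- structure(list(time = c(0, 30), state = st,
                         meta = list(scenario = "synthetic")),
                    class = "nfkb_trajectory")
  ct <- generate_qpcr(traj, times = c(0, 30), n = 2, seed = 1, sd_ct = 0)
  ik <- ct[ct$gene == "IkBat", ]
  expect_equal(unique(ik$ct_target[ik$time_min == 0]) -
                 unique(ik$ct_target[ik$time_min == 30]), 1.0)
  # reference gene is stimulus-independent
  expect_equal(length(unique(ct$ct_reference)), 1L)
  fc <- ddct_fold_change(ct)
  expect_equal(fc$fold_change[fc$gene == "IkBat" & fc$time_min == 0],
               c(1, 1))
  expect_equal(unique(fc$fold_change[fc$gene == "IkBat" & fc$time_min == 30]),
               2.0)
  expect_equal(unique(fc$fold_change[fc$gene == "A20t" & fc$time_min == 30]),
               0.25)
  st[1, "IkBat"] <- 0
  bad <- structure(list(time = c(0, 30), state = st, meta = list()),
                   class = "nfkb_trajectory")
  expect_error(generate_qpcr(bad, times = c(0, 30)), "nonpositive")
})

test_that("noiseless qPCR round-trips the trajectory's fold changes", {
  traj <- nominal_run()
  ct <- generate_qpcr(traj, times = c(0, 30, 60, 120), n = 3, seed = 1,
                      sd_ct = 0)
  fc <- ddct_fold_change(ct)
  for (g in c("IkBat", "A20t")) {
    model_fold <- normalize_series(observable(traj, g), "fold_over_initial")
    for (tp in c(30, 60, 120))
      expect_equal(unique(fc$fold_change[fc$gene == g & fc$time_min == tp]),
                   model_fold$value[model_fold$time == tp], tolerance = 1e-12)
  }
})
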