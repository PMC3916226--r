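test_that("the catalog contains the required perturbations", {
  cat_ <- scenario_catalog()
  s <- cat_$Fig6A_combined
  expect_equal(s$rates, c(kiA20 = 10, kc2a = 1 / 6))
  expect_equal(s$pools, c(NFkB_total = 0.70))
  expect_length(cat_$nominal$rates, 0)
  expect_length(cat_$nominal$pools, 0)
  # single-rate scans
  ka_factors <- sort(unname(vapply(cat_[grep("^Fig3A_ka", names(cat_))],
                                   function(x) unname(x$rates["ka"]),
                                   numeric(1))))
  expect_equal(ka_factors, c(1 / 16, 1 / 8, 1 / 4, 1 / 2))
  kc2a_factors <- sort(unname(vapply(cat_[grep("^Fig3B_kc2a", names(cat_))],
                                     function(x) unname(x$rates["kc2a"]),
                                     numeric(1))))
  expect_equal(kc2a_factors, c(1 / 32, 1 / 10, 1 / 6, 1 / 5))
  expect_equal(cat_$Fig4A_c2a_1_30$rates, c(c2a = 1 / 30))
  expect_equal(cat_$Fig5A_pool70$pools, c(NFkB_total = 0.70))
  expect_equal(cat_$Fig5B_combined$pools, c(NFkB_total = 0.70, IKK_total = 0.055))
  expect_equal(cat_$FigS7B_pool70_IKKn_1_18$pools,
               c(NFkB_total = 0.70, IKK_total = 1 / 18))
  expect_equal(cat_$FigS4B_IKKn_1_8_kc2a_1_5$rates, c(kc2a = 1 / 5))
  for (rate in c("kp", "ki", "kiA20", "kua1", "kuc1", "kupd"))
    expect_gte(length(cat_[grep(rate, names(cat_))]), 4)
  # every scenario applied to nominal remains a valid parameter set
  for (s in cat_) {
    ap <- apply_scenario(default_parameters(), default_pools(), s)
    expect_silent(validate_parameters(ap$params))
    expect_true(all(ap$pools >= 0))
    expect_true(nzchar(s$provenance))
  }
})

test_that("scenario application is multiplicative and leaves the rest untouched", {
  p <- default_parameters()
  pools <- default_pools()
  s <- scenario("ka_down", rates = c(ka = 1 / 16))
  ap <- apply_scenario(p, pools, s)
  expect_identical(unname(ap$params["ka"]), unname(p["ka"]) / 16)
  expect_identical(ap$params[names(p) != "ka"], p[names(p) != "ka"])
  expect_identical(ap$pools, pools)
  # factor 1 is the identity
  ap1 <- apply_scenario(p, pools, scenario("id", rates = c(kc2a = 1)))
  expect_identical(ap1$params, p)
})

test_that("applying a scenario then its inverse restores the nominal model", {
  p <- default_parameters()
  pools <- default_pools()
  s <- scenario("combo", rates = c(kiA20 = 10, kc2a = 1 / 6, c2a = 1 / 30),
                pools = c(NFkB_total = 0.7))
  fwd <- apply_scenario(p, pools, s)
  back <- apply_scenario(fwd$params, fwd$pools, inverse_scenario(s))
  expect_equal(back$params, p, tolerance = 1e-15)
  expect_equal(back$pools, pools, tolerance = 1e-15)
})

test_that("unknown names are rejected listing the valid ones", {
  p <- default_parameters()
  pools <- default_pools()
  expect_error(apply_scenario(p, pools, scenario("x", rates = c(nope = 2))),
               "unknown rate.*valid names.*ka")
  expect_error(apply_scenario(p, pools, scenario("x", pools = c(nope = 2))),
               "unknown pool")
  expect_error(scenario("x", rates = c(ka = -1)), "positive")
})

test_that("self-comparison yields no reductions and mismatched grids fail", {
  traj <- nominal_run()
  v <- evaluate_scenario(scenario_catalog()$nominal, traj, traj)
  expect_false(v$checks[["reduces_basal_total_IkBa"]])
  expect_false(v$checks[["reduces_peak_IKKa"]])
  expect_false(v$checks[["reduces_peak_nuclear_NFkB"]])
  expect_true(v$checks[["preserves_basal_NFkB_activity"]])
  other <- simulate_scenario(NULL, t_end = 60)
  expect_error(evaluate_scenario(scenario_catalog()$nominal, traj, other),
               "grid")
})

test_that("scenario classification reproduces the plausibility structure", {
  cat_ <- scenario_catalog()
  nominal <- nominal_run()
  # reducing only the IKK pool cannot reduce basal total IkBa
  v <- evaluate_scenario(cat_$FigS4A_IKKn_1_8, nominal,
                         scenario_run("FigS4A_IKKn_1_8"))
  expect_false(v$plausible)
  expect_true("reduces_basal_total_IkBa" %in% v$failed)
  # reduced p65 plus only downstream inhibition cannot reduce IKK activation
  v <- evaluate_scenario(cat_$FigS4C_pool70_kc2a_1_10, nominal,
                         scenario_run("FigS4C_pool70_kc2a_1_10"))
  expect_false(v$plausible)
  expect_true("reduces_peak_IKKa" %in% v$failed)
  # the combined scenarios carry both necessary components and pass
  for (nm in c("Fig6A_combined", "Fig5B_combined")) {
    v <- evaluate_scenario(cat_[[nm]], nominal, scenario_run(nm))
    expect_true(v$plausible)
  }
})

test_that("reducing the NF-kB pool leaves early IKK activation unchanged", {
  dev <- sup_deviation(scenario_run("Fig5A_pool70"), nominal_run(),
                       "IKKa", t_max = 30)
  expect_lt(dev, 0.01)
})

test_that("catalog serialization writes every entry with its factors", {
  f <- withr::local_tempfile(fileext = ".json")
  write_catalog(f)
  x <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(length(x), length(scenario_catalog()))
  expect_equal(x$Fig6A_combined$rates$kiA20, 10)
})
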