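# minimal hand-built trajectory for readout edge cases
fake_traj <- function(time, state) {
  structure(list(time = time, state = state,
                 meta = list(scenario = "synthetic", stimulus_on = TRUE,
                             solver = list(method = "none"))),
            class = "nfkb_trajectory")
}

test_that("peak takes the global maximum with earliest-time tie-breaking", {
  s <- structure(list(name = "x", time = 0:5, value = c(5, 4, 3, 2, 1, 0),
                      normalization = NULL), class = "nfkb_series")
  expect_equal(peak(s), list(amplitude = 5, time = 0))
  s$value <- c(1, 3, 3, 2, 3, 0)
  expect_equal(peak(s)$time, 1)  # first of the tied maxima
})

test_that("grid peaks agree with a 10x-refined simulation", {
  p <- default_parameters()
  eq <- nominal_eq()
  coarse <- run_stimulus(p, eq, grid = seq(0, 150, by = 1))
  fine <- run_stimulus(p, eq, grid = seq(0, 150, by = 0.1))
  for (obs in c("NFkBn", "IKKa")) {
    pk_c <- peak(observable(coarse, obs))$amplitude
    pk_f <- peak(observable(fine, obs))$amplitude
    expect_lt(abs(pk_c - pk_f) / pk_f, 0.005)
  }
})

test_that("equilibrium ratios behave for identity, scaling and degenerate input", {
  eq <- nominal_eq()
  expect_equal(steady_state_ratio(eq, eq, "total_IkBa"), 1.0)
  # the ratio grows with the pool factor
  ratios <- vapply(c(0.5, 0.7, 0.9), function(f) {
    eqf <- equilibrate(default_parameters(),
                       default_pools() * c(f, 1))
    steady_state_ratio(eqf, eq, "total_IkBa")
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  zero_eq <- eq; zero_eq[] <- 0
  expect_warning(r <- steady_state_ratio(eq, zero_eq, "IKKa"), "undefined")
  expect_true(is.na(r))
})

test_that("normalization modes hit their anchors and invert exactly", {
  traj <- nominal_run()
  s <- observable(traj, "NFkBn")
  f <- normalize_series(s, "fold_over_initial")
  expect_equal(f$value[1], 1.0)
  r <- normalize_series(s, "reference_timepoint", reference_time = 20)
  expect_equal(r$value[r$time == 20], 1.0)
  b <- normalize_series(s, "basal_is_10pct_of_max")
  expect_equal(b$value[1], 0.10)
  expect_equal(max(b$value), 1.0)
  for (ns in list(f, r, b)) {
    back <- denormalize_series(ns)
    expect_lt(max(abs(back$value - s$value)) / max(abs(s$value)), 1e-12)
  }
  expect_error(normalize_series(s, "reference_timepoint", reference_time = 3.14),
               "not on the grid")
  zero <- s; zero$value[1] <- 0
  expect_error(normalize_series(zero, "fold_over_initial"), "zero")
  expect_error(denormalize_series(s), "no normalization")
})

test_that("tagged fraction spans its limits", {
  expect_lt(tagged_fraction(nominal_run(), 0), 1e-9)
  st <- matrix(0, 2, length(species_names()),
               dimnames = list(NULL, species_names()))
  st[, "pIkBaNFkB"] <- 0.05
  expect_equal(tagged_fraction(fake_traj(c(0, 1), st), 1), 1.0)
  empty <- matrix(0, 1, length(species_names()),
                  dimnames = list(NULL, species_names()))
  expect_warning(r <- tagged_fraction(fake_traj(0, empty), 0), "undefined")
  expect_true(is.na(r))
  expect_error(tagged_fraction(nominal_run(), 7.77), "not on the trajectory grid")
})

test_that("blocking phosphorylation leaves less tagged IkBa than blocking the proteasome", {
  # at comparable attenuation of the response, inhibiting the kinase step
  # starves the tagged pool while inhibiting its clearance piles it up
  kc2a_low <- simulate_scenario(scenario("kc2a_1_8", rates = c(kc2a = 1 / 8)))
  kupd_low <- simulate_scenario(scenario("kupd_1_8", rates = c(kupd = 1 / 8)))
  for (t in c(5, 10, 20))
    expect_lt(tagged_fraction(kc2a_low, t), tagged_fraction(kupd_low, t))
})

test_that("total IkBa equals the sum of its component series everywhere", {
  traj <- scenario_run("Fig6A_combined")
  comp <- c("IkBa", "pIkBa", "pIkBaE3", "pIkBaUb", "IkBan", "IkBaNFkB",
            "pIkBaNFkB", "pIkBaE3NFkB", "pIkBaUbNFkB", "IkBaNFkBn")
  total <- observable(traj, "total_IkBa")$value
  parts <- Reduce(`+`, lapply(comp, function(x) observable(traj, x)$value))
  expect_lt(max(abs(total - parts)) / max(total), 1e-9)
  expect_true(all(total >= traj$state[, "IkBa"]))
})
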