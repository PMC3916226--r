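# Session-level cache so expensive simulations are shared across test files.
.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

nominal_run <- function() cached("nominal", simulate_scenario(NULL))

nominal_eq <- function() cached("nominal_eq",
                                equilibrate(default_parameters(), default_pools()))

scenario_run <- function(name) {
  cached(paste0("run_", name),
         simulate_scenario(scenario_catalog()[[name]]))
}

# sup-norm deviation of an observable between two runs, relative to the
# nominal observable's maximum on the window
sup_deviation <- function(traj_a, traj_b, obs, t_max = Inf) {
  a <- observable(traj_a, obs)
  b <- observable(traj_b, obs)
  w <- a$time <= t_max
  max(abs(a$value[w] - b$value[w])) / max(abs(b$value[w]))
}
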