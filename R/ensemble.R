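# Parameter-uncertainty ensembles: every rate constant and both initial
# pools drawn independently and uniformly on [(1-f)v, (1+f)v] around the
# nominal value v, each draw equilibrated under its own perturbed parameters
# before stimulation. Using the same sample list for a nominal and a scenario
# run gives paired draws (identical random factors), which isolates the
# scenario effect from sampling noise.

#' Sample perturbed parameter sets and pools
#'
#' @param nominal Named rate-constant vector the sampling is centered on.
#' @param pools Named initial pools the sampling is centered on.
#' @param fraction Half-width of the uniform interval as a proportion of the
#'   nominal value (0.2 = +/-20 percent). Must be in (0, 1) so that sampled
#'   rates stay positive.
#' @param n Number of draws.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return List of `n` elements, each a list with perturbed `params` and
#'   `pools`.
#' @export
sample_parameters <- function(nominal, pools = default_pools(), fraction = 0.2,
                              n = 100, seed = 1) {
  validate_parameters(nominal)
  pools <- validate_pools(pools)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1); fraction >= 1 would allow non-positive rates")
  if (n < 1) stop("n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  k <- length(nominal)
  m <- length(pools)
  lapply(seq_len(n), function(i) {
    fp <- stats::runif(k, 1 - fraction, 1 + fraction)
    fq <- stats::runif(m, 1 - fraction, 1 + fraction)
    list(params = nominal * fp, pools = pools * fq)
  })
}

#' Run an ensemble of simulations
#'
#' Simulates every sampled parameter set (optionally with a scenario applied
#' on top of the perturbed values; multiplicative factors commute, so this
#' equals centering the sampling on the scenario-modified model), each
#' equilibrated under its own parameters, and averages the trajectories
#' pointwise on the common grid.
#'
#' @param samples List from [sample_parameters()].
#' @param scn Optional `nfkb_scenario` applied to every draw.
#' @param t_end,grid,rtol,atol Simulation settings shared by all draws.
#' @param max_failure_rate Abort if more than this proportion of draws fails.
#' @return Object of class `nfkb_ensemble`: `members` (list of
#'   `nfkb_trajectory`), `mean` (an `nfkb_trajectory` whose state is the
#'   pointwise arithmetic mean of the members), `failures` (count), and the
#'   sampling/scenario metadata.
#' @export
run_ensemble <- function(samples, scn = NULL, t_end = 150,
                         grid = default_grid(t_end), rtol = 1e-8, atol = 1e-10,
                         max_failure_rate = 0.05) {
  if (!length(samples)) stop("samples must be nonempty")
  members <- vector("list", length(samples))
  failures <- 0L
  for (i in seq_along(samples)) {
    members[i] <- list(tryCatch(
      simulate_scenario(scn, params = samples[[i]]$params,
                        pools = samples[[i]]$pools, t_end = t_end,
                        grid = grid, rtol = rtol, atol = atol),
      error = function(e) {
        warning(sprintf("draw %d failed and was excluded: %s", i,
                        conditionMessage(e)))
        NULL
      }))
    if (is.null(members[[i]])) failures <- failures + 1L
  }
  if (failures > max_failure_rate * length(samples))
    stop(sprintf("%d of %d ensemble draws failed (> %g%% allowed)",
                 failures, length(samples), 100 * max_failure_rate))
  ok <- !vapply(members, is.null, logical(1))
  members <- members[ok]
  mean_state <- Reduce(`+`, lapply(members, `[[`, "state")) / length(members)
  mean_traj <- structure(
    list(time = members[[1L]]$time, state = mean_state,
         meta = list(scenario = if (is.null(scn)) "nominal" else scn$name,
                     stimulus_on = TRUE,
                     solver = members[[1L]]$meta$solver,
                     params = NULL, pools = NULL,
                     ensemble = list(n = length(members), failures = failures))),
    class = "nfkb_trajectory")
  structure(list(members = members, mean = mean_traj, failures = failures,
                 scenario = if (is.null(scn)) "nominal" else scn$name),
            class = "nfkb_ensemble")
}

#' @export
print.nfkb_ensemble <- function(x, ...) {
  cat(sprintf("<nfkb_ensemble> scenario '%s': %d members (%d failed draws)\n",
              x$scenario, length(x$members), x$failures))
  invisible(x)
}
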