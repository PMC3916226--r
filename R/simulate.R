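#' @importFrom deSolve lsoda
NULL

#' Default output grid
#'
#' 1-minute spacing over the experimental window, densified to 0.25 min over
#' the first 10 minutes where IKK activity changes fastest.
#'
#' @param t_end End of the window, minutes.
#' @return Strictly increasing numeric vector of output times starting at 0.
#' @export
default_grid <- function(t_end = 150) {
  stopifnot(t_end > 0)
  sort(unique(c(seq(0, min(10, t_end), by = 0.25), seq(0, t_end, by = 1), t_end)))
}

.integrate <- function(y0, times, params, stimulus_on, rtol, atol) {
  out <- deSolve::lsoda(
    y = unname(y0[.species]), times = times, func = .nfkb_deriv,
    parms = list(p = as.list(params), stimulus = as.numeric(isTRUE(stimulus_on))),
    rtol = rtol, atol = atol, maxsteps = 50000
  )
  if (attr(out, "istate")[1L] < 0)
    stop("ODE solver failed at t = ", max(out[, 1L]),
         "; last state: ", paste(sprintf("%s=%.3g", .species,
                                         out[nrow(out), -1L]), collapse = ", "))
  state <- out[, -1L, drop = FALSE]
  colnames(state) <- .species
  neg <- state < 0
  if (any(neg)) {
    worst <- min(state)
    if (worst < -1e-9)
      warning(sprintf("negative concentration %.3g clipped to 0", worst))
    state[neg] <- 0
  }
  list(time = out[, 1L], state = state)
}

#' Equilibrate the model without stimulus
#'
#' Integrates the unstimulated system from the initial pools until every
#' species' time derivative is negligible relative to its concentration: the
#' returned state `x*` satisfies `|rhs_i(x*)| <= tol * max(x*_i, floor)` for
#' every species, where `floor` guards near-zero species. This long-horizon
#' integration defines the t = 0 condition for stimulated runs.
#'
#' @param params Named rate-constant vector.
#' @param pools Named initial pools (`NFkB_total`, `IKK_total`).
#' @param tol Relative derivative-norm threshold for convergence.
#' @param t_max Maximum equilibration horizon, minutes.
#' @param floor Concentration floor (uM) for the component-wise safeguard.
#' @param rtol,atol Solver tolerances.
#' @return Named equilibrium state vector, with attribute `"t_converged"`.
#' @export
equilibrate <- function(params, pools = default_pools(), tol = 1e-9,
                        t_max = 1e5, floor = 1e-6, rtol = 1e-10, atol = 1e-14) {
  validate_parameters(params)
  pools <- validate_pools(pools)
  y0 <- initial_state(pools)
  checkpoints <- unique(c(0, t_max * c(1 / 64, 1 / 16, 1 / 4, 1 / 2, 1)))
  res <- .integrate(y0, checkpoints, params, stimulus_on = FALSE,
                    rtol = rtol, atol = atol)
  for (i in seq_along(res$time)[-1L]) {
    x <- res$state[i, ]
    d <- rhs(x, params, stimulus_on = FALSE)
    ok <- abs(d) <= tol * pmax(abs(x), floor)
    if (all(ok)) {
      attr(x, "t_converged") <- res$time[i]
      return(x)
    }
  }
  rel <- abs(d) / pmax(abs(x), floor)
  stop(sprintf(
    "equilibration did not converge within %g min; worst species %s (relative rate %.3g > tol %.3g)",
    t_max, names(which.max(rel)), max(rel), tol))
}

#' Simulate the stimulated response
#'
#' Integrates the model from a (typically equilibrated) start state with the
#' TNF stimulus present and constant from t = 0.
#'
#' @param params Named rate-constant vector.
#' @param start Named state vector at t = 0 (the post-equilibration state).
#' @param t_end Length of the stimulation window, minutes.
#' @param grid Output time grid; must start at 0 and be strictly increasing.
#' @param stimulus_on Logical; set `FALSE` to verify the fixed point.
#' @param rtol,atol Solver tolerances.
#' @param scenario Name recorded in the trajectory metadata.
#' @param pools Optional pools recorded in metadata.
#' @return An object of class `nfkb_trajectory`: list with `time`, `state`
#'   (time-by-species matrix), and `meta` (scenario, solver settings,
#'   parameter digest).
#' @export
run_stimulus <- function(params, start, t_end = 150, grid = default_grid(t_end),
                         stimulus_on = TRUE, rtol = 1e-8, atol = 1e-10,
                         scenario = "nominal", pools = NULL) {
  validate_parameters(params)
  if (!isTRUE(all(diff(grid) > 0)) || grid[1L] != 0)
    stop("grid must start at 0 and be strictly increasing")
  if (!setequal(names(start), .species))
    stop("start state must contain exactly the species in species_names()")
  res <- .integrate(start, grid, params, stimulus_on = stimulus_on,
                    rtol = rtol, atol = atol)
  structure(
    list(time = res$time, state = res$state,
         meta = list(scenario = scenario,
                     stimulus_on = isTRUE(stimulus_on),
                     solver = list(method = "lsoda", rtol = rtol, atol = atol),
                     params = params,
                     pools = pools,
                     params_digest = .params_digest(params, if (is.null(pools))
                       c(NFkB_total = NA_real_, IKK_total = NA_real_) else pools))),
    class = "nfkb_trajectory")
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat(sprintf("<nfkb_trajectory> scenario '%s': %d time points on [%g, %g] min, %d species\n",
              x$meta$scenario, length(x$time), min(x$time), max(x$time),
              ncol(x$state)))
  invisible(x)
}

#' Equilibrate then stimulate one scenario
#'
#' Applies a scenario's multiplicative factors to the nominal parameters and
#' pools (before equilibration, as constitutive changes), equilibrates without
#' stimulus, then simulates the stimulated response.
#'
#' @param scn A scenario from [scenario_catalog()] or [scenario()]; `NULL`
#'   means the nominal model.
#' @param params,pools Nominal parameters and pools.
#' @param t_end,grid,rtol,atol Passed to [run_stimulus()].
#' @param eq_tol Convergence tolerance passed to [equilibrate()].
#' @return `nfkb_trajectory` whose first row is the post-equilibration state;
#'   the equilibrium is attached as attribute `"equilibrium"`.
#' @export
simulate_scenario <- function(scn = NULL, params = default_parameters(),
                              pools = default_pools(), t_end = 150,
                              grid = default_grid(t_end), rtol = 1e-8,
                              atol = 1e-10, eq_tol = 1e-9) {
  name <- "nominal"
  if (!is.null(scn)) {
    ap <- apply_scenario(params, pools, scn)
    params <- ap$params
    pools <- ap$pools
    name <- scn$name
  }
  eq <- equilibrate(params, pools, tol = eq_tol)
  traj <- run_stimulus(params, eq, t_end = t_end, grid = grid,
                       rtol = rtol, atol = atol, scenario = name, pools = pools)
  attr(traj, "equilibrium") <- eq
  traj
}

#' Write a trajectory as tidy CSV plus JSON metadata
#'
#' @param traj `nfkb_trajectory`.
#' @param file Output CSV path (`time, species, value`); a `.json` sidecar
#'   with scenario, solver settings and parameter digest is written alongside.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  long <- data.frame(
    time = rep(traj$time, times = ncol(traj$state)),
    species = rep(colnames(traj$state), each = nrow(traj$state)),
    value = as.vector(traj$state))
  utils::write.csv(long, file, row.names = FALSE)
  meta <- traj$meta
  meta$params <- as.list(meta$params)
  meta$pools <- as.list(meta$pools)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", file),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
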