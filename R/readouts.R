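# Derived observables. "NF-kB activity" is mapped to the free nuclear NF-kB
# concentration (the DNA-binding ELISA proxy; complexed nuclear NF-kB is
# inhibited and does not count). This is the single place that
# biology-to-model mapping is made.

.observables <- list(
  NFkBn = "NFkBn",
  IKKa = "IKKa",
  total_IkBa = NULL,   # filled below from model.R groupings
  tagged_IkBa = NULL,
  IkBat = "IkBat",
  A20t = "A20t",
  A20 = "A20",
  IkBa = "IkBa",
  NFkB = "NFkB"
)

.state_observable <- function(state, name) {
  switch(name,
         total_IkBa = if (is.matrix(state))
           rowSums(state[, .ikba_species, drop = FALSE]) else
             sum(state[.ikba_species]),
         tagged_IkBa = if (is.matrix(state))
           rowSums(state[, .tagged_species, drop = FALSE]) else
             sum(state[.tagged_species]),
         {
           if (!name %in% .species) stop("unknown observable: ", name)
           if (is.matrix(state)) state[, name] else state[[name]]
         })
}

#' Extract an observable time series from a trajectory
#'
#' @param traj `nfkb_trajectory`.
#' @param name One of `"NFkBn"` (free nuclear NF-kB, the activity readout),
#'   `"IKKa"`, `"total_IkBa"` (free + complexed + tagged IkBa over both
#'   compartments), `"tagged_IkBa"` (phospho/ubiquitin-tagged forms),
#'   `"IkBat"`, `"A20t"`, or any single species name.
#' @return Object of class `nfkb_series`: list with `name`, `time`, `value`,
#'   and `normalization` (`NULL` until normalized).
#' @export
observable <- function(traj, name) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  structure(list(name = name, time = traj$time,
                 value = unname(.state_observable(traj$state, name)),
                 normalization = NULL),
            class = "nfkb_series")
}

#' @export
print.nfkb_series <- function(x, ...) {
  cat(sprintf("<nfkb_series> %s: %d points on [%g, %g] min%s\n", x$name,
              length(x$time), min(x$time), max(x$time),
              if (is.null(x$normalization)) "" else
                paste0(" (normalized: ", x$normalization$mode, ")")))
  invisible(x)
}

#' Peak of a series
#'
#' Global maximum over the grid; ties broken by the earliest time.
#'
#' @param series `nfkb_series`.
#' @return List with `amplitude` and `time`.
#' @export
peak <- function(series) {
  stopifnot(inherits(series, "nfkb_series"), length(series$value) > 0)
  i <- which.max(series$value)
  list(amplitude = series$value[i], time = series$time[i])
}

#' Equilibrium ratio of an observable between two models
#'
#' @param scenario_eq,nominal_eq Converged equilibrium states from
#'   [equilibrate()].
#' @param name Observable name as in [observable()].
#' @return Scenario/nominal ratio; `NA` (with a warning) when the nominal
#'   value is numerically zero.
#' @export
steady_state_ratio <- function(scenario_eq, nominal_eq, name) {
  a <- .state_observable(scenario_eq, name)
  b <- .state_observable(nominal_eq, name)
  if (!is.finite(b) || abs(b) < 1e-12) {
    warning("nominal equilibrium observable '", name,
            "' is ~0; ratio undefined")
    return(NA_real_)
  }
  a / b
}

#' Normalize a series the way the assays are reported
#'
#' Three normalization modes mirror the experimental figure conventions:
#' `reference_timepoint` divides by the value at a stated reference time (that
#' point maps to 1); `basal_is_10pct_of_max` applies the affine map sending
#' (basal value at t = 0, maximum) to (0.10, 1.0); `fold_over_initial`
#' divides by the t = 0 value. The affine coefficients are stored so the
#' transformation can be inverted with [denormalize_series()].
#'
#' @param series `nfkb_series`.
#' @param mode Normalization mode.
#' @param reference_time Reference time for `reference_timepoint` mode; must
#'   lie on the grid.
#' @return Normalized `nfkb_series` (dimensionless).
#' @export
normalize_series <- function(series,
                             mode = c("reference_timepoint",
                                      "basal_is_10pct_of_max",
                                      "fold_over_initial"),
                             reference_time = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "nfkb_series"))
  v <- series$value
  if (mode == "reference_timepoint") {
    if (is.null(reference_time)) stop("reference_time is required")
    i <- match(reference_time, series$time)
    if (is.na(i)) stop("reference_time ", reference_time, " is not on the grid")
    ref <- v[i]
    if (!is.finite(ref) || ref == 0) stop("reference value is zero; cannot normalize")
    a <- 1 / ref; b <- 0
  } else if (mode == "fold_over_initial") {
    ref <- v[1L]
    if (!is.finite(ref) || ref == 0) stop("initial value is zero; cannot normalize")
    a <- 1 / ref; b <- 0
  } else {
    basal <- v[1L]; mx <- max(v)
    if (mx == basal) stop("series is flat; basal-to-10% map undefined")
    a <- 0.9 / (mx - basal)
    b <- 0.10 - a * basal
  }
  series$value <- a * v + b
  series$normalization <- list(mode = mode, a = a, b = b,
                               reference_time = reference_time)
  series
}

#' Invert a stored normalization
#'
#' @param series Normalized `nfkb_series`.
#' @return Series on the original scale.
#' @export
denormalize_series <- function(series) {
  nz <- series$normalization
  if (is.null(nz)) stop("series carries no normalization to invert")
  series$value <- (series$value - nz$b) / nz$a
  series$normalization <- NULL
  series
}

#' Fraction of total IkBa in a tagged (phospho/ubiquitinated) state
#'
#' @param traj `nfkb_trajectory`.
#' @param t Time on the trajectory grid, minutes.
#' @return Proportion in \[0, 1\]; `NA` (with a warning) if total IkBa is ~0.
#' @export
tagged_fraction <- function(traj, t) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  i <- match(t, traj$time)
  if (is.na(i)) stop("t = ", t, " is not on the trajectory grid")
  tot <- .state_observable(traj$state, "total_IkBa")[i]
  if (tot < 1e-12) {
    warning("total IkBa ~0 at t = ", t, "; tagged fraction undefined")
    return(NA_real_)
  }
  .state_observable(traj$state, "tagged_IkBa")[i] / tot
}

#' Summarize a trajectory's headline readouts
#'
#' @param traj `nfkb_trajectory`.
#' @return List of peaks (amplitude and time), basal values and basal tagged
#'   fraction.
#' @export
summarize_readouts <- function(traj) {
  obs <- c("NFkBn", "IKKa", "total_IkBa", "tagged_IkBa", "IkBat", "A20t")
  peaks <- lapply(obs, function(o) peak(observable(traj, o)))
  names(peaks) <- obs
  basal <- vapply(obs, function(o) observable(traj, o)$value[1L], numeric(1))
  list(scenario = traj$meta$scenario, peaks = peaks, basal = as.list(basal),
       basal_tagged_fraction = tagged_fraction(traj, traj$time[1L]))
}
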