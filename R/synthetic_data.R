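# Pseudo-experimental replicate datasets with the measurement structure of
# the population-level assays: ELISA time courses (NF-kB p65 DNA binding,
# IKK kinase activity, total and Ser32-phospho IkBa) normalized to a stated
# control-cell reference time point, and qPCR Ct tables for IkBa/A20 mRNA
# with GAPDH as internal reference. Noise is multiplicative lognormal for
# ELISA readouts and additive Gaussian on the Ct scale for qPCR; both are
# stated assumptions (the experiments report only mean +/- SD).

.assay_specs <- list(
  p65 = list(observable = "NFkBn", times = c(0, 15, 20, 30, 105, 150),
             n = 6, reference_time = 20,
             description = "NF-kB p65 DNA-binding ELISA, normalized to control at 20 min"),
  IKK = list(observable = "IKKa", times = c(0, 2.5, 5, 10, 20),
             n = 6, reference_time = 5,
             description = "IKK kinase-activity ELISA, normalized to control at 5 min"),
  totalIkBa = list(observable = "total_IkBa", times = c(0, 5, 20, 60, 90),
                   n = 9, reference_time = 0,
                   description = "total IkBa ELISA OD, normalized to control at 0 min"),
  pIkBa = list(observable = "tagged_IkBa", times = c(0, 5, 20, 60, 90),
               n = 9, reference_time = 5,
               description = "Ser32-phospho IkBa ELISA, normalized to control at 5 min")
)

#' Assay specifications
#'
#' Sampling times, replicate counts and reference-normalization rules for the
#' four emulated ELISA assays.
#'
#' @return Named list of assay specs.
#' @export
assay_specs <- function() .assay_specs

#' Generate a synthetic ELISA dataset for a control/scenario pair
#'
#' Replicate values are the model observable at each sampling time multiplied
#' by lognormal noise with the stated coefficient of variation (the noise has
#' median 1, so the replicate mean exceeds the model value by the lognormal
#' mean factor `exp(sdlog^2/2)`). Both cell types are then normalized by the
#' control dataset's empirical mean at the assay's reference time point,
#' mirroring how the experimental figures are normalized. With `cv = 0` the
#' replicates equal the reference-normalized model values exactly.
#'
#' @param traj_control,traj_scenario `nfkb_trajectory` objects covering all
#'   requested time points.
#' @param assay One of `"p65"`, `"IKK"`, `"totalIkBa"`, `"pIkBa"`.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n Replicates per time point (defaults to the assay's spec).
#' @param seed Integer seed.
#' @return List with tidy data frames `control` and `scenario`
#'   (`assay, cell_type, time_min, replicate, value`) plus the `spec` used;
#'   regeneration with the same seed is bit-identical.
#' @export
generate_assay <- function(traj_control, traj_scenario,
                           assay = c("p65", "IKK", "totalIkBa", "pIkBa"),
                           cv = 0.15, n = NULL, seed = 1) {
  assay <- match.arg(assay)
  spec <- .assay_specs[[assay]]
  if (!is.null(n)) spec$n <- n
  stopifnot(inherits(traj_control, "nfkb_trajectory"),
            inherits(traj_scenario, "nfkb_trajectory"))
  for (tr in list(traj_control, traj_scenario)) {
    off <- setdiff(spec$times, tr$time)
    if (length(off))
      stop("requested assay time(s) not on trajectory grid: ",
           paste(off, collapse = ", "))
  }
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  draw <- function(traj, cell_type) {
    v <- .state_observable(traj$state, spec$observable)[match(spec$times, traj$time)]
    vals <- rep(v, each = spec$n)
    if (cv > 0) vals <- vals * exp(stats::rnorm(length(vals), 0, sdlog))
    data.frame(assay = assay, cell_type = cell_type,
               time_min = rep(spec$times, each = spec$n),
               replicate = rep(seq_len(spec$n), times = length(spec$times)),
               value = vals)
  }
  ctrl <- draw(traj_control, "control")
  scen <- draw(traj_scenario, "scenario")
  ref <- mean(ctrl$value[ctrl$time_min == spec$reference_time])
  if (!is.finite(ref) || ref == 0)
    stop("control reference mean at t = ", spec$reference_time, " is zero")
  ctrl$value <- ctrl$value / ref
  scen$value <- scen$value / ref
  list(control = ctrl, scenario = scen,
       spec = c(spec, list(cv = cv, seed = seed,
                           noise = "multiplicative lognormal, median 1")))
}

#' Generate a synthetic qPCR Ct table
#'
#' Target-gene Ct values decrease by one cycle per doubling of the transcript
#' level (`Ct = offset - log2(level) + noise`); the reference gene (GAPDH) is
#' stimulus-independent. Noise is additive Gaussian on the Ct scale.
#'
#' @param traj `nfkb_trajectory` containing the mRNA observables.
#' @param genes mRNA species to assay (`IkBat`, `A20t`).
#' @param times Sampling times (must lie on the trajectory grid).
#' @param n Replicates per time point.
#' @param seed Integer seed.
#' @param sd_ct Per-well Ct standard deviation (cycles).
#' @param target_offset,reference_ct Ct calibration offsets (cycles).
#' @return Tidy data frame `gene, time_min, replicate, ct_target,
#'   ct_reference`.
#' @export
generate_qpcr <- function(traj, genes = c("IkBat", "A20t"),
                          times = c(0, 30, 60, 120), n = 3, seed = 1,
                          sd_ct = 0.25, target_offset = 18, reference_ct = 16) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  off <- setdiff(times, traj$time)
  if (length(off))
    stop("requested qPCR time(s) not on trajectory grid: ",
         paste(off, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(genes, function(g) {
    lev <- .state_observable(traj$state, g)[match(times, traj$time)]
    if (any(lev <= 0))
      stop("nonpositive transcript level for ", g, "; Ct undefined")
    data.frame(gene = g, time_min = rep(times, each = n),
               replicate = rep(seq_len(n), times = length(times)),
               ct_target = rep(target_offset - log2(lev), each = n) +
                 stats::rnorm(n * length(times), 0, sd_ct),
               ct_reference = reference_ct +
                 stats::rnorm(n * length(times), 0, sd_ct))
  }))
  rownames(out) <- NULL
  out
}
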