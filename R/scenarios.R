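# Hypothesized modes of constitutive Hsp72 regulation, encoded as
# multiplicative factors on rate constants and/or initial pools. Factors are
# applied before equilibration; an empty scenario is the nominal model.

#' Construct a perturbation scenario
#'
#' @param name Scenario name.
#' @param rates Named numeric vector of strictly positive multiplicative
#'   factors on rate constants (empty for none).
#' @param pools Named numeric vector of strictly positive multiplicative
#'   factors on initial pools (`NFkB_total`, `IKK_total`).
#' @param provenance Free text: which figure/table the scenario reproduces.
#' @return Object of class `nfkb_scenario`.
#' @export
scenario <- function(name, rates = numeric(0), pools = numeric(0),
                     provenance = "") {
  rates <- unlist(rates)
  pools <- unlist(pools)
  if (length(rates) && (is.null(names(rates)) || any(rates <= 0)))
    stop("rate factors must be named and strictly positive")
  if (length(pools) && (is.null(names(pools)) || any(pools <= 0)))
    stop("pool factors must be named and strictly positive")
  structure(list(name = name, rates = rates, pools = pools,
                 provenance = provenance), class = "nfkb_scenario")
}

#' @export
print.nfkb_scenario <- function(x, ...) {
  fmt <- function(v) if (!length(v)) "(none)" else
    paste(sprintf("%s x %.4g", names(v), v), collapse = ", ")
  cat(sprintf("<nfkb_scenario> %s\n  rates: %s\n  pools: %s\n  provenance: %s\n",
              x$name, fmt(x$rates), fmt(x$pools), x$provenance))
  invisible(x)
}

#' Apply a scenario to parameters and pools
#'
#' Multiplicative application before equilibration; entries not named in the
#' scenario are returned bit-identical.
#'
#' @param params,pools Nominal parameters and pools.
#' @param scn `nfkb_scenario`.
#' @return List with perturbed `params` and `pools`.
#' @export
apply_scenario <- function(params, pools, scn) {
  stopifnot(inherits(scn, "nfkb_scenario"))
  validate_parameters(params)
  pools <- validate_pools(pools)
  bad <- setdiff(names(scn$rates), names(params))
  if (length(bad))
    stop("unknown rate name(s) in scenario: ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(params), collapse = ", "))
  bad <- setdiff(names(scn$pools), names(pools))
  if (length(bad))
    stop("unknown pool name(s) in scenario: ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(pools), collapse = ", "))
  for (nm in names(scn$rates)) params[[nm]] <- params[[nm]] * scn$rates[[nm]]
  for (nm in names(scn$pools)) pools[[nm]] <- pools[[nm]] * scn$pools[[nm]]
  list(params = params, pools = pools)
}

#' Invert a scenario
#'
#' @param scn `nfkb_scenario`.
#' @return Scenario with reciprocal factors; applying a scenario and then its
#'   inverse restores the nominal model.
#' @export
inverse_scenario <- function(scn) {
  stopifnot(inherits(scn, "nfkb_scenario"))
  scenario(paste0(scn$name, "_inverse"), rates = 1 / scn$rates,
           pools = 1 / scn$pools, provenance = scn$provenance)
}

#' The scenario catalog
#'
#' Every hypothesized mode of Hsp72 regulation evaluated in the analysis, as
#' named multiplicative perturbations: single-rate scans of the IKK module
#' (ka, kp, ki, kiA20), of IkBa phosphorylation (kc2a) and of the
#' ubiquitin/proteasome chain (kua1, kuc1, kupd), reduced IkBa translation
#' (c2a), reduced initial NF-kB and IKK pools, and the combined scenarios.
#' Hypothetical kp/ki/kiA20 scans use dyadic factors over \[1/16, 16\].
#'
#' @return Named list of `nfkb_scenario` objects; each entry's provenance
#'   cites the figure it reproduces.
#' @export
scenario_catalog <- function() {
  sc <- list(scenario("nominal", provenance = "unperturbed control model"))
  dy <- c(2, 4, 8, 16)
  lab <- function(x) gsub("\\.", "p", format(x, trim = TRUE))
  for (f in 1 / dy)
    sc <- c(sc, list(scenario(sprintf("Fig3A_ka_1_%d", round(1 / f)),
                              rates = c(ka = f), provenance = "Fig 3A / Fig S2A / Fig S6A ka scan")))
  for (f in 1 / dy)
    sc <- c(sc, list(scenario(sprintf("FigS2B_kp_1_%d", round(1 / f)),
                              rates = c(kp = f), provenance = "Fig S2B kp decrease scan")))
  for (f in dy)
    sc <- c(sc, list(scenario(sprintf("FigS2C_ki_%dx", f),
                              rates = c(ki = f), provenance = "Fig S2C ki increase scan")))
  for (f in dy)
    sc <- c(sc, list(scenario(sprintf("FigS2D_kiA20_%dx", f),
                              rates = c(kiA20 = f), provenance = "Fig S2D kiA20 increase scan")))
  for (d in c(5, 6, 10, 32))
    sc <- c(sc, list(scenario(sprintf("Fig3B_kc2a_1_%d", d),
                              rates = c(kc2a = 1 / d),
                              provenance = "Fig 3B / Fig S3A / Fig S6B kc2a scan")))
  for (d in dy) {
    sc <- c(sc, list(
      scenario(sprintf("FigS3C_kua1_1_%d", d), rates = c(kua1 = 1 / d),
               provenance = "Fig S3C kua1 decrease scan"),
      scenario(sprintf("FigS3D_kuc1_1_%d", d), rates = c(kuc1 = 1 / d),
               provenance = "Fig S3D kuc1 decrease scan"),
      scenario(sprintf("FigS3B_kupd_1_%d", d), rates = c(kupd = 1 / d),
               provenance = "Fig S3B kupd decrease scan")))
  }
  sc <- c(sc, list(
    scenario("Fig4A_c2a_1_30", rates = c(c2a = 1 / 30),
             provenance = "Fig 4A / Fig S6C: IkBa translation reduced to 1/30"),
    scenario("Fig5A_pool70", pools = c(NFkB_total = 0.70),
             provenance = "Fig 5A / Fig S7A: total p65 reduced to 70%"),
    scenario("FigS4A_IKKn_1_8", pools = c(IKK_total = 1 / 8),
             provenance = "Fig S4A: total IKK reduced to 1/8"),
    scenario("IKKn_0p055", pools = c(IKK_total = 0.055),
             provenance = "total IKK reduced to 5.5% (component of Fig 5B)"),
    scenario("IKKn_1_18", pools = c(IKK_total = 1 / 18),
             provenance = "total IKK reduced to 1/18 (component of Fig S7B)"),
    scenario("Fig5B_combined",
             pools = c(NFkB_total = 0.70, IKK_total = 0.055),
             provenance = "Fig 5B: p65 70% + total IKK 5.5%"),
    scenario("Fig6A_combined", rates = c(kiA20 = 10, kc2a = 1 / 6),
             pools = c(NFkB_total = 0.70),
             provenance = "Fig 5C / Fig 6A / Fig S7C: p65 70% + kiA20 x10 + kc2a /6"),
    scenario("FigS5_pool70_kiA20_10x", rates = c(kiA20 = 10),
             pools = c(NFkB_total = 0.70),
             provenance = "Fig S5: p65 70% + upstream kiA20 x10"),
    scenario("FigS4C_pool70_kc2a_1_10", rates = c(kc2a = 1 / 10),
             pools = c(NFkB_total = 0.70),
             provenance = "Fig S4C: p65 70% + downstream kc2a /10 only"),
    scenario("FigS4B_IKKn_1_8_kc2a_1_5", rates = c(kc2a = 1 / 5),
             pools = c(IKK_total = 1 / 8),
             provenance = "Fig S4B: total IKK 1/8 + kc2a /5"),
    scenario("FigS7B_pool70_IKKn_1_18", pools = c(NFkB_total = 0.70, IKK_total = 1 / 18),
             provenance = "Fig S7B: p65 70% + total IKK 1/18")))
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

#' Write the scenario catalog to JSON
#'
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_catalog <- function(file) {
  cat_ <- scenario_catalog()
  jsonlite::write_json(
    lapply(cat_, function(s) list(name = s$name, rates = as.list(s$rates),
                                  pools = as.list(s$pools),
                                  provenance = s$provenance)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Classify a scenario against the plausibility criteria
#'
#' A scenario is plausible as a complete account of the Hsp72 phenotype iff,
#' relative to the nominal run, it (i) reduces basal (pre-stimulus) total
#' IkBa, (ii) reduces peak IKK activity, (iii) reduces peak free nuclear
#' NF-kB, and (iv) leaves basal free nuclear NF-kB within a tolerance band of
#' nominal (unstimulated NF-kB activity is experimentally unchanged).
#' "Reduces" means the scenario/nominal ratio falls below
#' `reduction_threshold`.
#'
#' @param scn `nfkb_scenario` being judged.
#' @param nominal_run,scenario_run `nfkb_trajectory` objects on the same grid
#'   with the same solver settings.
#' @param reduction_threshold Ratio below which a readout counts as reduced.
#' @param basal_band Half-width of the relative band within which basal
#'   nuclear NF-kB counts as preserved.
#' @return Object of class `nfkb_verdict`: the four boolean checks with the
#'   numeric ratios behind them, the overall label, and any failed criteria.
#' @export
evaluate_scenario <- function(scn, nominal_run, scenario_run,
                              reduction_threshold = 0.95, basal_band = 0.15) {
  stopifnot(inherits(nominal_run, "nfkb_trajectory"),
            inherits(scenario_run, "nfkb_trajectory"))
  if (!isTRUE(all.equal(nominal_run$time, scenario_run$time)))
    stop("nominal and scenario runs must share the same time grid")
  if (!identical(nominal_run$meta$solver, scenario_run$meta$solver))
    stop("nominal and scenario runs must share solver settings")

  ratio <- function(obs, basal = FALSE) {
    a <- observable(scenario_run, obs)
    b <- observable(nominal_run, obs)
    if (basal) a$value[1L] / b$value[1L] else
      peak(a)$amplitude / peak(b)$amplitude
  }
  ratios <- c(basal_total_IkBa = ratio("total_IkBa", basal = TRUE),
              peak_IKKa = ratio("IKKa"),
              peak_NFkBn = ratio("NFkBn"),
              basal_NFkBn = ratio("NFkBn", basal = TRUE))
  checks <- c(
    reduces_basal_total_IkBa = ratios[["basal_total_IkBa"]] < reduction_threshold,
    reduces_peak_IKKa = ratios[["peak_IKKa"]] < reduction_threshold,
    reduces_peak_nuclear_NFkB = ratios[["peak_NFkBn"]] < reduction_threshold,
    preserves_basal_NFkB_activity =
      abs(ratios[["basal_NFkBn"]] - 1) <= basal_band)
  structure(list(scenario = scn$name, ratios = ratios, checks = checks,
                 plausible = all(checks),
                 failed = names(checks)[!checks],
                 settings = list(reduction_threshold = reduction_threshold,
                                 basal_band = basal_band)),
            class = "nfkb_verdict")
}

#' @export
print.nfkb_verdict <- function(x, ...) {
  cat(sprintf("<nfkb_verdict> %s: %s\n", x$scenario,
              if (x$plausible) "plausible" else "implausible"))
  for (nm in names(x$checks))
    cat(sprintf("  %-30s %-5s (ratio %.3f)\n", nm, x$checks[[nm]],
                x$ratios[[c(reduces_basal_total_IkBa = "basal_total_IkBa",
                            reduces_peak_IKKa = "peak_IKKa",
                            reduces_peak_nuclear_NFkB = "peak_NFkBn",
                            preserves_basal_NFkB_activity = "basal_NFkBn")[[nm]]]]))
  invisible(x)
}
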