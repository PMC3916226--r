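#' @importFrom jsonlite read_json write_json
NULL

.param_cache <- new.env(parent = emptyenv())

.read_manifest <- function() {
  if (is.null(.param_cache$manifest)) {
    path <- system.file("extdata", "parameters.json", package = "nfkbsim")
    if (!nzchar(path)) stop("parameter manifest not found in installed package")
    .param_cache$manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .param_cache$manifest
}

#' Parameter provenance manifest
#'
#' Returns the full machine-readable manifest shipped with the package: for
#' every rate constant and initial pool, its nominal value, units, biological
#' description and provenance (canonical Lipniacki-family value, O'Dea-adjusted
#' turnover rate, or assigned during calibration).
#'
#' @return A nested list mirroring `inst/extdata/parameters.json`.
#' @export
parameter_manifest <- function() .read_manifest()

#' Nominal rate constants
#'
#' The nominal parameter set of the NF-kB network model: one named nonnegative
#' scalar per rate constant. Concentrations are in uM and all rates are per
#' minute (second-order rates per uM per minute). See [parameter_manifest()]
#' for the meaning and provenance of each rate.
#'
#' @return Named numeric vector of rate constants.
#' @export
default_parameters <- function() {
  m <- .read_manifest()
  vapply(m$parameters, function(x) x$value, numeric(1))
}

#' Nominal initial pools
#'
#' The two conserved protein pools that seed the model before equilibration:
#' `NFkB_total` (initialized entirely as cytoplasmic IkBa:NF-kB complex) and
#' `IKK_total` (initialized as neutral IKK). All other species start at zero.
#'
#' @return Named numeric vector with elements `NFkB_total` and `IKK_total`.
#' @export
default_pools <- function() {
  m <- .read_manifest()
  vapply(m$pools, function(x) x$value, numeric(1))
}

#' Validate a parameter set
#'
#' @param params Named numeric vector of rate constants.
#' @return `params`, invisibly, after validation.
#' @export
validate_parameters <- function(params) {
  if (!is.numeric(params) || is.null(names(params)) || any(!nzchar(names(params))))
    stop("parameters must be a fully named numeric vector")
  need <- names(default_parameters())
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing rate constants: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), need)
  if (length(extra))
    stop("unknown rate constants: ", paste(extra, collapse = ", "),
         "; valid names are: ", paste(need, collapse = ", "))
  if (any(!is.finite(params)) || any(params < 0))
    stop("all rate constants must be finite and nonnegative")
  invisible(params)
}

#' Validate initial pools
#'
#' @param pools Named numeric vector with elements `NFkB_total`, `IKK_total`.
#' @return `pools`, invisibly, after validation.
#' @export
validate_pools <- function(pools) {
  need <- c("NFkB_total", "IKK_total")
  if (!is.numeric(pools) || !setequal(names(pools), need))
    stop("pools must be a named numeric vector with elements: ",
         paste(need, collapse = ", "))
  if (any(!is.finite(pools)) || any(pools < 0))
    stop("pools must be finite and nonnegative")
  invisible(pools[need])
}

#' Write parameters and pools to JSON
#'
#' Flat key/value serialization that round-trips losslessly (full double
#' precision).
#'
#' @param params Named numeric vector of rate constants.
#' @param pools Named numeric vector of initial pools.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_parameters <- function(params, pools, file) {
  validate_parameters(params)
  pools <- validate_pools(pools)
  jsonlite::write_json(list(parameters = as.list(params), pools = as.list(pools)),
                       file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' Read parameters and pools from JSON
#'
#' @param file Path written by [write_parameters()].
#' @return List with elements `params` and `pools` (named numeric vectors).
#' @export
read_parameters <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  params <- unlist(x$parameters)
  pools <- unlist(x$pools)
  validate_parameters(params)
  pools <- validate_pools(pools)
  list(params = params, pools = pools)
}

.params_digest <- function(params, pools) {
  txt <- paste(c(names(params), sprintf("%.17g", params),
                 names(pools), sprintf("%.17g", pools)), collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
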