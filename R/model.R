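# Network structure
#
# IKK module (three interconverting forms, conserved total):
#   IKKn --ka*TNF--> IKKa --(ki + kiA20*A20)--> IKKi --kp--> IKKn
# Downstream module: free and NF-kB-bound IkBa are phosphorylated by IKKa
# (kc1a / kc2a), then pass through E3-ligase engagement (kua1) and
# poly-ubiquitination (kuc1) to proteasomal degradation (kupd); degradation of
# a complexed IkBa releases NF-kB. Two structural modifications relative to
# the canonical network: tagged intermediates also decay constitutively (kdp),
# and the cytoplasmic IkBa:NF-kB complex can be imported into the nucleus
# (i2a). Free nuclear NF-kB drives transcription of IkBa and A20 mRNAs; A20
# protein feeds back on IKK inactivation; IkBa protein re-sequesters NF-kB.

.species <- c(
  "IKKn", "IKKa", "IKKi",
  "IkBa", "pIkBa", "pIkBaE3", "pIkBaUb",
  "NFkB",
  "IkBaNFkB", "pIkBaNFkB", "pIkBaE3NFkB", "pIkBaUbNFkB",
  "NFkBn", "IkBan", "IkBaNFkBn",
  "IkBat", "A20t", "A20"
)

.nfkb_species <- c("NFkB", "IkBaNFkB", "pIkBaNFkB", "pIkBaE3NFkB",
                   "pIkBaUbNFkB", "NFkBn", "IkBaNFkBn")
.ikk_species <- c("IKKn", "IKKa", "IKKi")
.ikba_species <- c("IkBa", "pIkBa", "pIkBaE3", "pIkBaUb", "IkBan",
                   "IkBaNFkB", "pIkBaNFkB", "pIkBaE3NFkB", "pIkBaUbNFkB",
                   "IkBaNFkBn")
.tagged_species <- c("pIkBa", "pIkBaE3", "pIkBaUb",
                     "pIkBaNFkB", "pIkBaE3NFkB", "pIkBaUbNFkB")

#' Model species names
#'
#' The fixed state-vector ordering of the model's 18 dynamic species. The TNF
#' stimulus is a binary input, not a dynamic species.
#'
#' @return Character vector of species names, in state order.
#' @export
species_names <- function() .species

# deSolve-facing derivative; parms = list(p = <list of rates>, stimulus = 0/1)
.nfkb_deriv <- function(t, y, parms) {
  p <- parms$p
  TNF <- parms$stimulus

  IKKn <- y[1L]; IKKa <- y[2L]; IKKi <- y[3L]
  IkBa <- y[4L]; pIkBa <- y[5L]; pIkBaE3 <- y[6L]; pIkBaUb <- y[7L]
  NFkB <- y[8L]
  C <- y[9L]; pC <- y[10L]; peC <- y[11L]; puC <- y[12L]
  NFkBn <- y[13L]; IkBan <- y[14L]; Cn <- y[15L]
  IkBat <- y[16L]; A20t <- y[17L]; A20 <- y[18L]

  act <- p$ka * TNF * IKKn
  inact <- (p$ki + p$kiA20 * A20) * IKKa

  dIKKn <- -act + p$kp * IKKi
  dIKKa <- act - inact
  dIKKi <- inact - p$kp * IKKi

  bind_c <- p$a4 * IkBa * NFkB
  bind_n <- p$a4 * IkBan * NFkBn
  phos_f <- p$kc1a * IKKa * IkBa
  phos_c <- p$kc2a * IKKa * C

  dIkBa <- p$c2a * IkBat - p$c5a * IkBa - phos_f - bind_c + p$d4 * C -
    p$i1a * IkBa + p$e1a * IkBan
  dpIkBa <- phos_f - (p$kua1 + p$kdp) * pIkBa
  dpIkBaE3 <- p$kua1 * pIkBa - (p$kuc1 + p$kdp) * pIkBaE3
  dpIkBaUb <- p$kuc1 * pIkBaE3 - (p$kupd + p$kdp) * pIkBaUb

  release <- p$kupd * puC + p$kdp * (pC + peC + puC) + p$c6a * C
  dNFkB <- release + p$d4 * C - bind_c - p$i1 * NFkB

  dC <- bind_c - (p$d4 + p$c6a) * C - phos_c - p$i2a * C + p$e2a * Cn
  dpC <- phos_c - (p$kua1 + p$kdp) * pC
  dpeC <- p$kua1 * pC - (p$kuc1 + p$kdp) * peC
  dpuC <- p$kuc1 * peC - (p$kupd + p$kdp) * puC

  dNFkBn <- p$i1 * NFkB - bind_n + p$d4 * Cn
  dIkBan <- p$i1a * IkBa - p$e1a * IkBan - bind_n + p$d4 * Cn - p$c5a * IkBan
  dCn <- bind_n - p$d4 * Cn - p$e2a * Cn + p$i2a * C

  dIkBat <- p$c1a * NFkBn - p$c3a * IkBat
  dA20t <- p$c1 * NFkBn - p$c3 * A20t
  dA20 <- p$c2 * A20t - p$c5 * A20

  list(c(dIKKn, dIKKa, dIKKi,
         dIkBa, dpIkBa, dpIkBaE3, dpIkBaUb,
         dNFkB,
         dC, dpC, dpeC, dpuC,
         dNFkBn, dIkBan, dCn,
         dIkBat, dA20t, dA20))
}

#' Model right-hand side
#'
#' Time derivative of every dynamic species at a given state. The TNF stimulus
#' enters only through the IKK activation flux `ka * TNF * IKKn`, so with
#' `stimulus_on = FALSE` that flux is identically zero. Total NF-kB (summed
#' over all NF-kB-containing species) and total IKK (IKKn + IKKa + IKKi) carry
#' zero net derivative: both pools are conserved.
#'
#' @param state Named numeric vector over [species_names()] (order-free; it is
#'   matched by name), finite and nonnegative.
#' @param params Named numeric vector of rate constants (see
#'   [default_parameters()]).
#' @param stimulus_on Logical; whether the TNF input is present.
#' @return Named numeric vector of per-species derivatives (concentration/min).
#' @export
rhs <- function(state, params, stimulus_on = TRUE) {
  validate_parameters(params)
  if (!is.numeric(state) || is.null(names(state)))
    stop("state must be a named numeric vector")
  if (!setequal(names(state), .species))
    stop("state must contain exactly the species in species_names()")
  if (any(!is.finite(state)))
    stop("state contains non-finite concentrations")
  if (any(state < 0))
    stop("state contains negative concentrations: ",
         paste(names(state)[state < 0], collapse = ", "))
  y <- state[.species]
  d <- .nfkb_deriv(0, unname(y), list(p = as.list(params),
                                      stimulus = as.numeric(isTRUE(stimulus_on))))[[1L]]
  names(d) <- .species
  d
}

#' Initial state before equilibration
#'
#' Builds the pre-equilibration state: the total NF-kB pool entirely as
#' cytoplasmic IkBa:NF-kB complex, the total IKK pool as neutral IKK, and all
#' other species at zero.
#'
#' @param pools Named numeric vector (`NFkB_total`, `IKK_total`).
#' @return Named numeric state vector in species order.
#' @export
initial_state <- function(pools = default_pools()) {
  pools <- validate_pools(pools)
  y <- stats::setNames(numeric(length(.species)), .species)
  y["IkBaNFkB"] <- pools[["NFkB_total"]]
  y["IKKn"] <- pools[["IKK_total"]]
  y
}

#' Conserved totals of a state or trajectory state matrix
#'
#' @param x Named state vector, or a state matrix with species columns.
#' @return Named vector (or matrix) with `NFkB_total` and `IKK_total`.
#' @export
conserved_totals <- function(x) {
  if (is.matrix(x)) {
    cbind(NFkB_total = rowSums(x[, .nfkb_species, drop = FALSE]),
          IKK_total = rowSums(x[, .ikk_species, drop = FALSE]))
  } else {
    c(NFkB_total = sum(x[.nfkb_species]), IKK_total = sum(x[.ikk_species]))
  }
}
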