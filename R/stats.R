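# The statistical battery applied per time point to replicate assay data:
# one-way ANOVA across cell types, Newman-Keuls stepwise post hoc comparisons
# (gated on a significant omnibus test), a one-sample t-test against unity
# for data already normalized to the control group, and delta-delta-Ct fold
# changes for qPCR tables. Tests are two-sided throughout.

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from the definitional sums of
#' squares: `F = MSB / MSW` with the p-value from the F distribution.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 replicates.
#' @return List with `F`, `p`, `df` (numerator, denominator), `msw` (within
#'   mean square) and `group_n`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least 2 numeric vectors")
  n <- lengths(groups)
  if (any(n < 2)) stop("every group needs at least 2 replicates")
  x <- unlist(groups, use.names = FALSE)
  N <- sum(n)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  gm <- mean(x)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (msw == 0) {
    # degenerate: zero within-group variance
    if (ssb == 0) return(list(F = 0, p = 1, df = c(k - 1, N - k),
                              msw = 0, group_n = n))
    return(list(F = Inf, p = 0, df = c(k - 1, N - k), msw = 0, group_n = n))
  }
  f <- msb / msw
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k), msw = msw, group_n = n)
}

#' Newman-Keuls stepwise multiple comparisons
#'
#' Student-Newman-Keuls procedure on ordered group means: the span of r
#' ordered means is declared different when its studentized range
#' `(max - min) / sqrt(MSW / n_h)` exceeds `q(1 - alpha, r, df_within)`,
#' where `n_h` is the harmonic mean of the two compared groups' sizes
#' (groups here are balanced; the harmonic-mean rule covers unbalanced
#' input). Non-significant spans block all comparisons nested inside them,
#' and the whole procedure is gated on a significant omnibus ANOVA.
#'
#' @param groups Named or unnamed list of numeric replicate vectors.
#' @param alpha Significance level.
#' @param gate_on_anova Return all-FALSE when the omnibus ANOVA p exceeds
#'   `alpha` (the convention used here).
#' @return Symmetric logical matrix of pairwise significance flags.
#' @export
newman_keuls <- function(groups, alpha = 0.05, gate_on_anova = TRUE) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  an <- anova_oneway(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  if (gate_on_anova && an$p > alpha) return(sig)
  if (an$msw == 0) {
    # all variation is between groups: distinct means are trivially different
    means <- vapply(groups, mean, numeric(1))
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- sig[j, i] <- means[i] != means[j]
    return(sig)
  }
  ord <- order(vapply(groups, mean, numeric(1)))
  means <- vapply(groups, mean, numeric(1))[ord]
  ns <- lengths(groups)[ord]
  dfw <- an$df[2]
  # blocked[a, b] (positions in the ordered sequence): comparison suppressed
  blocked <- matrix(FALSE, k, k)
  for (r in k:2) {
    for (a in 1:(k - r + 1)) {
      b <- a + r - 1
      if (blocked[a, b]) next
      nh <- 2 / (1 / ns[a] + 1 / ns[b])
      q_obs <- (means[b] - means[a]) / sqrt(an$msw / nh)
      if (q_obs > stats::qtukey(1 - alpha, r, dfw)) {
        i <- ord[a]; j <- ord[b]
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        # block every comparison nested within this span
        for (aa in a:b) for (bb in aa:b) blocked[aa, bb] <- TRUE
      }
    }
  }
  sig
}

#' One-sample t-test against unity
#'
#' Two-sided Student t-test of the null hypothesis that the mean is 1, for
#' measurements already normalized to the control group.
#'
#' @param values Numeric vector with >= 2 values and nonzero variance.
#' @return List with `t`, `p`, `df` and `mean`.
#' @export
one_sample_t_vs_unity <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("zero variance: the t statistic against unity is undefined")
  ht <- stats::t.test(values, mu = 1)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = mean(values))
}

#' Delta-delta-Ct fold changes
#'
#' Relative quantification of a qPCR table: per replicate,
#' `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean `dCt` of the
#' reference sample (per gene), and the fold change is `2^(-ddCt)`.
#'
#' @param ct_table Data frame from [generate_qpcr()] (columns `gene`,
#'   `time_min`, `replicate`, `ct_target`, `ct_reference`).
#' @param reference_time Reference sample time (defaults to 0 min).
#' @return The table with added columns `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct_table, reference_time = 0) {
  need <- c("gene", "time_min", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  if (!reference_time %in% ct_table$time_min)
    stop("reference_time ", reference_time, " absent from ct_table")
  ct_table$dct <- ct_table$ct_target - ct_table$ct_reference
  ref <- tapply(ct_table$dct[ct_table$time_min == reference_time],
                ct_table$gene[ct_table$time_min == reference_time], mean)
  ct_table$ddct <- ct_table$dct - as.vector(ref[as.character(ct_table$gene)])
  ct_table$fold_change <- 2^(-ct_table$ddct)
  ct_table
}

#' Per-time-point group comparison battery
#'
#' Applies one-way ANOVA and the Newman-Keuls post hoc test independently at
#' each time point of a tidy replicate dataset (each time point uses
#' independently harvested cells, so no correction is applied across times).
#'
#' @param data Tidy data frame with columns `cell_type`, `time_min`, `value`.
#' @param alpha Significance level.
#' @return List, one element per time point: `time`, `F`, `p`, and the
#'   pairwise Newman-Keuls significance matrix.
#' @export
compare_groups <- function(data, alpha = 0.05) {
  need <- c("cell_type", "time_min", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  lapply(split(data, data$time_min), function(d) {
    groups <- split(d$value, d$cell_type)
    an <- anova_oneway(groups)
    list(time = d$time_min[1L], F = an$F, p = an$p,
         pairwise = newman_keuls(groups, alpha = alpha))
  })
}
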