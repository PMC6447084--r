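#' Proportion of exposure variance explained by an instrument set
#'
#' For independent biallelic variants and a standardized trait,
#' `R^2 = sum_j 2 p_j (1 - p_j) beta_j^2`, with `p_j` the effect-allele
#' frequency and `beta_j` the per-allele effect in trait SD units.
#'
#' @param betas Numeric vector of per-allele effects (SD units).
#' @param eafs Numeric vector of effect-allele frequencies, same length,
#'   each in (0,1).
#' @return The proportion of variance explained (0 for empty input).
#' @examples
#' variance_explained(0.1, 0.5)  # 2 * 0.25 * 0.01 = 0.005
#' @export
variance_explained <- function(betas, eafs) {
  if (length(betas) != length(eafs)) {
    abort("betas and eafs must have equal length")
  }
  if (length(betas) == 0) return(0)
  stopifnot(all(eafs > 0 & eafs < 1))
  sum(2 * eafs * (1 - eafs) * betas^2)
}

#' Analytic power for MR with a continuous outcome
#'
#' Asymptotic two-sided test approximation: with `n_outcome` outcome-study
#' samples and an instrument explaining `r2` of the exposure variance, the
#' IVW z statistic for a true effect of `effect` SD outcome change per SD
#' exposure has noncentrality `|effect| sqrt(n_outcome * r2)`, giving
#' `power = Phi(|effect| sqrt(n_outcome * r2) - z_{1 - alpha/2})`.
#' At the null the value is `alpha / 2` (one tail of the two-sided test).
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param r2 Proportion of exposure variance explained by the instrument,
#'   in (0,1).
#' @param effect True causal effect, SD change per exposure SD.
#' @param alpha Significance threshold (default 0.05).
#' @return Power in (0,1). Vectorized over all arguments.
#' @export
power_continuous <- function(n_outcome, r2, effect, alpha = 0.05) {
  stopifnot(all(n_outcome > 0), all(r2 > 0 & r2 < 1), all(alpha > 0 & alpha < 1))
  pnorm(abs(effect) * sqrt(n_outcome * r2) - qnorm(1 - alpha / 2))
}

#' Analytic power for MR with a binary outcome
#'
#' As [power_continuous()], on the log-odds scale: for a true odds ratio
#' `effect` and case fraction `f` in the outcome study,
#' `power = Phi(|ln(effect)| sqrt(n_outcome * r2 * f (1 - f)) - z_{1 - alpha/2})`.
#'
#' @inheritParams power_continuous
#' @param effect True odds ratio per SD of exposure (must be positive).
#' @param case_fraction Proportion of cases in the outcome study, in (0,1).
#' @return Power in (0,1). Vectorized.
#' @export
power_binary <- function(n_outcome, r2, effect, case_fraction, alpha = 0.05) {
  if (any(effect <= 0)) abort("odds ratio must be positive")
  stopifnot(all(n_outcome > 0), all(r2 > 0 & r2 < 1),
            all(case_fraction > 0 & case_fraction < 1),
            all(alpha > 0 & alpha < 1))
  nc <- abs(log(effect)) * sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  pnorm(nc - qnorm(1 - alpha / 2))
}

#' Power table over a grid of designs
#'
#' Expands the full grid of sample sizes, variance explained and effect sizes
#' and computes analytic power for each cell, mirroring the per-outcome power
#' columns of a study design table.
#'
#' @param n_outcome,r2,effect Numeric vectors defining the grid.
#' @param case_fraction `NULL` for continuous outcomes, otherwise a scalar or
#'   vector of case fractions added to the grid (effects are then odds
#'   ratios).
#' @param alpha Significance threshold.
#' @return A tibble, one row per grid cell, with a `power` column.
#' @export
power_grid <- function(n_outcome, r2, effect, case_fraction = NULL,
                       alpha = 0.05) {
  if (is.null(case_fraction)) {
    g <- tidyr::expand_grid(n_outcome = n_outcome, r2 = r2, effect = effect)
    g$outcome_type <- "continuous"
    g$power <- power_continuous(g$n_outcome, g$r2, g$effect, alpha)
  } else {
    g <- tidyr::expand_grid(n_outcome = n_outcome, r2 = r2, effect = effect,
                            case_fraction = case_fraction)
    g$outcome_type <- "binary"
    g$power <- power_binary(g$n_outcome, g$r2, g$effect, g$case_fraction, alpha)
  }
  g$alpha <- alpha
  g
}
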