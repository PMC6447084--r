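#' Derive a sub-stream seed from the root seed
#'
#' One root seed, deterministic per-table streams: each table draws under
#' `(seed * 48271 + offset) mod (2^31 - 1)`, so regenerating one table never
#' perturbs another.
#' @noRd
.derive_seed <- function(seed, offset) {
  # exact in doubles: |seed| < 2^31 so seed * 48271 + offset < 2^53
  as.integer(((abs(as.double(seed)) * 48271 + offset * 7919) %% 2147483629) + 1)
}

#' Simulation configuration for two-sample GWAS summary statistics
#'
#' Defaults emulate the study conditions of a birthweight-style two-sample MR:
#' 46 independent instruments explaining 2.2% of the exposure variance,
#' exposure GWAS of 150,000 samples, outcome GWAS of 100,000 samples, and a
#' true causal effect of 0.15 SD per exposure SD.
#'
#' @param n_variants Number of independent instruments (default 46).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 150000, 100000).
#' @param r2_target Exposure variance explained by the instrument set
#'   (default 0.022).
#' @param theta_true True causal effect: SD per SD for continuous outcomes,
#'   log odds ratio per exposure SD when `binary_outcome = TRUE`
#'   (default 0.15).
#' @param pleiotropy_mode `"none"` (default), `"balanced"` (zero-mean direct
#'   effects), `"directional"` (mean `pleiotropy_mean`), or
#'   `"inside_violating"` (direct effects proportional to instrument
#'   strength, breaking the InSIDE assumption).
#' @param pleiotropy_mean,pleiotropy_sd Location and spread of per-variant
#'   direct effects on the outcome (outcome units per allele).
#' @param prop_invalid Fraction of variants carrying a pleiotropic effect;
#'   default 0 under `"none"`, 1 otherwise.
#' @param eaf_range Interval the effect-allele frequencies are drawn from
#'   (default `c(0.1, 0.9)`).
#' @param effect_profile `"equal"` (each variant explains `r2_target /
#'   n_variants`; default) or `"decay"` (exponentially decaying
#'   contributions, still summing to `r2_target`).
#' @param binary_outcome Simulate a case-control outcome on the log-odds
#'   scale (default `FALSE`).
#' @param case_fraction Case proportion of the binary outcome study
#'   (default 0.33).
#' @param flip_fraction Fraction of outcome records written with swapped
#'   allele order (beta negated, frequency complemented), to exercise
#'   harmonization (default 0.25).
#' @param seed Root seed; every draw is a deterministic function of it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 46, n_exposure = 150000, n_outcome = 100000,
                       r2_target = 0.022, theta_true = 0.15,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       prop_invalid = NULL, eaf_range = c(0.1, 0.9),
                       effect_profile = c("equal", "decay"),
                       binary_outcome = FALSE, case_fraction = 0.33,
                       flip_fraction = 0.25, seed = 1) {
  pleiotropy_mode <- arg_match(pleiotropy_mode)
  effect_profile <- arg_match(effect_profile)
  if (is.null(prop_invalid)) {
    prop_invalid <- if (pleiotropy_mode == "none") 0 else 1
  }
  stopifnot(n_variants >= 2, n_exposure > 0, n_outcome > 0,
            prop_invalid >= 0, prop_invalid <= 1,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            pleiotropy_sd >= 0,
            case_fraction > 0, case_fraction < 1,
            flip_fraction >= 0, flip_fraction <= 1)
  if (!(r2_target > 0 && r2_target < 1)) {
    abort("r2_target must lie in (0,1): not attainable as a variance proportion")
  }
  structure(list(
    n_variants = as.integer(n_variants), n_exposure = n_exposure,
    n_outcome = n_outcome, r2_target = r2_target, theta_true = theta_true,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, prop_invalid = prop_invalid,
    eaf_range = eaf_range, effect_profile = effect_profile,
    binary_outcome = binary_outcome, case_fraction = case_fraction,
    flip_fraction = flip_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Non-palindromic allele pairs for simulated variants
#' @noRd
.draw_alleles <- function(J) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), J, replace = TRUE), , drop = FALSE]
}

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates an exposure table and an outcome table of per-variant association
#' records from non-overlapping samples, plus the generating truth. Per
#' variant: the effect-allele frequency is uniform on `eaf_range`; the true
#' exposure effect is scaled so the set explains exactly `r2_target` of a
#' standardized exposure; the observed exposure beta adds noise with
#' `se = 1 / sqrt(n_exposure * 2 p (1 - p))`; the true outcome effect is
#' `theta_true * beta_x + alpha_j` with the direct (pleiotropic) effect
#' `alpha_j` drawn per `pleiotropy_mode`; the observed outcome beta adds noise
#' with the analogous outcome-scale SE (binary outcomes: log-odds scale,
#' `se = 1 / sqrt(n_outcome * f (1 - f) * 2 p (1 - p))`). Everything is a
#' deterministic function of `config$seed`.
#'
#' @param config A [sim_config()].
#' @param outcome_stream Integer (default 0). Shifts only the outcome-side
#'   random streams (pleiotropy, outcome noise, allele-order flips), so
#'   several outcome studies can share one exposure study: calling with the
#'   same config but different `outcome_stream` values reproduces the exposure
#'   table exactly while drawing independent outcomes.
#' @return A list: `exposure` and `outcome` tibbles in the canonical
#'   [read_summary_stats()] layout, and `truth` — a list with `theta_true`,
#'   `realized_r2` and a per-variant tibble (`variant_id`, `eaf`,
#'   `beta_x_true`, `pleiotropy_effect`, `invalid`).
#' @examples
#' sim <- simulate_two_sample(sim_config(n_variants = 10, seed = 7))
#' sim$truth$realized_r2
#' @export
simulate_two_sample <- function(config, outcome_stream = 0L) {
  stopifnot(outcome_stream >= 0)
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_variants
  ids <- sprintf("rs%04d", seq_len(J))

  # structural draws: frequencies, alleles, effect profile, invalid set
  structural <- withr::with_seed(.derive_seed(config$seed, 1L), {
    eaf <- runif(J, config$eaf_range[1], config$eaf_range[2])
    al <- .draw_alleles(J)
    n_invalid <- round(config$prop_invalid * J)
    invalid <- rep(FALSE, J)
    invalid[sample.int(J, n_invalid)] <- TRUE
    prof <- switch(config$effect_profile,
      equal = rep(1, J),
      decay = exp(-3 * (seq_len(J) - 1) / max(1, J - 1))
    )
    list(eaf = eaf, al = al, invalid = invalid, prof = prof)
  })
  eaf <- structural$eaf
  het <- 2 * eaf * (1 - eaf)
  # per-variant explained variance r2_target * prof_j / sum(prof):
  # 2p(1-p) beta^2 = share_j  =>  beta = sqrt(share_j / 2p(1-p))
  share <- config$r2_target * structural$prof / sum(structural$prof)
  beta_x_true <- sqrt(share / het)

  se_x <- 1 / sqrt(config$n_exposure * het)
  beta_x_obs <- withr::with_seed(.derive_seed(config$seed, 2L),
                                 rnorm(J, beta_x_true, se_x))

  alpha <- rep(0, J)
  if (config$pleiotropy_mode != "none" && any(structural$invalid)) {
    idx <- which(structural$invalid)
    alpha[idx] <- withr::with_seed(.derive_seed(config$seed, 3L + 100L * outcome_stream), {
      switch(config$pleiotropy_mode,
        balanced = rnorm(length(idx), 0, config$pleiotropy_sd),
        directional = rnorm(length(idx), config$pleiotropy_mean,
                            config$pleiotropy_sd),
        inside_violating = config$pleiotropy_mean * beta_x_true[idx] /
          mean(beta_x_true) + rnorm(length(idx), 0, config$pleiotropy_sd)
      )
    })
  }

  gamma_true <- config$theta_true * beta_x_true + alpha
  se_y <- if (config$binary_outcome) {
    1 / sqrt(config$n_outcome * config$case_fraction *
               (1 - config$case_fraction) * het)
  } else {
    1 / sqrt(config$n_outcome * het)
  }
  beta_y_obs <- withr::with_seed(.derive_seed(config$seed, 4L + 100L * outcome_stream),
                                 rnorm(J, gamma_true, se_y))

  exposure <- tibble(
    variant_id = ids,
    effect_allele = structural$al[, 1],
    other_allele = structural$al[, 2],
    eaf = eaf,
    beta = beta_x_obs,
    se = se_x,
    pvalue = 2 * pnorm(-abs(beta_x_obs) / se_x),
    n = config$n_exposure
  )
  outcome <- tibble(
    variant_id = ids,
    effect_allele = structural$al[, 1],
    other_allele = structural$al[, 2],
    eaf = eaf,
    beta = beta_y_obs,
    se = se_y,
    pvalue = 2 * pnorm(-abs(beta_y_obs) / se_y),
    n = config$n_outcome
  )
  if (config$flip_fraction > 0) {
    flip <- withr::with_seed(.derive_seed(config$seed, 5L + 100L * outcome_stream),
                             runif(J) < config$flip_fraction)
    outcome$effect_allele[flip] <- structural$al[flip, 2]
    outcome$other_allele[flip] <- structural$al[flip, 1]
    outcome$beta[flip] <- -outcome$beta[flip]
    outcome$eaf[flip] <- 1 - outcome$eaf[flip]
  }

  truth <- list(
    theta_true = config$theta_true,
    realized_r2 = variance_explained(beta_x_true, eaf),
    variants = tibble(
      variant_id = ids, eaf = eaf, beta_x_true = beta_x_true,
      pleiotropy_effect = alpha, invalid = structural$invalid
    )
  )
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a confounder/disease association table
#'
#' Emulates a lookup of instrument variants in external GWAS of outcome
#' diseases and confounder traits, the input to [select_iv2()]. A chosen
#' fraction of variants is planted with a strongly genome-wide-significant
#' P value (below 1e-9) for one randomly chosen trait; every other
#' (variant, trait) P value is uniform on (0,1). Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()] (supplies `n_variants` and the seed).
#' @param traits Character vector of trait names; the first entries are
#'   conventionally the outcome diseases.
#' @param prop_pleiotropic Fraction of variants planted with a significant
#'   trait association, in `[0, 1]`.
#' @param trait_class Optional character vector classifying each trait as
#'   `"outcome_disease"` or `"confounder"`; defaults to `"outcome_disease"`
#'   for CAD/AF/IS/T2D and `"confounder"` otherwise.
#' @return A long tibble `variant_id`, `trait`, `pvalue`, `trait_class`, with
#'   the planted variant IDs as attribute `"planted"`.
#' @export
simulate_confounder_table <- function(config,
                                      traits = c("CAD", "AF", "IS", "T2D",
                                                 "maternal_smoking",
                                                 "education_years",
                                                 "townsend_index"),
                                      prop_pleiotropic = 12 / 58,
                                      trait_class = NULL) {
  stopifnot(inherits(config, "sim_config"), length(traits) >= 1)
  if (prop_pleiotropic < 0 || prop_pleiotropic > 1) {
    abort("prop_pleiotropic must lie in [0, 1]")
  }
  if (is.null(trait_class)) {
    trait_class <- ifelse(traits %in% c("CAD", "AF", "IS", "T2D"),
                          "outcome_disease", "confounder")
  }
  stopifnot(length(trait_class) == length(traits))
  J <- config$n_variants
  ids <- sprintf("rs%04d", seq_len(J))
  n_flag <- round(prop_pleiotropic * J)
  tab <- withr::with_seed(.derive_seed(config$seed, 6L), {
    g <- tidyr::expand_grid(variant_id = ids, trait = traits)
    g$pvalue <- runif(nrow(g))
    flagged <- sort(sample.int(J, n_flag))
    for (i in flagged) {
      tr <- traits[sample.int(length(traits), 1)]
      g$pvalue[g$variant_id == ids[i] & g$trait == tr] <- 10^(-runif(1, 9, 20))
    }
    attr(g, "planted") <- ids[flagged]
    g
  })
  tab$trait_class <- trait_class[match(tab$trait, traits)]
  tab
}

#' Simulate a multivariable-MR instrument table
#'
#' Generates per-variant effects on K correlated exposures and one outcome,
#' for multivariable (mediation) MR: the outcome's true per-variant effect is
#' the weighted sum of the exposure effects under the supplied direct causal
#' effects `thetas`. Exposure effect vectors share a common component
#' (`cor_exposures`) so the mediation structure is non-trivial but full rank.
#'
#' @param config A [sim_config()] (supplies `n_variants`, sample sizes,
#'   `r2_target` and the seed).
#' @param thetas Named numeric vector of direct causal effects, one per
#'   exposure (length K >= 2); names become the `beta_<name>` columns.
#' @param cor_exposures Correlation of the true exposure effect vectors
#'   (default 0.3).
#' @return A tibble `variant_id`, one `beta_<name>`/`se_<name>` pair per
#'   exposure, `beta_y`, `se_y`; the true effects as attribute `"truth"`.
#' @export
simulate_mvmr_table <- function(config, thetas, cor_exposures = 0.3) {
  stopifnot(inherits(config, "sim_config"), length(thetas) >= 2,
            !is.null(names(thetas)), all(names(thetas) != ""),
            cor_exposures >= 0, cor_exposures < 1)
  J <- config$n_variants
  K <- length(thetas)
  ids <- sprintf("rs%04d", seq_len(J))
  withr::with_seed(.derive_seed(config$seed, 7L), {
    eaf <- runif(J, config$eaf_range[1], config$eaf_range[2])
    het <- 2 * eaf * (1 - eaf)
    scale_b <- sqrt(config$r2_target / (J * het))
    common <- rnorm(J)
    bx_true <- vapply(seq_len(K), function(k) {
      raw <- sqrt(cor_exposures) * common + sqrt(1 - cor_exposures) * rnorm(J)
      raw * scale_b
    }, numeric(J))
    se_x <- 1 / sqrt(config$n_exposure * het)
    se_y <- 1 / sqrt(config$n_outcome * het)
    bx_obs <- bx_true + matrix(rnorm(J * K), J, K) * se_x
    gamma <- as.vector(bx_true %*% thetas)
    by_obs <- rnorm(J, gamma, se_y)
    out <- tibble(variant_id = ids)
    for (k in seq_len(K)) {
      out[[paste0("beta_", names(thetas)[k])]] <- bx_obs[, k]
      out[[paste0("se_", names(thetas)[k])]] <- se_x
    }
    out$beta_y <- by_obs
    out$se_y <- se_y
    attr(out, "truth") <- list(thetas = thetas, beta_true = bx_true)
    out
  })
}
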