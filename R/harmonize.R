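#' Strand complement of allele vectors
#' @noRd
.complement <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the per-variant outcome association to the exposure's effect allele,
#' resolving allele order swaps and strand-complement reporting, and applying a
#' policy for palindromic (A/T, C/G) variants whose strand cannot be resolved
#' from allele labels alone. The harmonized table is the unit of all MR
#' estimation: per variant, the exposure effect (`beta_x`, `se_x`) and the
#' aligned outcome effect (`beta_y`, `se_y`).
#'
#' Only variants present in both tables are returned. When the outcome's
#' effect allele equals the exposure's other allele (directly or as its strand
#' complement), the outcome beta sign is flipped and its frequency replaced by
#' `1 - eaf`. Palindromic variants are dropped under `palindrome_policy =
#' "drop"`; under `"infer_by_eaf"` they are resolved by comparing which side
#' of 0.5 each study's effect-allele frequency falls on, and dropped only when
#' either frequency is missing or lies within `eaf_ambiguity_band` of 0.5.
#'
#' Every intersection variant appears in the output with a
#' `harmonization_action`: `unchanged`, `flipped`, `dropped_palindromic`,
#' `dropped_missing` (beta/se/allele missing) or `dropped_mismatch`
#' (allele pairs irreconcilable by swapping or strand complement). Dropped
#' rows carry `NA` outcome effects; filter on the action (or call
#' [orient_to_exposure()], which keeps only retained rows) before estimation.
#'
#' @param exposure,outcome Tibbles in the canonical layout of
#'   [read_summary_stats()]. Duplicate `variant_id`s are an error.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_ambiguity_band Half-width around 0.5 within which a palindromic
#'   variant's frequency is considered ambiguous (default 0.08).
#'
#' @return A tibble with columns `variant_id`, `effect_allele`, `other_allele`
#'   (exposure orientation), `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf`
#'   (exposure study), `pvalue_x`, `harmonization_action`.
#' @examples
#' exp <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
#'   pvalue = 1e-10, n = 1e5)
#' out <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = -0.05, se = 0.02,
#'   pvalue = 0.01, n = 2e5)
#' harmonize(exp, out)
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_ambiguity_band = 0.08) {
  palindrome_policy <- arg_match(palindrome_policy)
  stopifnot(is.numeric(eaf_ambiguity_band), eaf_ambiguity_band >= 0,
            eaf_ambiguity_band < 0.5)
  for (nm in c("exposure", "outcome")) {
    x <- get(nm)
    dup <- x$variant_id[duplicated(x$variant_id)]
    if (length(dup) > 0) {
      abort(paste0("duplicated variant_id in ", nm, " table: ",
                   paste(unique(dup), collapse = ", ")))
    }
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) abort("no shared variants between exposure and outcome")

  ex <- exposure[match(shared, exposure$variant_id), ]
  ot <- outcome[match(shared, outcome$variant_id), ]

  J <- length(shared)
  action <- character(J)
  beta_y <- se_y <- rep(NA_real_, J)

  for (j in seq_len(J)) {
    ea_x <- ex$effect_allele[j]; oa_x <- ex$other_allele[j]
    ea_y <- ot$effect_allele[j]; oa_y <- ot$other_allele[j]
    if (anyNA(c(ea_x, oa_x, ea_y, oa_y, ex$beta[j], ex$se[j],
                ot$beta[j], ot$se[j]))) {
      action[j] <- "dropped_missing"
      next
    }
    pal <- .is_palindromic(ea_x, oa_x)
    same <- (ea_y == ea_x && oa_y == oa_x)
    swapped <- (ea_y == oa_x && oa_y == ea_x)
    comp_same <- (ea_y == .complement(ea_x) && oa_y == .complement(oa_x))
    comp_swapped <- (ea_y == .complement(oa_x) && oa_y == .complement(ea_x))

    if (!pal && !(same || swapped || comp_same || comp_swapped)) {
      action[j] <- "dropped_mismatch"
      next
    }

    if (pal) {
      # allele labels cannot distinguish strand; same/swapped and
      # comp_swapped/comp_same coincide, so orientation comes from eaf
      if (!(same || swapped)) { action[j] <- "dropped_mismatch"; next }
      if (palindrome_policy == "drop") { action[j] <- "dropped_palindromic"; next }
      fx <- ex$eaf[j]; fy <- ot$eaf[j]
      ambiguous <- function(f) is.na(f) || abs(f - 0.5) <= eaf_ambiguity_band
      if (ambiguous(fx) || ambiguous(fy)) {
        action[j] <- "dropped_palindromic"
        next
      }
      # outcome eaf refers to its own effect allele; put on the exposure
      # effect-allele scale using the label match, then check strand by eaf side
      fy_aligned <- if (same) fy else 1 - fy
      sign_flip <- if (same) 1 else -1
      if ((fx - 0.5) * (fy_aligned - 0.5) < 0) {
        # opposite sides of 0.5: strand mismatch, flip again
        sign_flip <- -sign_flip
      }
      beta_y[j] <- sign_flip * ot$beta[j]
      se_y[j] <- ot$se[j]
      action[j] <- if (sign_flip == 1) "unchanged" else "flipped"
    } else {
      if (same || comp_same) {
        beta_y[j] <- ot$beta[j]
        se_y[j] <- ot$se[j]
        action[j] <- "unchanged"
      } else {
        beta_y[j] <- -ot$beta[j]
        se_y[j] <- ot$se[j]
        action[j] <- "flipped"
      }
    }
  }

  n_mismatch <- sum(action == "dropped_mismatch")
  if (n_mismatch > 0) {
    warn(paste0(n_mismatch, " variant(s) dropped: allele pairs irreconcilable",
                " by flipping or strand complement"))
  }

  tibble(
    variant_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_x = ex$beta,
    se_x = ex$se,
    beta_y = beta_y,
    se_y = se_y,
    eaf = ex$eaf,
    pvalue_x = ex$pvalue,
    harmonization_action = action
  )
}

#' Orient harmonized instruments to a positive exposure effect
#'
#' MR-Egger regression is only identified when every instrument is coded so
#' that its exposure effect is positive. For each retained variant with
#' `beta_x < 0`, both `beta_x` and `beta_y` are negated (standard errors
#' unchanged) and `eaf` replaced by `1 - eaf`; Wald ratios are invariant under
#' this joint sign flip. Rows dropped during harmonization are removed; a
#' variant with `beta_x` exactly 0 has an undefined ratio and is dropped with
#' a warning.
#'
#' @param instruments Output of [harmonize()] (or any tibble with `beta_x`,
#'   `se_x`, `beta_y`, `se_y`).
#' @return The oriented tibble, `beta_x >= 0` everywhere, retained rows only.
#' @export
orient_to_exposure <- function(instruments) {
  x <- as_tibble(instruments)
  stopifnot(all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(x)))
  if ("harmonization_action" %in% names(x)) {
    x <- dplyr::filter(x, !startsWith(.data$harmonization_action, "dropped"))
  }
  zero <- !is.na(x$beta_x) & x$beta_x == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " variant(s) dropped: beta_x is exactly 0",
                " (Wald ratio undefined)"))
    x <- x[!zero, , drop = FALSE]
  }
  neg <- x$beta_x < 0
  if (any(neg)) {
    x$beta_y[neg] <- -x$beta_y[neg]
    x$beta_x[neg] <- -x$beta_x[neg]
    if ("eaf" %in% names(x)) x$eaf[neg] <- 1 - x$eaf[neg]
    if (all(c("effect_allele", "other_allele") %in% names(x))) {
      ea <- x$effect_allele[neg]
      x$effect_allele[neg] <- x$other_allele[neg]
      x$other_allele[neg] <- ea
    }
  }
  x
}
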