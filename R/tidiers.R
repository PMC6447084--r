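#' Tidy an MR estimate into broom conventions
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`causal_effect`, and for
#'   Egger the pleiotropy `intercept`): `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(
    term = "causal_effect",
    estimate = x$theta,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$pvalue
  )
  if (!is.null(x$intercept)) {
    z <- qnorm(0.975)
    out <- bind_rows(out, tibble(
      term = "intercept",
      estimate = x$intercept,
      std.error = x$intercept_se,
      conf.low = x$intercept - z * x$intercept_se,
      conf.high = x$intercept + z * x$intercept_se,
      p.value = x$intercept_pvalue
    ))
  }
  out
}

#' @rdname tidy.mr_estimate
#' @return For `glance`: a one-row tibble with `method`, `n_variants` and the
#'   heterogeneity statistics where defined.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method,
    n_variants = x$n_variants,
    q = x$q %||% NA_real_,
    q_df = x$q_df %||% NA_integer_,
    q_pvalue = x$q_pvalue %||% NA_real_
  )
}

#' Flatten an mr_estimate (or failure) to one wide report row
#' @noRd
.estimate_row <- function(est, method = NULL) {
  if (inherits(est, "error") || inherits(est, "condition")) {
    return(tibble(
      method = method %||% NA_character_, status = "failed",
      reason = conditionMessage(est),
      n_variants = NA_integer_, theta = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
      intercept = NA_real_, intercept_se = NA_real_,
      intercept_pvalue = NA_real_, q = NA_real_, q_pvalue = NA_real_
    ))
  }
  tibble(
    method = est$method, status = "ok", reason = NA_character_,
    n_variants = est$n_variants, theta = est$theta, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
    intercept = est$intercept %||% NA_real_,
    intercept_se = est$intercept_se %||% NA_real_,
    intercept_pvalue = est$intercept_pvalue %||% NA_real_,
    q = est$q %||% NA_real_, q_pvalue = est$q_pvalue %||% NA_real_
  )
}

#' @export
tidy.mvmr_estimate <- function(x, ...) {
  tibble(
    term = x$exposure,
    estimate = x$theta,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$pvalue
  )
}

#' @export
glance.mvmr_estimate <- function(x, ...) {
  tibble(
    n_variants = attr(x, "n_variants"),
    n_exposures = attr(x, "n_exposures"),
    q = attr(x, "q"),
    q_df = attr(x, "q_df"),
    q_pvalue = pchisq(attr(x, "q"), attr(x, "q_df"), lower.tail = FALSE)
  )
}

#' Tidy an instrument set into a long status table
#'
#' @param x An `instrument_set`.
#' @param ... Unused.
#' @return A tibble `variant_id`, `status` (`retained`/`excluded`), `reason`,
#'   `trait`, `removal_order` — suitable for TSV serialization.
#' @export
tidy.instrument_set <- function(x, ...) {
  ret <- tibble(variant_id = x$variant_ids, status = "retained",
                reason = NA_character_)
  exc <- x$exclusions
  exc$status <- "excluded"
  out <- bind_rows(ret, exc)
  for (col in c("trait", "removal_order")) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out$label <- x$label
  dplyr::select(out, "label", "variant_id", "status", "reason", "trait",
                "removal_order", dplyr::any_of("all_triggers"),
                dplyr::any_of("q_pvalue_at_removal"))
}

#' @export
glance.instrument_set <- function(x, ...) {
  tibble(label = x$label,
         n_parent = length(x$variant_ids) + nrow(x$exclusions),
         n_retained = length(x$variant_ids),
         n_excluded = nrow(x$exclusions))
}

#' @export
tidy.mr_q <- function(x, ...) {
  x$contributions
}

#' @export
glance.mr_q <- function(x, ...) {
  tibble(q = x$q, df = x$df, pvalue = x$pvalue)
}

#' @export
tidy.mr_loo <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.mr_loo <- function(x, ...) {
  full <- attr(x, "full")
  tibble(method = full$method, theta_full = full$theta,
         ci_low_full = full$ci_low, ci_high_full = full$ci_high,
         n_flagged = sum(x$outside_full_ci, na.rm = TRUE))
}
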