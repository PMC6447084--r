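#' Cochran's Q heterogeneity statistic
#'
#' The weighted sum of squared deviations of the per-variant Wald ratios from
#' a pooled estimate: `q_j = w_j (theta_j - theta)^2` with
#' `w_j = beta_x_j^2 / se_y_j^2`, `Q = sum q_j`, compared against a chi-square
#' with `J - 1` degrees of freedom. Large per-variant contributions identify
#' heterogeneous (potentially pleiotropic) instruments; the statistic drives
#' the stepwise pruning in [select_iv3()].
#'
#' @param instruments Oriented harmonized instruments (>= 2 rows).
#' @param theta Pooled causal estimate on the same instrument set; defaults to
#'   the IVW estimate.
#' @return An object of class `mr_q`: list with `q`, `df`, `pvalue` and a
#'   `contributions` tibble (`variant_id`, `q_contrib`).
#' @export
cochran_q <- function(instruments, theta = NULL) {
  x <- .check_instruments(instruments, min_n = 2)
  core <- .ivw_core(x$beta_x, x$beta_y, x$se_y)
  if (is.null(theta)) theta <- core$theta
  contrib <- core$w * (core$ratio - theta)^2
  q <- sum(contrib)
  df <- nrow(x) - 1L
  structure(list(
    q = q,
    df = df,
    pvalue = pchisq(q, df, lower.tail = FALSE),
    theta = theta,
    contributions = tibble(
      variant_id = if ("variant_id" %in% names(x)) x$variant_id else
        paste0("v", seq_len(nrow(x))),
      q_contrib = contrib
    )
  ), class = "mr_q")
}

#' @export
print.mr_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, P = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' Dispatch an estimator by tag
#' @noRd
.fit_method <- function(instruments, method, ...) {
  switch(method,
    ivw = ,
    ivw_mre = mr_ivw(instruments, model = "mre"),
    ivw_fixed = mr_ivw(instruments, model = "fixed"),
    ivw_penalized_robust = mr_ivw_penalized_robust(instruments, ...),
    weighted_median = mr_weighted_median(instruments, ...),
    egger = mr_egger(instruments),
    abort(paste0("unknown estimator tag: ", method))
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, each run omitting one variant, to
#' reveal whether a single SNP drives the association. An omission is flagged
#' when its estimate falls outside the full-set 95% confidence interval.
#'
#' @param instruments Oriented harmonized instruments (>= 3 rows).
#' @param method Estimator tag: `"ivw"` (multiplicative random effects,
#'   default), `"ivw_fixed"`, `"ivw_penalized_robust"`, `"weighted_median"` or
#'   `"egger"`.
#' @param ... Passed to the estimator (e.g. `seed` for the weighted median).
#' @return An object of class `mr_loo`: a tibble with one row per omitted
#'   variant (`omitted`, `theta`, `se`, `ci_low`, `ci_high`, `pvalue`,
#'   `outside_full_ci`, `error`), with the full-set `mr_estimate` as attribute
#'   `"full"` and the flagging rule recorded as attribute `"flag_rule"`.
#' @export
leave_one_out <- function(instruments, method = "ivw", ...) {
  x <- .check_instruments(instruments, min_n = 3)
  full <- .fit_method(x, method, ...)
  ids <- if ("variant_id" %in% names(x)) x$variant_id else
    paste0("v", seq_len(nrow(x)))
  rows <- purrr::map(seq_len(nrow(x)), function(j) {
    fit <- tryCatch(.fit_method(x[-j, , drop = FALSE], method, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(omitted = ids[j], theta = NA_real_, se = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
             outside_full_ci = NA, error = conditionMessage(fit))
    } else {
      tibble(omitted = ids[j], theta = fit$theta, se = fit$se,
             ci_low = fit$ci_low, ci_high = fit$ci_high, pvalue = fit$pvalue,
             outside_full_ci = fit$theta < full$ci_low | fit$theta > full$ci_high,
             error = NA_character_)
    }
  })
  out <- bind_rows(rows)
  structure(out, class = c("mr_loo", class(out)), full = full,
            flag_rule = "omitted-set estimate outside full-set 95% CI")
}
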