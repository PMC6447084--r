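#' Construct an mr_estimate object
#' @noRd
new_mr_estimate <- function(method, theta, se, n_variants,
                            intercept = NULL, intercept_se = NULL,
                            q = NULL, q_df = NULL, extra = list()) {
  z <- qnorm(0.975)
  est <- list(
    method = method,
    theta = theta,
    se = se,
    ci_low = theta - z * se,
    ci_high = theta + z * se,
    pvalue = 2 * pnorm(-abs(theta) / se),
    n_variants = n_variants,
    q = q,
    q_df = q_df,
    q_pvalue = if (!is.null(q)) pchisq(q, q_df, lower.tail = FALSE) else NULL
  )
  if (!is.null(intercept)) {
    est$intercept <- intercept
    est$intercept_se <- intercept_se
    est$intercept_pvalue <- 2 * pnorm(-abs(intercept) / intercept_se)
  }
  structure(c(est, extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s>\n", x$method))
  cat(sprintf("  theta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], P = %.3g, J = %d\n",
              x$theta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_variants))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), P = %.3g  [pleiotropy test]\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  }
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, P = %.3g\n",
                x$q, x$q_df, x$q_pvalue))
  }
  invisible(x)
}

#' Extract the analysis columns and check estimator preconditions
#' @noRd
.check_instruments <- function(instruments, min_n, require_oriented = TRUE) {
  x <- as_tibble(instruments)
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("instrument table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if ("harmonization_action" %in% names(x)) {
    x <- x[!startsWith(x$harmonization_action, "dropped"), , drop = FALSE]
  }
  if (anyNA(x$beta_x) || anyNA(x$beta_y) || anyNA(x$se_y)) {
    abort("instrument table contains missing effects; harmonize and filter first")
  }
  if (nrow(x) < min_n) {
    abort(paste0("at least ", min_n, " instruments required, got ", nrow(x)))
  }
  if (require_oriented && any(x$beta_x <= 0)) {
    abort("instruments must be oriented to beta_x > 0; run orient_to_exposure()")
  }
  if (any(x$se_y <= 0) || any(x$se_x <= 0)) abort("standard errors must be positive")
  x
}

#' Per-variant Wald ratio estimates
#'
#' The per-variant causal estimate `theta_j = beta_y / beta_x` with first-order
#' delta-method standard error `se_j = se_y / beta_x` (exposure-side
#' uncertainty ignored, the convention for strong instruments). These ratios
#' underpin the weighted median estimator and leave-one-out analysis.
#'
#' @param instruments Oriented harmonized instruments (`beta_x > 0`); see
#'   [orient_to_exposure()].
#' @return A tibble `variant_id`, `theta`, `se`.
#' @export
wald_ratios <- function(instruments) {
  x <- .check_instruments(instruments, min_n = 1)
  tibble(
    variant_id = if ("variant_id" %in% names(x)) x$variant_id else
      paste0("v", seq_len(nrow(x))),
    theta = x$beta_y / x$beta_x,
    se = x$se_y / x$beta_x
  )
}

#' IVW closed form on effect vectors; the single numerical core shared by the
#' public estimator, Q, IV3 pruning and the simulation loops.
#' @noRd
.ivw_core <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  ratio <- by / bx
  sw <- sum(w)
  theta <- sum(w * ratio) / sw
  q_contrib <- w * (ratio - theta)^2
  list(theta = theta, se_fixed = 1 / sqrt(sw), w = w, ratio = ratio,
       q = sum(q_contrib), q_contrib = q_contrib)
}

#' Inverse-variance weighted estimator
#'
#' Combines per-variant Wald ratios with weights `w_j = beta_x_j^2 / se_y_j^2`
#' (equivalently a weighted zero-intercept regression of outcome on exposure
#' effects). Under `model = "fixed"` the standard error is `(sum w_j)^(-1/2)`;
#' under the default multiplicative random-effects model (`"mre"`) it is
#' scaled by `max(1, sqrt(Q / (J - 1)))`, so heterogeneity widens but never
#' narrows the interval. P values are two-sided normal.
#'
#' @param instruments Oriented harmonized instruments (>= 2 rows).
#' @param model `"mre"` (default) or `"fixed"`.
#' @return An `mr_estimate` object; see [tidy.mr_estimate()].
#' @examples
#' sim <- simulate_two_sample(sim_config(seed = 1))
#' iv <- orient_to_exposure(harmonize(sim$exposure, sim$outcome))
#' mr_ivw(iv)
#' @export
mr_ivw <- function(instruments, model = c("mre", "fixed")) {
  model <- arg_match(model)
  x <- .check_instruments(instruments, min_n = 2)
  core <- .ivw_core(x$beta_x, x$beta_y, x$se_y)
  if (!is.finite(core$se_fixed) || sum(core$w) <= 0) abort("all IVW weights are zero")
  J <- nrow(x)
  scale <- if (model == "mre") max(1, sqrt(core$q / (J - 1))) else 1
  new_mr_estimate(
    method = paste0("ivw_", model),
    theta = core$theta, se = core$se_fixed * scale, n_variants = J,
    q = core$q, q_df = J - 1
  )
}

#' Penalized robust IVW estimator
#'
#' A pleiotropy-robust variant of IVW: (i) per-variant Cochran's Q
#' contributions `q_j` are computed against the plain IVW estimate; (ii) the
#' IVW weight of each variant is multiplied by `min(1, penalty_scale * p_j)`
#' where `p_j` is the upper chi-square(1) tail of `q_j`, down-weighting
#' outlying ratios; (iii) the zero-intercept weighted regression is refit with
#' bounded-influence M-estimation (Tukey bisquare). The standard error comes
#' from the robust fit, scaled by `max(1, sigma)` so heterogeneity never
#' shrinks it.
#'
#' @param instruments Oriented harmonized instruments (>= 3 rows).
#' @param penalty_scale Weight-penalty multiplier (default 20): a variant's
#'   weight is untouched whenever its outlier P value exceeds
#'   `1 / penalty_scale`.
#' @param max_iter Iteration budget for the M-estimation (default 100).
#' @details The M-estimation standardizes residuals by their known sampling
#'   scale (`se_y`, carrying the penalty), not by a re-estimated robust scale:
#'   under homogeneity the standardized residuals are unit-normal by
#'   construction, so the bisquare weights stay at 1 and the estimator
#'   collapses to plain IVW; only genuinely outlying variants are
#'   down-weighted or rejected.
#' @return An `mr_estimate` object.
#' @export
mr_ivw_penalized_robust <- function(instruments, penalty_scale = 20,
                                    max_iter = 100) {
  stopifnot(penalty_scale > 0)
  x <- .check_instruments(instruments, min_n = 3)
  bx <- x$beta_x; by <- x$beta_y
  core <- .ivw_core(bx, by, x$se_y)
  pj <- pchisq(core$q_contrib, df = 1, lower.tail = FALSE)
  pen <- pmin(1, penalty_scale * pj)
  w_pen <- pen / x$se_y^2  # regression-form weights carry the penalty
  cc <- 4.685              # Tukey bisquare, 95% Gaussian efficiency
  bisq <- function(r) ifelse(abs(r) < cc, (1 - (r / cc)^2)^2, 0)
  theta <- sum(w_pen * bx * by) / sum(w_pen * bx^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- bisq(sqrt(w_pen) * (by - theta * bx))
    w_fin <- w_pen * u
    denom <- sum(w_fin * bx^2)
    if (denom <= 0) abort("robust IVW: every instrument was rejected")
    theta_new <- sum(w_fin * bx * by) / denom
    if (abs(theta_new - theta) <= 1e-12 * max(1, abs(theta_new))) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  if (!converged) {
    abort(paste0("robust IVW fit did not converge within ", max_iter,
                 " iterations"))
  }
  u <- bisq(sqrt(w_pen) * (by - theta * bx))
  w_fin <- w_pen * u
  J <- nrow(x)
  se_base <- 1 / sqrt(sum(w_fin * bx^2))
  q_rob <- sum(w_fin * (by - theta * bx)^2)
  se <- se_base * max(1, sqrt(q_rob / (J - 1)))
  new_mr_estimate(
    method = "ivw_penalized_robust",
    theta = theta, se = se, n_variants = J,
    q = core$q, q_df = J - 1,
    extra = list(penalty = pen, robust_weight = u, iterations = it)
  )
}

#' Weighted-median core on ratio/weight vectors
#' @noRd
.weighted_median_core <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  s <- 100 * (cumsum(wn) - wn / 2)
  approx(s, r, xout = 50, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The causal estimate at the 50th weight percentile of the ordered Wald
#' ratios: ratios are sorted, weights `w_j = beta_x_j^2 / se_y_j^2` normalized,
#' cumulative midpoint percentiles `s_j = 100 (sum_{i<=j} w_i - w_j/2)` formed,
#' and the estimate linearly interpolated at `s = 50`. Consistent when less
#' than half the total weight comes from invalid (pleiotropic) instruments.
#' The standard error is the standard deviation of the estimate over
#' `n_boot` parametric bootstrap resamples in which every `beta_x_j` and
#' `beta_y_j` is redrawn from its reported normal sampling distribution;
#' deterministic given `seed`.
#'
#' @param instruments Oriented harmonized instruments (>= 3 rows).
#' @param n_boot Bootstrap replicates for the SE (default 1000; < 100 warns).
#' @param seed Integer seed for the bootstrap (default 1). The global RNG
#'   state is left untouched.
#' @return An `mr_estimate` object.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  x <- .check_instruments(instruments, min_n = 3)
  if (n_boot < 100) warn("n_boot < 100: bootstrap SE will be unstable")
  w <- x$beta_x^2 / x$se_y^2
  theta <- .weighted_median_core(x$beta_y / x$beta_x, w)
  J <- nrow(x)
  boot <- withr::with_seed(seed, {
    bx <- matrix(rnorm(n_boot * J, mean = rep(x$beta_x, each = n_boot),
                       sd = rep(x$se_x, each = n_boot)), nrow = n_boot)
    by <- matrix(rnorm(n_boot * J, mean = rep(x$beta_y, each = n_boot),
                       sd = rep(x$se_y, each = n_boot)), nrow = n_boot)
    vapply(seq_len(n_boot), function(b) {
      .weighted_median_core(by[b, ] / bx[b, ], bx[b, ]^2 / x$se_y^2)
    }, numeric(1))
  })
  new_mr_estimate(
    method = "weighted_median",
    theta = theta, se = sd(boot), n_variants = J,
    extra = list(n_boot = n_boot, seed = seed)
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects *with* an
#' intercept, weights `1 / se_y^2`. The slope is the causal estimate; the
#' intercept estimates the average directional (horizontal) pleiotropy across
#' instruments, and its two-sided test is the pleiotropy diagnostic. Both
#' standard errors are scaled by `max(1, sqrt(Q_egger / (J - 2)))`
#' (multiplicative random effects; never deflates). Requires instruments
#' oriented to `beta_x > 0` for identifiability and valid only under the
#' InSIDE assumption (instrument strength independent of direct effects).
#'
#' @param instruments Oriented harmonized instruments (>= 3 rows).
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pvalue` fields.
#' @export
mr_egger <- function(instruments) {
  x <- .check_instruments(instruments, min_n = 3)
  if (var(x$beta_x) == 0) abort("zero variance in beta_x: Egger design singular")
  w <- 1 / x$se_y^2
  fit <- lm(beta_y ~ beta_x, data = x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(Q_egger / (J - 2)) under these weights
  scale <- max(1, sigma)
  co <- sm$coefficients
  theta <- co["beta_x", "Estimate"]
  se <- co["beta_x", "Std. Error"] / sigma * scale
  a <- co["(Intercept)", "Estimate"]
  a_se <- co["(Intercept)", "Std. Error"] / sigma * scale
  J <- nrow(x)
  new_mr_estimate(
    method = "egger",
    theta = theta, se = se, n_variants = J,
    intercept = a, intercept_se = a_se,
    q = sigma^2 * (J - 2), q_df = J - 2
  )
}
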