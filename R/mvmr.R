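#' Multivariable MR (weighted regression of outcome on several exposures)
#'
#' Estimates the direct causal effect of each of K exposures on the outcome
#' simultaneously, by multiple weighted regression of the per-variant outcome
#' effects on the K columns of exposure effects, without intercept and with
#' weights `1 / se_y^2`. This is the mediation analysis used to ask whether an
#' exposure's effect on disease persists after accounting for a mediator
#' (e.g. birthweight and BMI on coronary artery disease). Standard errors are
#' scaled by `max(1, sqrt(Q / (J - K)))`; P values are two-sided normal.
#'
#' @param instruments_multi Tibble with one row per variant: outcome columns
#'   `beta_y`, `se_y`, plus one exposure-effect column per exposure, named in
#'   `exposures` (e.g. `beta_birthweight`, `beta_bmi`). Companion
#'   `se_<exposure>` columns may be present but are not used (first-order
#'   weighting). Requires more variants than exposures and a full-rank design.
#' @param exposures Character vector (length >= 2) of exposure-effect column
#'   names.
#' @return An object of class `mvmr_estimate`: a tibble with one row per
#'   exposure (`exposure`, `theta`, `se`, `ci_low`, `ci_high`, `pvalue`) and
#'   attributes `n_variants`, `n_exposures`, `q`, `q_df`.
#' @export
mr_mvmr <- function(instruments_multi, exposures) {
  x <- as_tibble(instruments_multi)
  stopifnot(length(exposures) >= 2)
  miss <- setdiff(c(exposures, "beta_y", "se_y"), names(x))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  J <- nrow(x)
  K <- length(exposures)
  if (J <= K) abort(paste0("need more variants (", J, ") than exposures (", K, ")"))
  if (any(x$se_y <= 0)) abort("se_y must be positive")
  X <- as.matrix(x[, exposures])
  dec <- qr(X)
  if (dec$rank < K) {
    cc <- exposures[dec$pivot[(dec$rank + 1L):K]]
    abort(paste0("rank-deficient exposure design; collinear column(s): ",
                 paste(cc, collapse = ", ")))
  }
  w <- 1 / x$se_y^2
  fit <- lm(x$beta_y ~ 0 + X, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(Q / (J - K)) under these weights
  scale <- max(1, sigma)
  theta <- unname(coef(fit))
  se <- unname(sm$coefficients[, "Std. Error"]) / sigma * scale
  z <- qnorm(0.975)
  out <- tibble(
    exposure = exposures,
    theta = theta,
    se = se,
    ci_low = theta - z * se,
    ci_high = theta + z * se,
    pvalue = 2 * pnorm(-abs(theta) / se)
  )
  structure(out, class = c("mvmr_estimate", class(out)),
            n_variants = J, n_exposures = K,
            q = sigma^2 * (J - K), q_df = J - K)
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate: %d exposures, %d variants>\n",
              attr(x, "n_exposures"), attr(x, "n_variants")))
  NextMethod()
}
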