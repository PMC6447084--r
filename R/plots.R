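#' Funnel plot of per-variant Wald ratios
#'
#' Precision (`1/se_j`) against the per-variant causal estimate; asymmetry
#' suggests directional pleiotropy. Vertical lines mark pooled estimates.
#'
#' @param instruments Oriented harmonized instruments.
#' @param estimates Optional list of `mr_estimate` objects drawn as reference
#'   lines.
#' @return A ggplot object. The underlying data table is available via
#'   [wald_ratios()].
#' @export
plot_funnel <- function(instruments, estimates = list()) {
  d <- wald_ratios(instruments)
  d$precision <- 1 / d$se
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "per-variant causal estimate (Wald ratio)",
                  y = "precision (1/SE)")
  if (length(estimates) > 0) {
    ref <- bind_rows(lapply(estimates, .estimate_row))
    p <- p + ggplot2::geom_vline(
      data = ref, ggplot2::aes(xintercept = .data$theta,
                               linetype = .data$method)
    )
  }
  p
}

#' Forest plot of MR estimates
#'
#' @param estimates A tidy estimate table (e.g. `report$estimates` from
#'   [run_analysis()], or `dplyr::bind_rows(lapply(list(...), tidy))`) with
#'   columns `method`, `theta`, `ci_low`, `ci_high` and optionally `outcome`
#'   and `iv`.
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates) {
  d <- as_tibble(estimates)
  stopifnot(all(c("method", "theta", "ci_low", "ci_high") %in% names(d)))
  d$y <- interaction(
    d$method,
    if ("iv" %in% names(d)) d$iv else "",
    drop = TRUE, sep = " / "
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$y)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "causal effect (95% CI)", y = NULL)
  if ("outcome" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~outcome, scales = "free_x")
  }
  p
}

#' @describeIn leave_one_out Forest plot of the leave-one-out estimates with
#'   the full-set estimate (line) and CI (band); flagged omissions in colour.
#' @param object An `mr_loo` object.
#' @export
autoplot.mr_loo <- function(object, ...) {
  full <- attr(object, "full")
  d <- as_tibble(object)
  d$omitted <- factor(d$omitted, levels = rev(d$omitted))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$omitted)) +
    ggplot2::annotate("rect", xmin = full$ci_low, xmax = full$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_vline(xintercept = full$theta, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$outside_full_ci)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = sprintf("%s estimate omitting each variant", full$method),
                  y = "omitted variant")
}

#' Power curves over a design grid
#'
#' @param grid Output of [power_grid()].
#' @return A ggplot object: power against sample size, one curve per
#'   (r2, effect) combination.
#' @export
plot_power_grid <- function(grid) {
  d <- as_tibble(grid)
  d$design <- sprintf("r2=%.3g, effect=%.3g", d$r2, d$effect)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_outcome, y = .data$power,
                                  colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "outcome sample size", y = "power")
}
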