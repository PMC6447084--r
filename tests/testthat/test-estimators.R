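test_that("Wald ratios equal element-wise brute-force recomputation", {
  x <- toy_instruments(J = 5, seed = 7)
  r <- wald_ratios(x)
  for (j in 1:5) {
    expect_equal(r$theta[j], x$beta_y[j] / x$beta_x[j])
    expect_equal(r$se[j], x$se_y[j] / x$beta_x[j])
  }
  one <- tibble::tibble(beta_x = 0.1, se_x = 0.01, beta_y = 0.02, se_y = 0.01)
  expect_equal(wald_ratios(one)$theta, 0.2)
  expect_equal(wald_ratios(one)$se, 0.1)
  one$beta_y <- 0
  expect_equal(wald_ratios(one)$theta, 0)
  one$beta_x <- -0.1
  expect_error(wald_ratios(one), "oriented")
})

test_that("IVW matches closed forms and the normal-equations oracle", {
  # homogeneous ratios: exact recovery, Q = 0, fixed and mre SEs coincide
  b <- 0.3
  hom <- tibble::tibble(beta_x = c(0.05, 0.1, 0.2), se_x = 0.01,
                        beta_y = b * c(0.05, 0.1, 0.2), se_y = c(0.004, 0.01, 0.02))
  fit_f <- mr_ivw(hom, model = "fixed")
  fit_m <- mr_ivw(hom, model = "mre")
  expect_equal(fit_f$theta, b)
  expect_equal(fit_f$q, 0)
  expect_equal(fit_f$se, fit_m$se)

  # two instruments: hand-computed precision-weighted mean of the ratios
  two <- tibble::tibble(beta_x = c(0.1, 0.2), se_x = 0.01,
                        beta_y = c(0.03, 0.02), se_y = c(0.004, 0.006))
  w <- two$beta_x^2 / two$se_y^2
  th <- two$beta_y / two$beta_x
  expect_equal(mr_ivw(two)$theta, sum(w * th) / sum(w))

  # 20 instruments: zero-intercept WLS oracle to 1e-8 relative
  x <- toy_instruments(20)
  o <- oracle_wls(matrix(x$beta_x, ncol = 1), x$beta_y, 1 / x$se_y^2)
  fit <- mr_ivw(x, model = "fixed")
  expect_equal(fit$theta, o$beta, tolerance = 1e-8)
  expect_equal(fit$se, o$se_unscaled, tolerance = 1e-8)

  expect_error(mr_ivw(x[1, ]), "at least 2")
})

test_that("Egger matches exact lines and the weighted normal-equations oracle", {
  # points exactly on beta_y = a + t * beta_x
  a <- 0.004; t <- 0.3
  ln <- tibble::tibble(beta_x = seq(0.02, 0.1, length.out = 6), se_x = 0.01,
                       beta_y = a + t * seq(0.02, 0.1, length.out = 6),
                       se_y = runif(6, 0.003, 0.01))
  fit <- mr_egger(ln)
  expect_equal(fit$theta, t, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)

  # 15-instrument table vs explicit weighted solve
  x <- toy_instruments(15, seed = 42)
  X <- cbind(1, x$beta_x)
  o <- oracle_wls(X, x$beta_y, 1 / x$se_y^2)
  fit2 <- mr_egger(x)
  expect_equal(fit2$intercept, o$beta[1], tolerance = 1e-8)
  expect_equal(fit2$theta, o$beta[2], tolerance = 1e-8)
  # mre scaling never deflates below the unscaled weighted-LS standard error
  expect_gte(fit2$se, o$se_unscaled[2] * (1 - 1e-12))

  expect_error(mr_egger(x[1:2, ]), "at least 3")
  sing <- tibble::tibble(beta_x = rep(0.05, 4), se_x = 0.01,
                         beta_y = rnorm(4, 0, 0.01), se_y = 0.01)
  expect_error(mr_egger(sing), "singular")
})

test_that("weighted median follows the cumulative-weight definition", {
  # three equal-weight ratios: the middle one sits exactly at percentile 50
  eq <- tibble::tibble(beta_x = 1, se_x = 0.01,
                       beta_y = c(0.1, 0.2, 0.9), se_y = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 100, seed = 1)$theta, 0.2)

  # degenerate: all ratios equal
  b <- 0.4
  hom <- tibble::tibble(beta_x = c(0.05, 0.1, 0.2, 0.3), se_x = 0.005,
                        beta_y = b * c(0.05, 0.1, 0.2, 0.3),
                        se_y = c(0.004, 0.01, 0.02, 0.01))
  fit <- mr_weighted_median(hom, n_boot = 200, seed = 2)
  expect_equal(fit$theta, b)

  # unequal weights vs the brute-force percentile walk
  x <- toy_instruments(10, seed = 9)
  fit2 <- mr_weighted_median(x, n_boot = 100, seed = 3)
  expect_equal(fit2$theta,
               oracle_weighted_median(x$beta_y / x$beta_x,
                                      x$beta_x^2 / x$se_y^2))

  # deterministic given the seed; warning for a tiny bootstrap
  fit3 <- mr_weighted_median(x, n_boot = 100, seed = 3)
  expect_identical(fit2$se, fit3$se)
  expect_warning(mr_weighted_median(x, n_boot = 50, seed = 1), "n_boot")
  expect_error(mr_weighted_median(x[1:2, ], n_boot = 100, seed = 1),
               "at least 3")
})

test_that("penalized robust IVW dampens outliers and leaves clean data alone", {
  # near-homogeneous ratios: penalties and bisquare weights stay inactive
  hom <- withr::with_seed(5, {
    bx <- runif(12, 0.03, 0.09)
    sy <- runif(12, 0.003, 0.008)
    tibble::tibble(beta_x = bx, se_x = 0.005,
                   beta_y = 0.25 * bx + rnorm(12, 0, 0.01 * sy), se_y = sy)
  })
  expect_equal(mr_ivw_penalized_robust(hom)$theta, mr_ivw(hom)$theta,
               tolerance = 1e-6)

  x <- toy_instruments(20, seed = 5)

  # chi-square tail penalty: q_j at the 5% point with penalty_scale 20 keeps
  # the weight (min(1, 20 * 0.05) = 1)
  q05 <- qchisq(0.95, df = 1)
  expect_equal(min(1, 20 * pchisq(q05, 1, lower.tail = FALSE)), 1)

  # one gross outlier: robust estimate stays near the clean-data IVW
  clean_theta <- mr_ivw(x)$theta
  y <- x
  y$beta_y[7] <- y$beta_y[7] + 0.08
  expect_lt(abs(mr_ivw_penalized_robust(y)$theta - clean_theta),
            abs(mr_ivw(y)$theta - clean_theta))
})

test_that("estimators are scale equivariant in the outcome units", {
  x <- toy_instruments(12, seed = 31)
  for (c_scale in c(0.1, 3)) {
    y <- x
    y$beta_y <- c_scale * x$beta_y
    y$se_y <- c_scale * x$se_y
    for (fit_fun in list(
      function(d) mr_ivw(d),
      function(d) mr_egger(d),
      function(d) mr_weighted_median(d, n_boot = 150, seed = 8),
      function(d) mr_ivw_penalized_robust(d)
    )) {
      f0 <- fit_fun(x); f1 <- fit_fun(y)
      expect_equal(f1$theta, c_scale * f0$theta, tolerance = 1e-6)
      expect_equal(f1$se, c_scale * f0$se, tolerance = 1e-6)
    }
  }
})

test_that("Egger intercept is unbiased under balanced pleiotropy and its
           test calibrated without pleiotropy", {
  # run at the causal null: with a nonzero causal effect the intercept also
  # absorbs the exposure-noise dilution of the slope (see methods vignette),
  # which would confound the pleiotropy property under test
  nrep <- 600
  a_bal <- numeric(nrep)
  rej_clean <- logical(nrep)
  for (s in seq_len(nrep)) {
    iv <- sim_instruments(seed = 20000 + s, theta_true = 0,
                          pleiotropy_mode = "balanced", pleiotropy_sd = 0.002)
    a_bal[s] <- mr_egger(iv)$intercept
    iv0 <- sim_instruments(seed = 50000 + s, theta_true = 0)
    rej_clean[s] <- mr_egger(iv0)$intercept_pvalue < 0.05
  }
  # balanced (mean-zero) direct effects leave the intercept centred on zero
  expect_lt(abs(mean(a_bal)), 3 * sd(a_bal) / sqrt(nrep))
  # with homogeneous instruments the 5% intercept test is calibrated
  expect_gt(mean(rej_clean), 0.03)
  expect_lt(mean(rej_clean), 0.07)
})

test_that("tidy and glance return broom-shaped tibbles", {
  x <- toy_instruments(10)
  fit <- mr_egger(x)
  td <- tidy(fit)
  expect_equal(td$term, c("causal_effect", "intercept"))
  expect_true(all(c("estimate", "std.error", "conf.low", "conf.high",
                    "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$method, "egger")
  expect_equal(gl$n_variants, 10L)
  td_ivw <- tidy(mr_ivw(x))
  expect_equal(nrow(td_ivw), 1)
})
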