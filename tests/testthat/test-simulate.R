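test_that("the generator is deterministic and hits its variance target", {
  cfg <- sim_config(seed = 42)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a, b)

  expect_equal(a$truth$realized_r2, 0.022, tolerance = 1e-12)
  expect_equal(nrow(a$exposure), 46)
  expect_equal(a$exposure$variant_id, a$outcome$variant_id)
  # generated SEs follow the asymptotic formula the power module assumes
  het <- 2 * a$truth$variants$eaf * (1 - a$truth$variants$eaf)
  expect_equal(a$exposure$se, 1 / sqrt(150000 * het))
  expect_equal(a$outcome$se, 1 / sqrt(100000 * het))

  # a different outcome stream reuses the exposure draw exactly
  c2 <- simulate_two_sample(cfg, outcome_stream = 3)
  expect_identical(c2$exposure, a$exposure)
  expect_false(identical(c2$outcome$beta, a$outcome$beta))
})

test_that("pleiotropy modes plant the configured number and kind of effects", {
  cfg <- sim_config(seed = 5, pleiotropy_mode = "directional",
                    pleiotropy_mean = 0.004, pleiotropy_sd = 0.001,
                    prop_invalid = 0.5)
  tr <- simulate_two_sample(cfg)$truth$variants
  expect_equal(sum(tr$invalid), 23)  # round(0.5 * 46)
  expect_true(all(tr$pleiotropy_effect[!tr$invalid] == 0))
  # 23 draws from N(0.004, 0.001): mean within 4 standard errors
  expect_lt(abs(mean(tr$pleiotropy_effect[tr$invalid]) - 0.004),
            4 * 0.001 / sqrt(sum(tr$invalid)))

  none <- simulate_two_sample(sim_config(seed = 5))$truth$variants
  expect_true(all(none$pleiotropy_effect == 0))
  expect_false(any(none$invalid))
})

test_that("binary outcomes use case-fraction scaled standard errors", {
  cfg <- sim_config(seed = 9, binary_outcome = TRUE, case_fraction = 0.33,
                    n_outcome = 184305)
  sim <- simulate_two_sample(cfg)
  het <- 2 * sim$truth$variants$eaf * (1 - sim$truth$variants$eaf)
  expect_equal(sim$outcome$se, 1 / sqrt(184305 * 0.33 * 0.67 * het))
})

test_that("the confounder table plants the configured fraction deterministically", {
  cfg <- sim_config(n_variants = 58, seed = 77)
  t1 <- simulate_confounder_table(cfg, prop_pleiotropic = 12 / 58)
  t2 <- simulate_confounder_table(cfg, prop_pleiotropic = 12 / 58)
  expect_identical(t1, t2)
  planted <- attr(t1, "planted")
  expect_equal(length(planted), 12)
  expect_true(all(t1$pvalue[t1$variant_id %in% planted &
                              t1$pvalue < 5e-8] < 1e-8))
  expect_true(all(t1$pvalue[!t1$variant_id %in% planted] >= 5e-8))
  expect_setequal(unique(t1$trait_class), c("outcome_disease", "confounder"))

  # zero planting leaves IV2 complete when the exposure P values dominate
  t0 <- simulate_confounder_table(cfg, prop_pleiotropic = 0)
  iv1 <- select_iv1(tibble::tibble(variant_id = sprintf("rs%04d", 1:58)))
  expo <- tibble::tibble(variant_id = sprintf("rs%04d", 1:58), pvalue = 1e-30)
  expect_equal(length(select_iv2(iv1, expo, t0)$variant_ids), 58)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(r2_target = 1.2), "r2_target")
  expect_error(sim_config(n_variants = 1), "n_variants")
  expect_error(simulate_confounder_table(sim_config(), prop_pleiotropic = 1.5),
               "prop_pleiotropic")
})
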