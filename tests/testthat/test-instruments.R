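test_that("IV1 removes exactly the listed loci and records the reason", {
  hits <- tibble::tibble(variant_id = sprintf("rs%02d", 1:10))
  s <- select_iv1(hits, excluded_loci = "rs03")
  expect_equal(length(s$variant_ids), 9)
  expect_false("rs03" %in% s$variant_ids)
  expect_equal(s$exclusions$reason, "imprinting/manual")

  # identity with no exclusions; the paper-scale case
  expect_equal(select_iv1(hits)$variant_ids, hits$variant_id)
  hits58 <- tibble::tibble(variant_id = sprintf("rs%02d", 1:58))
  expect_equal(length(select_iv1(hits58)$variant_ids), 58)

  expect_warning(select_iv1(hits, excluded_loci = "rs99"), "rs99")
  td <- tidy(s)
  expect_equal(sum(td$status == "retained"), 9)
  expect_equal(sum(td$status == "excluded"), 1)
})

test_that("IV2 applies both exclusion rules and logs every trigger", {
  iv1 <- select_iv1(tibble::tibble(variant_id = c("rs1", "rs2", "rs3")))
  expo_p <- tibble::tibble(variant_id = c("rs1", "rs2", "rs3"),
                           pvalue = c(1e-10, 0.03, 1e-12))
  assoc <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs3"),
    trait = c("CAD", "maternal_smoking", "CAD", "T2D"),
    pvalue = c(1e-9, 0.01, 0.5, 0.9),
    trait_class = c("outcome_disease", "confounder", "outcome_disease",
                    "outcome_disease")
  )
  s <- select_iv2(iv1, expo_p, assoc)
  expect_equal(s$variant_ids, "rs3")  # all trait P above threshold and own P
  excl <- s$exclusions
  expect_equal(excl$reason[excl$variant_id == "rs1"], "gwas_significance")
  expect_equal(excl$reason[excl$variant_id == "rs2"], "stronger_than_exposure")
  expect_match(excl$all_triggers[excl$variant_id == "rs1"], "CAD")

  # a variant absent from the table counts as no evidence
  iv1b <- select_iv1(tibble::tibble(variant_id = c("rs1", "rs4")))
  expo_b <- tibble::tibble(variant_id = c("rs1", "rs4"), pvalue = c(1e-10, 1e-8))
  expect_message(select_iv2(iv1b, expo_b, assoc), "no evidence")
  s2 <- suppressMessages(select_iv2(iv1b, expo_b, assoc))
  expect_true("rs4" %in% s2$variant_ids)
})

test_that("IV2 first-rule exclusions are monotone in the threshold", {
  cfg <- sim_config(n_variants = 30, seed = 17)
  assoc <- simulate_confounder_table(cfg, prop_pleiotropic = 0.3)
  iv1 <- select_iv1(tibble::tibble(variant_id = sprintf("rs%04d", 1:30)))
  # uniform exposure P values far below every trait P value isolate rule (a)
  expo <- tibble::tibble(variant_id = sprintf("rs%04d", 1:30), pvalue = 1e-30)
  sizes <- sapply(c(5e-8, 5e-6, 5e-4), function(thr) {
    nrow(select_iv2(iv1, expo, assoc, gwas_threshold = thr)$exclusions)
  })
  expect_true(all(diff(sizes) >= 0))  # stricter threshold excludes no more
})

test_that("IV3 pruning removes planted outliers first and stops at homogeneity", {
  hom <- tibble::tibble(variant_id = sprintf("v%02d", 1:6),
                        beta_x = seq(0.05, 0.3, length.out = 6), se_x = 0.01,
                        beta_y = 0.2 * seq(0.05, 0.3, length.out = 6),
                        se_y = 0.01)
  s0 <- select_iv3(hom)
  expect_equal(nrow(s0$exclusions), 0)
  expect_equal(s0$variant_ids, hom$variant_id)

  # one planted extreme ratio among 46: removed first, final set homogeneous
  iv <- sim_instruments(seed = 303, theta_true = 0.15)
  iv$beta_y[20] <- iv$beta_y[20] + 12 * iv$se_y[20]
  s1 <- select_iv3(iv)
  expect_equal(s1$exclusions$variant_id[1], iv$variant_id[20])
  expect_gte(attr(s1, "final_q")$pvalue, 0.05)
  expect_lte(nrow(s1$exclusions), nrow(iv) - 2)

  expect_error(select_iv3(hom[1:2, ]), "at least 3")
})

test_that("IV3 breaks exact contribution ties lexicographically", {
  x <- tibble::tibble(
    variant_id = c("rs_b", "rs_a", "v1", "v2", "v3", "v4"),
    beta_x = c(0.1, 0.1, 0.1, 0.12, 0.14, 0.16), se_x = 0.01,
    beta_y = c(0.09, 0.09, 0.02, 0.024, 0.028, 0.032),  # two identical outliers
    se_y = 0.01
  )
  s <- select_iv3(x)
  expect_equal(s$exclusions$variant_id[1:2], c("rs_a", "rs_b"))
})

test_that("removing the top Q contributor never increases Q after refit", {
  for (s in 1:20) {
    iv <- sim_instruments(seed = 600 + s, n_variants = 12, theta_true = 0.1,
                          pleiotropy_mode = "balanced", pleiotropy_sd = 0.004,
                          prop_invalid = 0.25)
    q0 <- cochran_q(iv)
    worst <- q0$contributions$variant_id[which.max(q0$contributions$q_contrib)]
    q1 <- cochran_q(iv[iv$variant_id != worst, ])
    expect_lte(q1$q, q0$q + 1e-12)
  }
})
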