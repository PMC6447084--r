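test_that("allele configurations resolve to the documented actions", {
  ex <- assoc_row("rs1", "A", "G", 0.1, eaf = 0.3)
  cases <- list(
    list(out = assoc_row("rs1", "A", "G", 0.05, eaf = 0.3),
         beta_y = 0.05, action = "unchanged"),
    list(out = assoc_row("rs1", "G", "A", 0.05, eaf = 0.7),
         beta_y = -0.05, action = "flipped"),
    list(out = assoc_row("rs1", "T", "C", 0.05, eaf = 0.3),   # strand complement
         beta_y = 0.05, action = "unchanged"),
    list(out = assoc_row("rs1", "C", "T", 0.05, eaf = 0.7),   # complement, swapped
         beta_y = -0.05, action = "flipped"),
    list(out = assoc_row("rs1", "A", "C", 0.05),              # irreconcilable
         beta_y = NA_real_, action = "dropped_mismatch")
  )
  for (cs in cases) {
    if (cs$action == "dropped_mismatch") {
      expect_warning(harmonize(ex, cs$out), "irreconcilable")
      h <- suppressWarnings(harmonize(ex, cs$out))
    } else {
      h <- harmonize(ex, cs$out)
    }
    expect_equal(h$beta_y, cs$beta_y, info = cs$action)
    expect_equal(h$harmonization_action, cs$action)
    expect_equal(h$beta_x, 0.1)
  }
})

test_that("palindromic variants follow the policy", {
  ex_amb <- assoc_row("rs1", "A", "T", 0.1, eaf = 0.50)
  out <- assoc_row("rs1", "A", "T", 0.05, eaf = 0.50)
  h <- harmonize(ex_amb, out, palindrome_policy = "infer_by_eaf",
                 eaf_ambiguity_band = 0.08)
  expect_equal(h$harmonization_action, "dropped_palindromic")

  # resolvable: both frequencies far from 0.5 and concordant
  ex <- assoc_row("rs2", "C", "G", 0.1, eaf = 0.2)
  same_side <- assoc_row("rs2", "C", "G", 0.05, eaf = 0.25)
  h2 <- harmonize(ex, same_side)
  expect_equal(h2$harmonization_action, "unchanged")
  expect_equal(h2$beta_y, 0.05)

  # discordant sides imply a strand flip of the same labels
  opp_side <- assoc_row("rs2", "C", "G", 0.05, eaf = 0.75)
  h3 <- harmonize(ex, opp_side)
  expect_equal(h3$harmonization_action, "flipped")
  expect_equal(h3$beta_y, -0.05)

  # drop policy removes palindromic variants regardless of eaf
  h4 <- harmonize(ex, same_side, palindrome_policy = "drop")
  expect_equal(h4$harmonization_action, "dropped_palindromic")

  # missing eaf is treated as ambiguous under infer_by_eaf
  h5 <- harmonize(ex, assoc_row("rs2", "C", "G", 0.05, eaf = NA))
  expect_equal(h5$harmonization_action, "dropped_palindromic")
})

test_that("duplicates and empty intersections are hard errors", {
  ex <- dplyr::bind_rows(assoc_row("rs1", "A", "G", 0.1),
                         assoc_row("rs1", "A", "G", 0.1))
  out <- assoc_row("rs1", "A", "G", 0.05)
  expect_error(harmonize(ex, out), "duplicated")
  expect_error(harmonize(assoc_row("rs1", "A", "G", 0.1),
                         assoc_row("rs9", "A", "G", 0.1)),
               "no shared variants")
})

test_that("record counts are conserved across actions and harmonization is idempotent", {
  sim <- simulate_two_sample(sim_config(n_variants = 40, seed = 11,
                                        flip_fraction = 0.5))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h), 40)  # full intersection present, action per record
  expect_setequal(unique(h$harmonization_action), c("unchanged", "flipped"))

  # rebuild canonical tables from the harmonized output; harmonizing again
  # must change nothing
  as_assoc <- function(h, beta, se) {
    tibble::tibble(variant_id = h$variant_id, effect_allele = h$effect_allele,
                   other_allele = h$other_allele, eaf = h$eaf,
                   beta = h[[beta]], se = h[[se]], pvalue = 0.5, n = 1e5)
  }
  h2 <- harmonize(as_assoc(h, "beta_x", "se_x"), as_assoc(h, "beta_y", "se_y"))
  expect_equal(h2$beta_y, h$beta_y)
  expect_equal(h2$beta_x, h$beta_x)
  expect_true(all(h2$harmonization_action == "unchanged"))
})

test_that("orientation flips signs jointly and preserves Wald ratios", {
  x <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    beta_x = c(-0.1, 0.05, 0.2), se_x = 0.01,
    beta_y = c(0.05, 0.01, -0.02), se_y = 0.004,
    eaf = c(0.3, 0.4, 0.5)
  )
  o <- orient_to_exposure(x)
  expect_true(all(o$beta_x > 0))
  expect_equal(o$beta_x[1], 0.1)
  expect_equal(o$beta_y[1], -0.05)
  expect_equal(o$se_y, x$se_y)
  expect_equal(o$eaf[1], 0.7)
  expect_equal(o$beta_y / o$beta_x, x$beta_y / x$beta_x)

  # already-positive input is untouched
  expect_equal(orient_to_exposure(x[2:3, ]), x[2:3, ])

  # exact zero is dropped with a warning
  x$beta_x[2] <- 0
  expect_warning(o2 <- orient_to_exposure(x), "exactly 0")
  expect_equal(nrow(o2), 2)
})
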