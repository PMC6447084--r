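#' Build and validate a full-analysis configuration
#'
#' One declarative configuration drives [run_analysis()]: where the summary
#' statistics come from (files, or the synthetic generator), how the three
#' nested instrument sets are built, estimator settings, the power grid and
#' the optional multivariable-MR block. A YAML file with the same field names
#' can be passed directly to [run_analysis()].
#'
#' @param exposure `NULL` for synthetic data, or
#'   `list(file =, column_map =, delim =)` for a summary-statistic file.
#' @param outcomes Named list, one entry per outcome. Synthetic mode:
#'   `list(theta_true =, n_outcome =, binary = FALSE, case_fraction = 0.33)`.
#'   File mode: `list(file =, column_map =, delim =, binary =)`.
#' @param sim A [sim_config()] (or list of its arguments) for synthetic mode;
#'   per-outcome `theta_true`/`n_outcome`/`binary` override it.
#' @param confounder_table `NULL` to simulate one (synthetic mode), a file
#'   path to a long TSV (`variant_id`, `trait`, `pvalue`, `trait_class`), or
#'   a tibble. `prop_pleiotropic` controls the simulated planting.
#' @param prop_pleiotropic Planted fraction for the simulated confounder
#'   table (default 12/58).
#' @param excluded_loci Variant IDs removed from IV1 (imprinted/manual loci).
#' @param gwas_threshold Genome-wide significance for IV2 (default 5e-8).
#' @param pruning_alpha Heterogeneity threshold for IV3 (default 0.05).
#' @param iv3_parent `"IV2"` (default) or `"IV1"`: the set IV3 pruning starts
#'   from.
#' @param variance_model IVW variance model, `"mre"` or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param penalty_scale Robust-IVW weight penalty (default 20).
#' @param mvmr `NULL`, or `list(thetas = c(name = effect, ...))` to simulate
#'   and fit a multivariable model, or `list(file =, exposures =)`.
#' @param power `NULL`, or a list of [power_grid()] arguments.
#' @param n_traits_bonferroni Optional trait count for a Bonferroni-adjusted
#'   P column (the study design tests many outcomes); `NULL` omits it.
#' @param palindrome_policy,eaf_ambiguity_band Passed to [harmonize()].
#' @param seed Root seed for every stochastic step (simulation and
#'   weighted-median bootstrap).
#' @param output_dir `NULL`, or a directory where [write_report()] output is
#'   placed by [run_analysis()].
#' @return A validated list of class `mr_analysis_config`.
#' @export
mr_config <- function(exposure = NULL,
                      outcomes = list(CAD = list(theta_true = -0.3,
                                                 binary = TRUE)),
                      sim = sim_config(),
                      confounder_table = NULL,
                      prop_pleiotropic = 12 / 58,
                      excluded_loci = character(),
                      gwas_threshold = 5e-8,
                      pruning_alpha = 0.05,
                      iv3_parent = c("IV2", "IV1"),
                      variance_model = c("mre", "fixed"),
                      n_boot = 1000,
                      penalty_scale = 20,
                      mvmr = NULL,
                      power = NULL,
                      n_traits_bonferroni = NULL,
                      palindrome_policy = "infer_by_eaf",
                      eaf_ambiguity_band = 0.08,
                      seed = 1,
                      output_dir = NULL) {
  iv3_parent <- arg_match(iv3_parent)
  variance_model <- arg_match(variance_model)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, as.list(sim))
  stopifnot(length(outcomes) >= 1, !is.null(names(outcomes)),
            all(names(outcomes) != ""))
  for (src in list(exposure, confounder_table)) {
    if (is.list(src) && !is.data.frame(src) && !is.null(src$file) &&
        !file.exists(src$file)) {
      abort(paste0("configured file does not exist: ", src$file))
    }
  }
  if (is.character(confounder_table) && !file.exists(confounder_table)) {
    abort(paste0("configured file does not exist: ", confounder_table))
  }
  for (nm in names(outcomes)) {
    f <- outcomes[[nm]]$file
    if (!is.null(f) && !file.exists(f)) {
      abort(paste0("configured file does not exist: ", f))
    }
  }
  sim$seed <- as.integer(seed)
  structure(list(
    exposure = exposure, outcomes = outcomes, sim = sim,
    confounder_table = confounder_table, prop_pleiotropic = prop_pleiotropic,
    excluded_loci = excluded_loci, gwas_threshold = gwas_threshold,
    pruning_alpha = pruning_alpha, iv3_parent = iv3_parent,
    variance_model = variance_model, n_boot = n_boot,
    penalty_scale = penalty_scale, mvmr = mvmr, power = power,
    n_traits_bonferroni = n_traits_bonferroni,
    palindrome_policy = palindrome_policy,
    eaf_ambiguity_band = eaf_ambiguity_band,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "mr_analysis_config")
}

#' Load a configuration from a YAML file
#' @noRd
.config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$mvmr) && !is.null(raw$mvmr$thetas)) {
    raw$mvmr$thetas <- unlist(raw$mvmr$thetas)
  }
  do.call(mr_config, raw)
}

#' Run the full two-sample MR analysis
#'
#' Orchestrates every stage from one configuration: obtain (or simulate)
#' exposure, outcome and confounder-association tables; harmonize each outcome
#' to the exposure; build IV1 (lead variants minus excluded loci), IV2
#' (pleiotropy-filtered) and IV3 (heterogeneity-pruned, per outcome); run the
#' four estimators (IVW, penalized robust IVW, weighted median, MR-Egger) on
#' every (outcome, IV) cell with Cochran's Q and Egger-intercept diagnostics;
#' leave-one-out on the main (IV2) model; optional multivariable MR and power
#' table. A failing cell is recorded with its reason; the pipeline continues.
#'
#' @param config An [mr_config()] object, or the path to a YAML file of its
#'   arguments.
#' @return An `mr_report`: a list with `estimates` (one row per
#'   outcome x IV x method), `instrument_sets`, `heterogeneity`, `loo`,
#'   `mvmr`, `power`, `harmonization`, and `log` (config hash, seed, package
#'   version). Written to `config$output_dir` when set.
#' @examples
#' \donttest{
#' cfg <- mr_config(outcomes = list(CAD = list(theta_true = -0.3, binary = TRUE)),
#'                  sim = sim_config(n_variants = 58), seed = 42, n_boot = 200)
#' rep <- run_analysis(cfg)
#' rep$estimates
#' }
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- .config_from_yaml(config)
  stopifnot(inherits(config, "mr_analysis_config"))

  synthetic <- is.null(config$exposure)
  outcome_names <- names(config$outcomes)

  # --- data acquisition -----------------------------------------------------
  outcome_tables <- list()
  truths <- list()
  if (synthetic) {
    for (k in seq_along(outcome_names)) {
      oc <- config$outcomes[[k]]
      cfg_k <- config$sim
      if (!is.null(oc$theta_true)) cfg_k$theta_true <- oc$theta_true
      if (!is.null(oc$n_outcome)) cfg_k$n_outcome <- oc$n_outcome
      if (isTRUE(oc$binary)) {
        cfg_k$binary_outcome <- TRUE
        if (!is.null(oc$case_fraction)) cfg_k$case_fraction <- oc$case_fraction
      }
      sim_k <- simulate_two_sample(cfg_k, outcome_stream = k)
      if (k == 1) exposure <- sim_k$exposure
      outcome_tables[[outcome_names[k]]] <- sim_k$outcome
      truths[[outcome_names[k]]] <- sim_k$truth
    }
  } else {
    exposure <- read_summary_stats(config$exposure$file,
                                   column_map = config$exposure$column_map,
                                   delim = config$exposure$delim %||% "\t")
    for (nm in outcome_names) {
      oc <- config$outcomes[[nm]]
      outcome_tables[[nm]] <- read_summary_stats(
        oc$file, column_map = oc$column_map, delim = oc$delim %||% "\t")
    }
  }

  assoc <- config$confounder_table
  if (is.null(assoc) && synthetic) {
    assoc <- simulate_confounder_table(config$sim,
                                       prop_pleiotropic = config$prop_pleiotropic)
  } else if (is.character(assoc)) {
    assoc <- readr::read_tsv(assoc, show_col_types = FALSE, progress = FALSE)
  }

  # --- instrument sets shared across outcomes -------------------------------
  iv1 <- select_iv1(exposure, excluded_loci = config$excluded_loci)
  iv2 <- if (!is.null(assoc)) {
    select_iv2(iv1, exposure[, c("variant_id", "pvalue")], assoc,
               gwas_threshold = config$gwas_threshold)
  } else {
    NULL
  }
  parent_label <- if (config$iv3_parent == "IV2" && !is.null(iv2)) "IV2" else "IV1"

  methods <- c("ivw", "ivw_penalized_robust", "weighted_median", "egger")
  est_rows <- list()
  q_rows <- list()
  loo_out <- list()
  sets_out <- list(IV1 = iv1)
  if (!is.null(iv2)) sets_out$IV2 <- iv2
  harmon_rows <- list()

  fit_cell <- function(inst, method, boot_seed) {
    tryCatch(switch(method,
      ivw = mr_ivw(inst, model = config$variance_model),
      ivw_penalized_robust =
        mr_ivw_penalized_robust(inst, penalty_scale = config$penalty_scale),
      weighted_median =
        mr_weighted_median(inst, n_boot = config$n_boot, seed = boot_seed),
      egger = mr_egger(inst)
    ), error = function(e) e)
  }

  for (k in seq_along(outcome_names)) {
    nm <- outcome_names[k]
    harm <- harmonize(exposure, outcome_tables[[nm]],
                      palindrome_policy = config$palindrome_policy,
                      eaf_ambiguity_band = config$eaf_ambiguity_band)
    harmon_rows[[nm]] <- dplyr::count(harm, .data$harmonization_action)
    harmon_rows[[nm]]$outcome <- nm
    oriented <- orient_to_exposure(harm)

    iv_sets <- list(IV1 = filter_instruments(oriented, iv1))
    if (!is.null(iv2)) iv_sets$IV2 <- filter_instruments(oriented, iv2)
    iv3 <- tryCatch(
      select_iv3(iv_sets[[parent_label]], alpha = config$pruning_alpha,
                 label = paste0("IV3_", nm)),
      error = function(e) e)
    if (!inherits(iv3, "error")) {
      iv_sets$IV3 <- filter_instruments(oriented, iv3)
      sets_out[[paste0("IV3_", nm)]] <- iv3
    }

    for (iv_label in names(iv_sets)) {
      inst <- iv_sets[[iv_label]]
      for (m in seq_along(methods)) {
        boot_seed <- .derive_seed(config$seed,
                                  1000L + 20L * k + 5L * match(iv_label,
                                                               c("IV1", "IV2", "IV3")) + m)
        est <- fit_cell(inst, methods[m], boot_seed)
        row <- .estimate_row(est, method = methods[m])
        row$method_detail <- row$method
        row$method <- methods[m]
        row$outcome <- nm
        row$iv <- iv_label
        est_rows[[length(est_rows) + 1L]] <- row
      }
      qr <- tryCatch(cochran_q(inst), error = function(e) e)
      if (!inherits(qr, "error")) {
        q_rows[[length(q_rows) + 1L]] <- tibble(
          outcome = nm, iv = iv_label, q = qr$q, df = qr$df, pvalue = qr$pvalue
        )
      }
    }

    main_label <- if ("IV2" %in% names(iv_sets)) "IV2" else "IV1"
    loo <- tryCatch(
      leave_one_out(iv_sets[[main_label]], method = "ivw"),
      error = function(e) e)
    if (!inherits(loo, "error")) {
      tab <- tidy(loo)
      tab$outcome <- nm
      tab$iv <- main_label
      loo_out[[nm]] <- tab
    }
  }

  estimates <- bind_rows(est_rows)
  estimates <- dplyr::select(estimates, "outcome", "iv", dplyr::everything())
  if (!is.null(config$n_traits_bonferroni)) {
    estimates$pvalue_bonferroni <- pmin(1, estimates$pvalue *
                                          config$n_traits_bonferroni)
  }
  # odds-ratio reporting for binary outcomes (estimation stays on log-odds)
  binary_outcomes <- outcome_names[vapply(config$outcomes,
                                          function(o) isTRUE(o$binary), logical(1))]
  estimates$odds_ratio <- ifelse(estimates$outcome %in% binary_outcomes,
                                 exp(estimates$theta), NA_real_)

  mvmr_res <- NULL
  if (!is.null(config$mvmr)) {
    mvmr_res <- tryCatch({
      if (!is.null(config$mvmr$thetas)) {
        tab <- simulate_mvmr_table(config$sim, thetas = config$mvmr$thetas)
        fit <- mr_mvmr(tab, exposures = paste0("beta_", names(config$mvmr$thetas)))
      } else {
        tab <- readr::read_tsv(config$mvmr$file, show_col_types = FALSE,
                               progress = FALSE)
        fit <- mr_mvmr(tab, exposures = config$mvmr$exposures)
      }
      tidy(fit)
    }, error = function(e) tibble(error = conditionMessage(e)))
  }

  power_tab <- if (!is.null(config$power)) do.call(power_grid, config$power) else NULL

  report <- structure(list(
    estimates = estimates,
    instrument_sets = bind_rows(lapply(sets_out, tidy)),
    instrument_set_summary = bind_rows(lapply(sets_out, glance)),
    heterogeneity = bind_rows(q_rows),
    loo = bind_rows(loo_out),
    mvmr = mvmr_res,
    power = power_tab,
    harmonization = bind_rows(harmon_rows),
    truth = if (synthetic) truths else NULL,
    log = list(
      # hash identifies the analysis, not where it is written
      config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                        "output_dir")]),
      seed = config$seed,
      package_version = as.character(packageVersion("mrpipe"))
    )
  ), class = "mr_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  cat(sprintf("  seed %d, config %s, mrpipe %s\n", x$log$seed,
              x$log$config_hash, x$log$package_version))
  cat(sprintf("  %d estimate cells (%d failed) across %d outcome(s)\n",
              nrow(x$estimates), sum(x$estimates$status == "failed"),
              length(unique(x$estimates$outcome))))
  print(x$instrument_set_summary)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' One machine-readable JSON plus one TSV per table.
#'
#' @param report An `mr_report` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("estimates", "instrument_sets", "instrument_set_summary",
            "heterogeneity", "loo", "mvmr", "power", "harmonization")
  for (nm in tabs) {
    if (!is.null(report[[nm]]) && nrow(report[[nm]]) > 0) {
      readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  json <- report[c(tabs, "log")]
  json <- json[!vapply(json, is.null, logical(1))]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
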