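#' Construct an instrument_set
#' @noRd
new_instrument_set <- function(label, retained, exclusions, parent) {
  stopifnot(is.character(retained),
            all(c("variant_id", "reason") %in% names(exclusions)))
  structure(list(
    label = label,
    variant_ids = retained,
    exclusions = as_tibble(exclusions),
    parent = parent
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set %s: %d retained, %d excluded (parent %d)>\n",
              x$label, length(x$variant_ids), nrow(x$exclusions),
              length(x$variant_ids) + nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    cat("  exclusions:\n")
    print(x$exclusions, n = 10)
  }
  invisible(x)
}

#' IV1: genome-wide significant lead variants minus manually excluded loci
#'
#' The widest instrument: all independent lead variants of the exposure GWAS,
#' after removing loci excluded on biological grounds (e.g. an imprinted locus
#' such as IGF2, where the fetal-effect interpretation of the per-allele
#' estimate breaks down).
#'
#' @param exposure_hits Tibble of the exposure GWAS lead variants (canonical
#'   layout; only `variant_id` is required).
#' @param excluded_loci Character vector of variant IDs to exclude; entries
#'   absent from `exposure_hits` produce a warning, not an error.
#' @return An `instrument_set` labelled `"IV1"`; see [tidy.instrument_set()].
#' @export
select_iv1 <- function(exposure_hits, excluded_loci = character()) {
  ids <- if (is.data.frame(exposure_hits)) exposure_hits$variant_id else
    as.character(exposure_hits)
  if (anyDuplicated(ids)) abort("duplicated variant_id among exposure hits")
  ghost <- setdiff(excluded_loci, ids)
  if (length(ghost) > 0) {
    warn(paste0("excluded_loci not among exposure hits: ",
                paste(ghost, collapse = ", ")))
  }
  hit <- intersect(excluded_loci, ids)
  new_instrument_set(
    label = "IV1",
    retained = setdiff(ids, hit),
    exclusions = tibble(variant_id = hit,
                        reason = rep("imprinting/manual", length(hit)),
                        trait = NA_character_),
    parent = ids
  )
}

#' IV2: pleiotropy-filtered instrument
#'
#' Removes from IV1 every variant with evidence of association with a listed
#' outcome disease or confounder trait, under either rule: (a) the trait
#' association reaches genome-wide significance (`pvalue < gwas_threshold`),
#' or (b) the trait association is stronger than the variant's own association
#' with the exposure (`pvalue < exposure pvalue`). A variant is excluded on
#' its first triggering trait (in the association table's order) but all
#' triggers are recorded.
#'
#' @param iv1 Parent `instrument_set` (typically from [select_iv1()]).
#' @param exposure_pvalues Tibble `variant_id`, `pvalue` (the exposure-GWAS
#'   P values) or a named numeric vector.
#' @param assoc Long-format confounder/disease association table:
#'   `variant_id`, `trait`, `pvalue` and optionally `trait_class`
#'   (`outcome_disease` or `confounder`).
#' @param gwas_threshold Genome-wide significance threshold (default 5e-8).
#' @return An `instrument_set` labelled `"IV2"`, exclusions carrying the
#'   triggering trait and rule (`gwas_significance` or
#'   `stronger_than_exposure`) plus an `all_triggers` audit column.
#' @export
select_iv2 <- function(iv1, exposure_pvalues, assoc, gwas_threshold = 5e-8) {
  stopifnot(inherits(iv1, "instrument_set"),
            gwas_threshold > 0, gwas_threshold < 1)
  if (is.data.frame(exposure_pvalues)) {
    expo_p <- setNames(exposure_pvalues$pvalue, exposure_pvalues$variant_id)
  } else {
    expo_p <- exposure_pvalues
  }
  miss_p <- setdiff(iv1$variant_ids, names(expo_p))
  if (length(miss_p) > 0) {
    abort(paste0("exposure P value missing for: ", paste(miss_p, collapse = ", ")))
  }
  assoc <- as_tibble(assoc)
  stopifnot(all(c("variant_id", "trait", "pvalue") %in% names(assoc)))

  no_evidence <- setdiff(iv1$variant_ids, unique(assoc$variant_id))
  if (length(no_evidence) > 0) {
    inform(paste0(length(no_evidence), " variant(s) absent from the association",
                  " table; treated as no evidence and retained"))
  }

  retained <- character()
  excl <- list()
  for (v in iv1$variant_ids) {
    rows <- assoc[assoc$variant_id == v, , drop = FALSE]
    if (nrow(rows) == 0) { retained <- c(retained, v); next }
    gw <- rows$pvalue < gwas_threshold
    st <- rows$pvalue < expo_p[[v]]
    trig <- gw | st
    if (!any(trig)) { retained <- c(retained, v); next }
    first <- which(trig)[1]
    rule <- if (gw[first]) "gwas_significance" else "stronger_than_exposure"
    all_trig <- paste0(rows$trait[trig], ":",
                       ifelse(gw[trig], "gwas_significance",
                              "stronger_than_exposure"),
                       collapse = ";")
    excl[[v]] <- tibble(variant_id = v, reason = rule,
                        trait = rows$trait[first], all_triggers = all_trig)
  }
  exclusions <- if (length(excl) > 0) bind_rows(excl) else
    tibble(variant_id = character(), reason = character(),
           trait = character(), all_triggers = character())
  new_instrument_set("IV2", retained, exclusions, parent = iv1$variant_ids)
}

#' IV3: heterogeneity-pruned instrument
#'
#' Stepwise downward selection: the IVW estimate and Cochran's Q are computed
#' on the current set; while Q's P value is below `alpha`, the single variant
#' with the largest Q contribution is removed (ties broken lexicographically
#' by variant ID) and the estimate refit. Stops when the heterogeneity test is
#' no longer significant or only two variants remain.
#'
#' @param instruments Oriented harmonized instruments (>= 3 rows) with a
#'   `variant_id` column.
#' @param alpha Heterogeneity significance threshold (default 0.05).
#' @param label Label for the resulting set (default `"IV3"`).
#' @return An `instrument_set`; exclusions carry `removal_order` and the Q
#'   P value at the time of removal. Attribute `"final_q"` holds the terminal
#'   `mr_q`.
#' @export
select_iv3 <- function(instruments, alpha = 0.05, label = "IV3") {
  x <- .check_instruments(instruments, min_n = 3)
  if (!"variant_id" %in% names(x)) x$variant_id <- paste0("v", seq_len(nrow(x)))
  stopifnot(alpha > 0, alpha < 1)
  parent <- x$variant_id
  removed <- list()
  k <- 0L
  repeat {
    qres <- cochran_q(x)
    if (qres$pvalue >= alpha || nrow(x) <= 2) break
    contrib <- qres$contributions
    worst <- contrib$variant_id[contrib$q_contrib == max(contrib$q_contrib)]
    worst <- sort(worst)[1]
    k <- k + 1L
    removed[[k]] <- tibble(variant_id = worst, reason = "heterogeneity",
                           removal_order = k, q_pvalue_at_removal = qres$pvalue)
    x <- x[x$variant_id != worst, , drop = FALSE]
  }
  exclusions <- if (k > 0) bind_rows(removed) else
    tibble(variant_id = character(), reason = character(),
           removal_order = integer(), q_pvalue_at_removal = numeric())
  out <- new_instrument_set(label, x$variant_id, exclusions, parent = parent)
  attr(out, "final_q") <- cochran_q(x)
  out
}

#' Subset an instrument table to an instrument set
#'
#' @param instruments Harmonized instrument tibble with `variant_id`.
#' @param set An `instrument_set` (or character vector of IDs).
#' @return The rows of `instruments` whose variants the set retains, in the
#'   set's order.
#' @export
filter_instruments <- function(instruments, set) {
  ids <- if (inherits(set, "instrument_set")) set$variant_ids else
    as.character(set)
  x <- as_tibble(instruments)
  x[match(intersect(ids, x$variant_id), x$variant_id), , drop = FALSE]
}
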