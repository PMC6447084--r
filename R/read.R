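#' Canonical columns of a GWAS summary-statistic table
#'
#' Every per-variant association record handled by mrpipe carries the variant
#' identifier, the two alleles, the effect-allele frequency, the per-allele
#' effect (`beta`, trait units or log-odds), its standard error, the
#' association P value and the sample size. `eaf`, `pvalue` and `n` may be
#' missing.
#'
#' @keywords internal
#' @noRd
.sumstats_mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
.sumstats_optional <- c("eaf", "pvalue", "n")
.sumstats_cols <- c(.sumstats_mandatory, .sumstats_optional)

#' Validate a summary-statistic tibble row-wise
#'
#' Returns a tibble of problems: one row per (line, field, message).
#' @noRd
.validate_sumstats <- function(x) {
  bad <- list()
  flag <- function(rows, field, msg) {
    if (any(rows)) {
      bad[[length(bad) + 1L]] <<- tibble(
        line = which(rows), field = field, message = msg
      )
    }
  }
  allele_ok <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(is.na(x$variant_id) | x$variant_id == "", "variant_id", "missing variant id")
  flag(!allele_ok(x$effect_allele), "effect_allele", "allele must be one of A/C/G/T")
  flag(!allele_ok(x$other_allele), "other_allele", "allele must be one of A/C/G/T")
  flag(allele_ok(x$effect_allele) & allele_ok(x$other_allele) &
         x$effect_allele == x$other_allele,
       "other_allele", "effect and other allele must differ")
  flag(is.na(x$beta) | !is.finite(x$beta), "beta", "beta must be a finite number")
  flag(is.na(x$se) | !(x$se > 0), "se", "se must be positive")
  flag(!is.na(x$eaf) & !(x$eaf > 0 & x$eaf < 1), "eaf", "eaf must lie in (0,1)")
  flag(!is.na(x$pvalue) & !(x$pvalue > 0 & x$pvalue <= 1),
       "pvalue", "pvalue must lie in (0,1]")
  flag(!is.na(x$n) & !(x$n > 0), "n", "n must be positive")
  if (length(bad) == 0) {
    return(tibble(line = integer(), field = character(), message = character()))
  }
  dplyr::arrange(bind_rows(bad), .data$line)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text file (gzip-transparent) of per-variant association
#' records into the canonical mrpipe layout: `variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`. Alleles are upper-cased.
#' Files whose headers differ from the canonical names are remapped through
#' `column_map`.
#'
#' @param path Path to a tab- or whitespace-delimited text file with a header
#'   row. `.gz` files are read transparently.
#' @param column_map Named character vector mapping canonical field names to
#'   the file's headers, e.g. `c(variant_id = "SNP", beta = "b")`. Only
#'   headers that differ need to be listed. Must cover at least
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`.
#' @param delim Field delimiter; `"\t"` (default) or `NULL` for
#'   arbitrary-whitespace tables.
#' @param on_invalid `"error"` (default) aborts listing the offending line
#'   numbers; `"warn"` drops invalid rows with a warning and attaches the
#'   problem table as attribute `"problems"`.
#'
#' @return A tibble with the canonical columns, one row per valid data row.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
#'              "rs1\ta\tg\t0.4\t0.03\t0.004\t1e-12\t150000"), f)
#' read_summary_stats(f, column_map = c(variant_id = "SNP", effect_allele = "EA",
#'   other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
#'   pvalue = "P", n = "N"))
#' @export
read_summary_stats <- function(path, column_map = NULL, delim = "\t",
                               on_invalid = c("error", "warn")) {
  on_invalid <- arg_match(on_invalid)
  if (!file.exists(path)) {
    abort(paste0("summary-statistic file not found: ", path))
  }
  raw <- if (is.null(delim)) {
    readr::read_table(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                      progress = FALSE, trim_ws = TRUE)
  }

  map <- setNames(.sumstats_cols, .sumstats_cols)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), .sumstats_cols)
    if (length(unknown) > 0) {
      abort(paste0("column_map names must be canonical fields; unknown: ",
                   paste(unknown, collapse = ", ")))
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- setdiff(map[.sumstats_mandatory], names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", "),
                 " (remap headers via column_map)"))
  }

  get_col <- function(field) {
    if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NA_character_
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- tibble(
    variant_id = get_col("variant_id"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    pvalue = num(get_col("pvalue")),
    n = num(get_col("n"))
  )
  # unparseable numerics: present in file but NA after coercion
  for (field in c("eaf", "beta", "se", "pvalue", "n")) {
    src <- get_col(field)
    if (all(is.na(src))) next
    bad <- !is.na(src) & src != "" & src != "NA" & is.na(out[[field]])
    if (any(bad) && on_invalid == "error") {
      abort(paste0("unparseable numeric in column '", field, "' at data line(s) ",
                   paste(which(bad), collapse = ", ")))
    }
  }

  problems <- .validate_sumstats(out)
  if (nrow(problems) > 0) {
    msg <- paste0("invalid summary-statistic row(s): ",
                  paste0("line ", problems$line, " [", problems$field, "] ",
                         problems$message, collapse = "; "))
    if (on_invalid == "error") abort(msg)
    warn(msg)
    out <- out[-unique(problems$line), , drop = FALSE]
  }
  attr(out, "problems") <- problems
  out
}

#' Write a summary-statistic or harmonized-instrument table as TSV
#'
#' @param x A tibble (canonical summary statistics, harmonized instruments,
#'   or any mrpipe table).
#' @param path Output path; `.gz` compresses transparently.
#' @return `x`, invisibly.
#' @export
write_mr_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}
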