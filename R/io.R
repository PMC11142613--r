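# Table IO: read/write delimited differential-results tables, with a
# column map whose defaults follow the DESeq2 results dialect, and the
# schema normalizer every builder funnels through.

#' Map input column names onto the results-table schema
#'
#' Defaults follow the DESeq2 results dialect: `log2FoldChange`, `pvalue`,
#' `padj`, `baseMean`. Exactly one of `fc`/`log2fc` may be mapped; the
#' other encoding is derived on read.
#'
#' @param feature_id,fc,log2fc,pvalue,padj,base_mean Column names in the
#'   input file, or `NA` to leave unmapped.
#' @return A named list of class `fc_column_map`.
#' @examples
#' column_map()
#' column_map(fc = "FoldChange", log2fc = NA)
#' @export
column_map <- function(feature_id = "feature_id", fc = NA,
                       log2fc = "log2FoldChange", pvalue = "pvalue",
                       padj = "padj", base_mean = "baseMean") {
  if (!is.na(fc) && !is.na(log2fc)) {
    abort("map exactly one of fc/log2fc, not both",
          class = "madfc_config_error")
  }
  if (is.na(fc) && is.na(log2fc)) {
    abort("one of fc/log2fc must be mapped", class = "madfc_config_error")
  }
  structure(list(feature_id = feature_id, fc = fc, log2fc = log2fc,
                 pvalue = pvalue, padj = padj, base_mean = base_mean),
            class = "fc_column_map")
}

#' Normalize a data frame to the results-table schema
#'
#' Accepts any data frame carrying fold change (`fc`) and/or log2 fold
#' change (`log2fc`) plus optional `feature_id`, `pvalue`, `padj`, and
#' `base_mean` columns; derives the missing fold-change encoding (checking
#' consistency when both are present), synthesizes feature ids when absent,
#' and validates that p-values lie in `[0, 1]`.
#'
#' @param data A data frame.
#' @inheritParams fold_change_units
#' @return A tibble with columns `feature_id`, `fc`, `log2fc`, `pvalue`,
#'   `padj`, `base_mean` (plus any extra input columns, untouched).
#' @examples
#' as_results_table(data.frame(log2fc = c(1, -1, 0), pvalue = 0.05))
#' @export
as_results_table <- function(data, policy = "propagate") {
  t <- as_tibble(data)
  has_fc <- "fc" %in% names(t)
  has_l <- "log2fc" %in% names(t)
  if (!has_fc && !has_l) {
    abort("need an fc or log2fc column", class = "madfc_config_error")
  }
  if (has_fc && has_l) {
    ok <- is.na(t$fc) | is.na(t$log2fc) |
      abs(t$log2fc - log2(pmax(t$fc, .Machine$double.xmin))) < 1e-6
    if (!all(ok)) {
      abort("fc and log2fc columns disagree; supply one of them",
            class = "madfc_config_error")
    }
  } else if (has_fc) {
    t$log2fc <- fc_to_log2(t$fc, policy = policy)
  } else {
    t$fc <- log2_to_fc(t$log2fc)
  }
  t$fc <- check_fc_domain(t$fc, policy = policy)
  if (!"feature_id" %in% names(t)) {
    t$feature_id <- sprintf("feature_%d", seq_len(nrow(t)))
  }
  if (!"pvalue" %in% names(t)) t$pvalue <- NA_real_
  if (!"padj" %in% names(t)) t$padj <- NA_real_
  if (!"base_mean" %in% names(t)) t$base_mean <- NA_real_
  for (col in c("pvalue", "padj")) {
    v <- t[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("%s values must lie in [0, 1]", col),
            class = "madfc_config_error")
    }
  }
  if (any(!is.na(t$base_mean) & t$base_mean < 0)) {
    abort("base_mean must be nonnegative", class = "madfc_config_error")
  }
  dplyr::relocate(t, "feature_id", "fc", "log2fc", "pvalue", "padj",
                  "base_mean")
}

#' Read a differential-results table from CSV/TSV
#'
#' The delimiter is sniffed from the file extension (`.csv` comma,
#' otherwise tab) unless given. Mapped columns are renamed onto the schema
#' and normalized with [as_results_table()]; unmapped extra columns are
#' preserved untouched. Counts of rows with missing or out-of-domain fold
#' changes are reported as messages.
#'
#' @param path File path.
#' @param colmap A [column_map()].
#' @inheritParams fold_change_units
#' @param delim Field delimiter; default sniffed from the extension.
#' @return A results tibble (see [as_results_table()]).
#' @export
read_results <- function(path, colmap = column_map(),
                         policy = "propagate", delim = NULL) {
  stopifnot(inherits(colmap, "fc_column_map"))
  delim <- delim %||%
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!nrow(raw)) abort("input table has no rows",
                        class = "madfc_config_error")
  required <- c("fc", "log2fc")
  for (field in names(colmap)) {
    src <- colmap[[field]]
    if (is.na(src)) next
    if (!src %in% names(raw)) {
      if (field %in% required) {
        abort(sprintf(
          "mapped column '%s' (for %s) not found; available: %s",
          src, field, paste(names(raw), collapse = ", ")
        ), class = "madfc_config_error")
      }
      next
    }
    names(raw)[names(raw) == src] <- field
  }
  t <- as_results_table(raw, policy = policy)
  n_bad <- sum(is.na(t$fc))
  if (n_bad > 0) {
    rlang::inform(sprintf(
      "%d of %d rows have missing or out-of-domain fold changes",
      n_bad, nrow(t)))
  }
  t
}

#' Write a results table to CSV/TSV
#'
#' Round-trips losslessly through [read_results()] with
#' `column_map(feature_id = "feature_id", fc = NA, log2fc = "log2fc",
#' pvalue = "pvalue", padj = "padj", base_mean = "base_mean")`. Optionally
#' appends the MAD display coordinate (`madfc`, equal to fold change
#' units) per row.
#'
#' @param data A results data frame.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param add_madfc Append a `madfc` column (default `FALSE`).
#' @return The written tibble, invisibly.
#' @export
write_results <- function(data, path, add_madfc = FALSE) {
  t <- as_results_table(data)
  if (add_madfc) t$madfc <- madfc_forward(t$fc, policy = "propagate")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(t, path, progress = FALSE)
  } else {
    readr::write_tsv(t, path, progress = FALSE)
  }
  invisible(t)
}
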