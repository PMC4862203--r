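#' Percentage breakdown of a clinical characteristic
#'
#' Computes the percentage each category contributes to its cohort total,
#' rounded to one decimal, as printed in cohort-characteristics tables.
#'
#' @param counts Named integer vector of category counts.
#' @param total Denominator; defaults to `sum(counts)` (pass the cohort size
#'   explicitly when categories exclude missing values).
#' @return Named numeric vector of percentages (one decimal).
#' @export
category_percentages <- function(counts, total = sum(counts)) {
  if (any(counts < 0) || total <= 0) stop_tg("counts must be non-negative with a positive total")
  round(100 * counts / total, 1)
}

#' Classification-consistency percentage
#'
#' The share of samples classified consistently by a set of models, as a
#' percentage of all samples considered, rounded to one decimal.
#'
#' @param n_consistent Number of consistently classified samples.
#' @param n_total Total samples.
#' @return Percentage (one decimal).
#' @export
concordance_summary <- function(n_consistent, n_total) {
  if (n_total <= 0 || n_consistent < 0 || n_consistent > n_total)
    stop_tg("need 0 <= n_consistent <= n_total with n_total > 0")
  round(100 * n_consistent / n_total, 1)
}

#' Read a cohort clinical-characteristics count table
#'
#' Reads a long-format TSV with columns `cohort`, `characteristic`,
#' `category`, `count` (the form in which published cohort tables are
#' transcribed) and returns it with per-characteristic percentages added.
#' The denominator for each characteristic is the cohort size, i.e. the
#' total over all categories of that characteristic including any
#' missing/NA category.
#'
#' @param path TSV path; defaults to the table bundled with the package.
#' @return Data frame with a `pct` column appended.
#' @export
read_clinical_characteristics <- function(path = system.file(
    "extdata", "clinical_characteristics.tsv", package = "tgrade")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort", "characteristic", "category", "count")
  if (!all(need %in% names(df)))
    stop_tg("characteristics table needs columns: %s", paste(need, collapse = ", "))
  df$pct <- NA_real_
  for (co in unique(df$cohort)) {
    for (ch in unique(df$characteristic[df$cohort == co])) {
      sel <- df$cohort == co & df$characteristic == ch
      df$pct[sel] <- category_percentages(df$count[sel])
    }
  }
  df
}
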