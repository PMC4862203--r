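#' Raw count matrix container
#'
#' A light S3 container for feature-by-sample RNA-seq raw counts at gene or
#' isoform level. Isoform-level matrices carry an isoform-to-gene map; any
#' isoform without a mapping is flagged unmapped rather than dropped.
#'
#' @param values Non-negative integer-valued matrix, features in rows,
#'   samples in columns.
#' @param feature_ids,sample_ids Character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param level `"gene"` or `"isoform"`.
#' @param iso2gene For isoform-level matrices, a named character vector
#'   mapping isoform ID to gene ID.
#' @return An object of class `tg_counts` with elements `values`, `level`,
#'   and (isoform level) `iso2gene` and `unmapped`.
#' @export
count_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values),
                         level = c("gene", "isoform"), iso2gene = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop_tg("count_matrix requires feature and sample identifiers")
  if (anyDuplicated(feature_ids))
    stop_tg("duplicate feature IDs: %s",
            paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_tg("duplicate sample IDs: %s",
            paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop_tg("counts must be finite and non-negative")
  if (max(abs(values - round(values))) > 1e-8)
    stop_tg("counts must be integer-valued")
  dimnames(values) <- list(feature_ids, sample_ids)
  unmapped <- character(0)
  if (level == "isoform") {
    if (!is.null(iso2gene)) {
      unmapped <- setdiff(feature_ids, names(iso2gene))
    } else {
      unmapped <- feature_ids
    }
  }
  structure(list(values = values, level = level,
                 iso2gene = iso2gene, unmapped = unmapped),
            class = "tg_counts")
}

#' @export
print.tg_counts <- function(x, ...) {
  cat(sprintf("tg_counts: %d %s-level features x %d samples\n",
              nrow(x$values), x$level, ncol(x$values)))
  if (length(x$unmapped))
    cat(sprintf("  %d isoforms without gene mapping\n", length(x$unmapped)))
  invisible(x)
}

#' @export
dim.tg_counts <- function(x) dim(x$values)

subset_counts <- function(counts, features = NULL, samples = NULL) {
  v <- counts$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  count_matrix(v, level = counts$level, iso2gene = counts$iso2gene)
}
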