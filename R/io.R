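#' Read a count matrix from TSV or MatrixMarket triplet
#'
#' TSV: features in rows, header row of sample IDs, first column of feature
#' IDs. MTX: a MatrixMarket file plus `<path>.rownames` / `<path>.colnames`
#' sidecar files (one ID per line). Entries must be non-negative integers;
#' duplicate IDs are rejected.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @param level,iso2gene Passed to [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              level = "gene", iso2gene = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    ids <- as.character(df[[1]])
    m <- suppressWarnings(
      vapply(df[, -1, drop = FALSE], as.numeric, numeric(nrow(df))))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1]))
    bad_row <- which(apply(m, 1, function(r)
      any(is.na(r) | r < 0 | r != round(r))))
    if (length(bad_row))
      stop_tg("non-numeric or negative count at line %d of %s",
              bad_row[1] + 1L, path)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop_tg("MTX requires sidecar files %s and %s", rn, cn)
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  }
  count_matrix(m, level = level, iso2gene = iso2gene)
}

#' Write a count matrix as TSV or MatrixMarket triplet
#'
#' @param counts A [count_matrix()].
#' @param path Output path (sidecar `.rownames`/`.colnames` files are
#'   written alongside MTX output).
#' @param format `"tsv"` or `"mtx"`.
#' @param gzip Compress TSV output with gzip.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx"),
                               gzip = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(counts, "tg_counts"))
  v <- counts$values
  if (format == "tsv") {
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(data.frame(feature_id = rownames(v), v,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
    writeLines(rownames(v), paste0(path, ".rownames"))
    writeLines(colnames(v), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a clinical table (CSV)
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop_tg("clinical CSV needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop_tg("duplicate sample_id in clinical CSV")
  df
}

#' @rdname read_clinical_table
#' @param clinical Data frame to write.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}
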