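#' Counts per million
#'
#' @param counts A [count_matrix()] or numeric matrix (features x samples).
#' @return Numeric matrix of CPM values, same dimensions.
#' @export
cpm <- function(counts) {
  v <- if (inherits(counts, "tg_counts")) counts$values else as.matrix(counts)
  libs <- colSums(v)
  if (any(libs <= 0))
    stop_tg("zero library size for sample(s): %s",
            paste(colnames(v)[libs <= 0], collapse = ", "))
  sweep(v, 2, libs, `/`) * 1e6
}

#' Filter features on a CPM threshold
#'
#' Keeps features whose CPM reaches `min_cpm` in at least `min_frac` of the
#' samples (inclusive boundary: with 4 samples and `min_frac = 0.75`, passing
#' in 3 of 4 keeps the feature). This is the isoform filter applied ahead of
#' all downstream analyses.
#'
#' @param counts A [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_frac Required fraction of samples in (0, 1] (default 0.75).
#' @return The filtered [count_matrix()], feature order preserved; the number
#'   of dropped features is reported via `message()` and attribute
#'   `n_dropped`.
#' @export
filter_by_cpm <- function(counts, min_cpm = 1, min_frac = 0.75) {
  stopifnot(inherits(counts, "tg_counts"))
  if (min_frac <= 0 || min_frac > 1) stop_tg("`min_frac` must be in (0, 1]")
  keep <- rowMeans(cpm(counts) >= min_cpm) >= min_frac
  out <- subset_counts(counts, features = which(keep))
  n_dropped <- sum(!keep)
  message(sprintf("filter_by_cpm: dropped %d of %d features", n_dropped,
                  length(keep)))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' TMM normalisation factors
#'
#' Trimmed-mean-of-M-values scaling factors (log-ratio trim 30 %, abundance
#' trim 5 %, precision-weighted mean of M-values against a reference sample),
#' computed by edgeR's implementation and rescaled to geometric mean 1. The
#' reference defaults to the library whose 75th-percentile CPM is closest to
#' the mean of those percentiles.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param ref_sample Optional reference column index or name.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  v <- if (inherits(counts, "tg_counts")) counts$values else as.matrix(counts)
  if (ncol(v) < 2) stop_tg("TMM needs at least two samples")
  if (any(colSums(v) <= 0)) stop_tg("TMM requires positive library sizes")
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(v))
  f <- tryCatch(
    edgeR::calcNormFactors(v, method = "TMM", refColumn = ref_sample),
    error = function(e) {
      warning("TMM trimming removed all genes; falling back to unit factors")
      rep(1, ncol(v))
    })
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(v))
}

#' Variance-stabilising log transform
#'
#' Computes median-of-ratios size factors (geometric-mean reference over
#' features with all-positive counts) and returns `log2(count / size_factor
#' + 1)`. This is a monotone variance-stabilising transform of the kind used
#' to prepare counts for prediction modelling; it is the package's own
#' transform, with the size-factor convention recorded in the result.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @return A list of class `tg_normalised` with `values` (transformed
#'   matrix), `size_factors` and `transform = "log-size-factor"`.
#' @export
vst_like_transform <- function(counts) {
  v <- if (inherits(counts, "tg_counts")) counts$values else as.matrix(counts)
  all_pos <- rowSums(v <= 0) == 0
  if (!any(all_pos)) {
    warning("no feature has all-positive counts; using library-size factors")
    sf <- colSums(v) / geometric_mean(colSums(v))
  } else {
    ref <- exp(rowMeans(log(v[all_pos, , drop = FALSE])))
    sf <- apply(v[all_pos, , drop = FALSE], 2, function(col)
      stats::median(col / ref))
  }
  vals <- log2(sweep(v, 2, sf, `/`) + 1)
  structure(list(values = vals, size_factors = stats::setNames(sf, colnames(v)),
                 transform = "log-size-factor"),
            class = "tg_normalised")
}

#' Per-dataset mean-centring
#'
#' Centres each feature to mean zero independently within two datasets that
#' share a feature space, removing global per-gene batch offsets ahead of
#' cross-dataset model transfer.
#'
#' @param matrixA,matrixB Numeric matrices (features x samples) with
#'   identical rownames in identical order.
#' @return List with centred `A` and `B`.
#' @export
mean_center <- function(matrixA, matrixB) {
  a <- as.matrix(matrixA); b <- as.matrix(matrixB)
  if (!identical(rownames(a), rownames(b))) {
    bad <- union(setdiff(rownames(a), rownames(b)),
                 setdiff(rownames(b), rownames(a)))
    stop_tg("feature sets differ or are reordered; offending IDs: %s",
            paste(utils::head(c(bad, "(order mismatch)"), 5), collapse = ", "))
  }
  list(A = a - rowMeans(a), B = b - rowMeans(b))
}
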