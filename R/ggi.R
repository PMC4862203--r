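#' Genomic-grade-index signature
#'
#' A GGI signature is two disjoint gene sets: genes up-regulated in grade-3
#' tumours and genes up-regulated in grade-1 tumours. The shipped raw score
#' is the unweighted up-minus-down expression sum (the probe weighting and
#' cohort-specific scale constant of the original microarray index are not
#' part of this package; the choice is recorded in the score's metadata).
#'
#' @param up_genes,down_genes Character vectors of gene IDs.
#' @return List of class `tg_ggi_signature`.
#' @export
ggi_signature <- function(up_genes, down_genes) {
  up <- unique(as.character(up_genes)); down <- unique(as.character(down_genes))
  if (length(intersect(up, down))) stop_tg("up and down gene sets overlap")
  if (!length(up) && !length(down)) stop_tg("signature is empty")
  structure(list(up = up, down = down), class = "tg_ggi_signature")
}

#' Read a GGI signature from a two-column TSV (gene_id, direction up/down)
#' @param path TSV file path.
#' @return A [ggi_signature()].
#' @export
read_ggi_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(df)))
    stop_tg("signature file needs columns gene_id and direction")
  ggi_signature(df$gene_id[df$direction == "up"],
                df$gene_id[df$direction == "down"])
}

#' Raw genomic grade index
#'
#' Per-sample raw score: sum of expression over the up (grade-3-associated)
#' genes minus the sum over the down (grade-1-associated) genes. Signature
#' genes absent from the matrix are dropped with a message.
#'
#' @param x Normalised expression matrix, features x samples.
#' @param sig A [ggi_signature()].
#' @return Named numeric vector of raw scores (one per sample).
#' @export
raw_ggi <- function(x, sig) {
  stopifnot(inherits(sig, "tg_ggi_signature"))
  x <- if (inherits(x, "tg_normalised")) x$values else as.matrix(x)
  up <- intersect(sig$up, rownames(x))
  down <- intersect(sig$down, rownames(x))
  n_missing <- (length(sig$up) - length(up)) + (length(sig$down) - length(down))
  if (!length(up) && !length(down))
    stop_tg("no signature gene present in the expression matrix")
  if (n_missing > 0)
    message(sprintf("raw_ggi: %d signature genes absent from the matrix",
                    n_missing))
  up_sum <- if (length(up)) colSums(x[up, , drop = FALSE]) else 0
  down_sum <- if (length(down)) colSums(x[down, , drop = FALSE]) else 0
  up_sum - down_sum
}

#' Train-anchored GGI standardisation to \[-1, 1\]
#'
#' Maps the training minimum to -1 and maximum to +1 and applies the same
#' affine map to the test scores (which may therefore fall outside
#' \[-1, 1\]).
#'
#' @param train_raw,test_raw Raw GGI scores.
#' @return List: `train`, `test`, `standardisation` (offset, scale) with the
#'   convention `standardised = scale * raw + offset`.
#' @export
standardise_ggi <- function(train_raw, test_raw = NULL) {
  rng <- range(train_raw)
  if (length(train_raw) < 2 || diff(rng) == 0)
    stop_tg("training GGI scores are constant; cannot standardise")
  scale <- 2 / diff(rng)
  offset <- -1 - scale * rng[1]
  list(train = scale * train_raw + offset,
       test = if (is.null(test_raw)) NULL else scale * test_raw + offset,
       standardisation = list(offset = offset, scale = scale))
}
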