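## shared small fixtures, built in code

toy_counts <- function(values, n_row, n_col, level = "gene") {
  m <- matrix(values, n_row, n_col, byrow = TRUE,
              dimnames = list(sprintf("g%d", seq_len(n_row)),
                              sprintf("s%d", seq_len(n_col))))
  count_matrix(m, level = level)
}

## independent brute-force TMM oracle: doubly trimmed, precision-weighted
## mean of M-values against an explicit reference column
tmm_oracle <- function(v, ref) {
  lib <- colSums(v)
  f <- vapply(seq_len(ncol(v)), function(j) {
    if (j == ref) return(1)
    x <- v[, j]; r <- v[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    M <- log2((x / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((x / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

## exhaustive pairwise concordance AUC (ties count one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## small strong-signal cohort reused by model tests
small_signal_cohort <- function(seed = 11, n = 160, genes = 250) {
  simulate_cohort(simulation_config(
    n_samples = n, n_genes = genes, frac_de = 0.1, lfc_scale = 2,
    frac_opposite = 0, dispersion = 0.1, seed = seed))
}

quick_spec <- function() elastic_net_spec(alpha_grid = c(0.1, 0.5, 0.9),
                                          n_lambda = 50)
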