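## log2-CPM with the 0.5 / +1 pseudo-count convention; effective library
## sizes carry the TMM scaling factors
.log_cpm <- function(v, norm_factors = NULL) {
  lib <- colSums(v)
  if (!is.null(norm_factors)) lib <- lib * norm_factors
  log2(sweep(v + 0.5, 2, lib + 1, `/`) * 1e6)
}

.de_design <- function(groups, covariates = NULL) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop_tg("exactly two groups are required")
  if (any(table(g) < 2)) stop_tg("each group needs at least 2 samples")
  if (is.null(covariates)) stats::model.matrix(~g)
  else stats::model.matrix(~ g + ., data = as.data.frame(covariates))
}

#' Precision weights from the count mean-variance trend
#'
#' Transforms counts to log2-CPM (0.5 pseudo-count) and estimates
#' per-observation precision weights from the fitted mean-variance
#' relationship: a lowess trend (span 0.5) of the square-root residual
#' standard deviation against mean log2-CPM, evaluated at each observation's
#' fitted value and inverted to the fourth power.
#'
#' Counts are placed on TMM-normalised effective library sizes before the
#' log transform, following the usual normalisation of count libraries ahead
#' of differential expression.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param groups Two-level group factor (>= 2 samples per group).
#' @param covariates Optional data frame of adjustment covariates.
#' @param norm_factors Per-sample scaling factors; the default computes
#'   [tmm_factors()] (unit factors if that fails on degenerate input).
#' @return List: `logcpm` (features x samples), `weights` (same shape,
#'   strictly positive), `trend` (the lowess fit).
#' @export
voom_weights <- function(counts, groups, covariates = NULL,
                         norm_factors = NULL) {
  v <- if (inherits(counts, "tg_counts")) counts$values else as.matrix(counts)
  design <- .de_design(groups, covariates)
  if (is.null(norm_factors))
    norm_factors <- tryCatch(suppressWarnings(tmm_factors(v)),
                             error = function(e) rep(1, ncol(v)))
  y <- .log_cpm(v, norm_factors)
  if (nrow(y) < 10) {
    warning("fewer than 10 features; mean-variance trend not fitted, unit weights used")
    return(list(logcpm = y, weights = array(1, dim(y), dimnames(y)),
                trend = NULL))
  }
  qrX <- qr(design)
  fitted <- t(qr.fitted(qrX, t(y)))
  res <- y - fitted
  df_resid <- ncol(y) - qrX$rank
  sd_res <- sqrt(rowSums(res^2) / df_resid)
  sx <- rowMeans(y)
  sy <- sqrt(sd_res)
  keep <- sd_res > 0
  lo <- stats::lowess(sx[keep], sy[keep], f = 0.5)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2)$y
  w <- 1 / pmax(pred, 1e-6)^4
  list(logcpm = y,
       weights = matrix(w, nrow(y), ncol(y), dimnames = dimnames(y)),
       trend = lo)
}

## Newton solve of trigamma(y) = x (vectorised scalar use)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t-statistics
#'
#' Per-feature weighted least-squares contrast of group 2 versus group 1,
#' with residual variances shrunk toward an inverse-chi-square prior whose
#' degrees of freedom `d0` and scale `s0^2` are estimated by
#' method-of-moments on the log residual variances. The moderated t uses
#' `d0 + d_resid` degrees of freedom. `prior = "none"` sets `d0 = 0`, giving
#' the ordinary t-statistic.
#'
#' @param logcpm Features-by-samples matrix (e.g. from [voom_weights()]).
#' @param weights Per-observation precision weights (same shape), or NULL
#'   for unit weights.
#' @param groups Two-level factor; the contrast is level 2 minus level 1.
#' @param covariates Optional adjustment covariates.
#' @param prior `"moments"` (default) or `"none"`.
#' @return Data frame of class `tg_de_table`: feature_id, log2fc,
#'   mean_logcpm, t, df, p, fdr, direction; attributes `d0`, `s0_sq`.
#' @export
moderated_t <- function(logcpm, weights = NULL, groups, covariates = NULL,
                        prior = c("moments", "none")) {
  prior <- match.arg(prior)
  y <- as.matrix(logcpm)
  design <- .de_design(groups, covariates)
  n <- ncol(y); pcol <- ncol(design)
  d_resid <- n - pcol
  if (d_resid <= 0) stop_tg("zero residual degrees of freedom")
  if (is.null(weights)) weights <- array(1, dim(y))
  G <- nrow(y)
  coefs <- se_unit <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    fit <- stats::lm.wfit(design, y[g, ], w)
    xtx_inv <- chol2inv(chol(crossprod(design * sqrt(w))))
    coefs[g] <- fit$coefficients[2]
    se_unit[g] <- sqrt(xtx_inv[2, 2])
    s2[g] <- sum(w * fit$residuals^2) / d_resid
  }
  if (prior == "none") {
    d0 <- 0; s0_sq <- NA_real_
    s2_post <- s2
  } else {
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(d_resid / 2) + log(d_resid / 2)
    t2 <- stats::var(e) - trigamma(d_resid / 2)
    if (is.finite(t2) && t2 > 0) {
      d0 <- 2 * .trigamma_inverse(t2)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
    s2_post <- if (is.infinite(d0)) rep(s0_sq, G) else
      (d0 * s0_sq + d_resid * s2) / (d0 + d_resid)
  }
  tstat <- coefs / (sqrt(s2_post) * se_unit)
  df_total <- d0 + d_resid
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(feature_id = rownames(y) %||% as.character(seq_len(G)),
                    log2fc = coefs, mean_logcpm = rowMeans(y),
                    t = tstat, df = df_total, p = p, fdr = bh_fdr(p),
                    direction = ifelse(coefs >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("tg_de_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()] after range
#' validation).
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_tg("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genes whose isoforms move in opposite directions
#'
#' Returns genes having at least one significantly up- and one significantly
#' down-regulated isoform at `fdr < fdr_cut` (strict) in an isoform-level
#' differential-expression table.
#'
#' @param iso_de A `tg_de_table` at isoform level.
#' @param iso2gene Named character vector, isoform ID to gene ID.
#' @param fdr_cut Significance cutoff on the FDR-adjusted p.
#' @return Character vector of gene IDs.
#' @export
opposite_direction_genes <- function(iso_de, iso2gene, fdr_cut = 0.05) {
  gene <- iso2gene[iso_de$feature_id]
  n_unmapped <- sum(is.na(gene))
  if (n_unmapped > 0)
    message(sprintf("opposite_direction_genes: %d unmapped isoforms skipped",
                    n_unmapped))
  sig <- iso_de$fdr < fdr_cut & !is.na(gene)
  if (!any(sig)) return(character(0))
  tab <- table(gene[sig], factor(iso_de$direction[sig],
                                 levels = c("down", "up")))
  sort(rownames(tab)[tab[, "up"] > 0 & tab[, "down"] > 0])
}

#' Gene- versus isoform-level differential-expression overlap
#'
#' Set algebra over the significant features of a gene-level and an
#' isoform-level analysis: how many genes are detected at both levels, how
#' many genes are detected only through their isoforms, and how many
#' significant isoforms belong to genes missed at the gene level.
#'
#' @param gene_de,iso_de `tg_de_table`s.
#' @param iso2gene Named isoform-to-gene map.
#' @param fdr_cut Significance cutoff (strict `<`).
#' @return List of counts: `n_gene_sig`, `n_iso_sig`, `n_iso_genes`,
#'   `genes_both_levels`, `isoform_only_genes`, `isoform_only_isoforms`.
#' @export
de_overlap_summary <- function(gene_de, iso_de, iso2gene, fdr_cut = 0.05) {
  sig_genes <- gene_de$feature_id[gene_de$fdr < fdr_cut]
  sig_iso <- iso_de$feature_id[iso_de$fdr < fdr_cut]
  iso_gene <- iso2gene[sig_iso]
  iso_gene_set <- unique(iso_gene[!is.na(iso_gene)])
  list(n_gene_sig = length(sig_genes),
       n_iso_sig = length(sig_iso),
       n_iso_genes = length(iso_gene_set),
       genes_both_levels = length(intersect(iso_gene_set, sig_genes)),
       isoform_only_genes = length(setdiff(iso_gene_set, sig_genes)),
       isoform_only_isoforms = sum(!is.na(iso_gene) &
                                     !(iso_gene %in% sig_genes)))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap with the query gene list is
#' larger than expected under hypergeometric sampling from the universe:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(N = |universe|,
#' K = |set in universe|, n = |query|)`. Benjamini-Hochberg adjustment is
#' applied across sets.
#'
#' @param de_genes Query gene IDs (must be a subset of `universe`).
#' @param universe Background gene IDs.
#' @param gene_sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @return Data frame: set_id, set_size, overlap, universe_size, de_size,
#'   p_hypergeom, fdr; ordered by p.
#' @export
hypergeom_ora <- function(de_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop_tg("empty universe")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stop_tg("query genes must be a subset of the universe")
  n <- length(de_genes); N <- length(universe)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    ov <- length(intersect(set, de_genes))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, overlap = ov, universe_size = N,
               de_size = n, p_hypergeom = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_hypergeom)
  out[order(out$p_hypergeom), ]
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of gene-ID character vectors; descriptions in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop_tg("malformed GMT line %d", bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}
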