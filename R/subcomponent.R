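#' Fit a penalised regression for one grade subcomponent
#'
#' Each Nottingham subcomponent (tubularity, nuclearity, mitotic count) is
#' modelled by an elastic-net penalised linear regression on the numeric
#' subscores 1/2/3. Samples with a missing score are excluded; tuning
#' mirrors the grade model with a squared-error criterion.
#'
#' @param x Samples-by-features matrix.
#' @param scores Subscores in \{1, 2, 3\}, NA allowed.
#' @param spec An [elastic_net_spec()].
#' @param inner_reps,inner_folds,seed Tuning CV settings.
#' @return A `tg_enet_model` (gaussian family) with attribute `n_used`.
#' @export
fit_subcomponent <- function(x, scores, spec = elastic_net_spec(),
                             inner_reps = 10, inner_folds = 10, seed = 1) {
  keep <- !is.na(scores)
  s <- scores[keep]
  if (!all(s %in% 1:3)) stop_tg("subscores must be 1, 2 or 3 (or NA)")
  if (length(unique(s)) < 2)
    stop_tg("need at least 2 distinct subscore values to fit")
  xs <- as.matrix(x)[keep, , drop = FALSE]
  tuned <- tune_alpha_lambda(xs, s, spec, inner_reps, inner_folds,
                             criterion = "mse", family = "gaussian",
                             seed = seed)
  model <- fit_elastic_net_logistic(xs, s, tuned$alpha, tuned$lambda,
                                    family = "gaussian",
                                    standardize = spec$standardize)
  attr(model, "n_used") <- sum(keep)
  model
}

#' Composite subcomponent grade prediction
#'
#' The composite score is exactly the sum of the three predicted subscores
#' (no re-scaling); the usual ROC machinery is applied to the composite for
#' grade-1-versus-3 evaluation and HG2 dichotomisation.
#'
#' @param model_T,model_N,model_M Fitted [fit_subcomponent()] models.
#' @param x Samples-by-features matrix to score.
#' @return Data frame: sample_id, pred_T, pred_N, pred_M, composite.
#' @export
composite_predict <- function(model_T, model_N, model_M, x) {
  for (m in list(model_T, model_N, model_M))
    if (!inherits(m, "tg_enet_model")) stop_tg("all three models are required")
  x <- as.matrix(x)
  pt <- predict(model_T, x); pn <- predict(model_N, x); pm <- predict(model_M, x)
  data.frame(sample_id = rownames(x) %||% seq_len(nrow(x)),
             pred_T = pt, pred_N = pn, pred_M = pm,
             composite = pt + pn + pm, stringsAsFactors = FALSE)
}
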