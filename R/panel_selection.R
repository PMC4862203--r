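#' Selection frequencies over cross-validation rounds
#'
#' Tallies, for every feature, in how many Monte-Carlo CV rounds the tuned
#' elastic-net model gave it a nonzero coefficient. Because the elastic net
#' performs variable selection, these frequencies rank features by the
#' robustness of their selection under data subsampling.
#'
#' @param cv_result A `tg_cv_result` from [nested_cv()].
#' @return Data frame: feature_id, times_selected, rounds; ordered by
#'   decreasing frequency.
#' @export
selection_frequency <- function(cv_result) {
  stopifnot(inherits(cv_result, "tg_cv_result"))
  rounds <- length(cv_result$rounds)
  tab <- table(unlist(lapply(cv_result$rounds, `[[`, "nonzero")))
  out <- data.frame(feature_id = names(tab),
                    times_selected = as.integer(tab),
                    rounds = rounds, stringsAsFactors = FALSE)
  out[order(-out$times_selected, out$feature_id), ]
}

#' Evaluate nested selection-frequency panels on an external cohort
#'
#' For each threshold `k`, the panel is the set of features selected in at
#' least `k` rounds (panels are therefore nested across thresholds). Each
#' panel is refitted on the training cohort with ridge-penalised logistic
#' regression (lambda tuned by 10-fold CV) and with plain logistic
#' regression, and scored by AUC on the external test cohort. The chosen
#' panel is the smallest one whose ridge AUC is within `tolerance` of the
#' best across thresholds.
#'
#' @param freq [selection_frequency()] table.
#' @param thresholds Integer thresholds (default the ten values from the
#'   round count down to round count minus 9, e.g. 99:90 for 100 rounds).
#' @param x_train,y_train Training cohort.
#' @param x_test,y_test External test cohort (disjoint samples).
#' @param tolerance AUC slack defining "maximal performance" (default
#'   0.005).
#' @param seed Seed for ridge-lambda CV folds.
#' @return List of class `tg_panel_report`: `table` (per-threshold panel
#'   size, ridge AUC, logistic AUC), `panels` (named list of feature IDs),
#'   `chosen_threshold`, `chosen_panel`.
#' @export
evaluate_threshold_panels <- function(freq, thresholds = NULL,
                                      x_train, y_train, x_test, y_test,
                                      tolerance = 0.005, seed = 1) {
  rounds <- freq$rounds[1]
  if (is.null(thresholds)) thresholds <- seq(rounds, max(rounds - 9, 1))
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  y_tr <- .as01(y_train); y_te <- .as01(y_test)
  panels <- list(); rows <- list()
  for (k in thresholds) {
    panel <- freq$feature_id[freq$times_selected >= k]
    if (!length(panel)) {
      warning(sprintf("no feature selected in >= %d rounds; threshold skipped", k))
      next
    }
    xtr <- as.matrix(x_train[, panel, drop = FALSE])
    xte <- as.matrix(x_test[, panel, drop = FALSE])
    set.seed(substream_seed(seed, 3000L + k))
    ridge_auc <- logit_auc <- NA_real_
    if (length(panel) >= 2) {
      cvr <- glmnet::cv.glmnet(xtr, y_tr, family = "binomial", alpha = 0,
                               nfolds = 10)
      p_r <- as.numeric(stats::predict(cvr, xte, s = "lambda.min",
                                       type = "response"))
      ridge_auc <- roc_auc(p_r, y_te)$auc
    } else {
      ridge_auc <- roc_auc(xte[, 1], y_te)$auc
    }
    glm_fit <- suppressWarnings(
      stats::glm(y ~ ., data = data.frame(y = y_tr, xtr),
                 family = stats::binomial()))
    p_g <- suppressWarnings(
      stats::predict(glm_fit, newdata = data.frame(xte), type = "response"))
    logit_auc <- roc_auc(as.numeric(p_g), y_te)$auc
    panels[[as.character(k)]] <- panel
    rows[[as.character(k)]] <- data.frame(threshold = k,
                                          panel_size = length(panel),
                                          ridge_auc = ridge_auc,
                                          logistic_auc = logit_auc)
  }
  if (!length(rows)) stop_tg("all thresholds produced empty panels")
  tab <- do.call(rbind, rows)
  best <- max(tab$ridge_auc)
  ok <- tab[tab$ridge_auc >= best - tolerance, ]
  chosen <- ok$threshold[which.min(ok$panel_size)]
  structure(list(table = tab, panels = panels,
                 chosen_threshold = chosen,
                 chosen_panel = panels[[as.character(chosen)]],
                 tolerance = tolerance),
            class = "tg_panel_report")
}

#' @export
print.tg_panel_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen: >= %d rounds, %d features\n", x$chosen_threshold,
              length(x$chosen_panel)))
  invisible(x)
}
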