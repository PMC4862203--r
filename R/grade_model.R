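#' Elastic-net model specification
#'
#' The mixing parameter alpha is evaluated on a fixed grid (default: the ten
#' points 0.001-0.9 used throughout the grading models) and, for each alpha,
#' lambda on a log-spaced path of `n_lambda` values from the data-driven
#' maximum down to `1e-4` times it.
#'
#' @param alpha_grid Ordered alpha values in \[0, 1\] (1 = lasso-like).
#' @param n_lambda Number of lambda path points.
#' @param standardize Standardise predictors internally (coefficients are
#'   always reported on the original scale).
#' @return List of class `tg_enet_spec`.
#' @export
elastic_net_spec <- function(alpha_grid = c(0.001, 0.005, 0.01, 0.05, 0.1,
                                            0.2, 0.3, 0.5, 0.7, 0.9),
                             n_lambda = 100, standardize = TRUE) {
  if (!length(alpha_grid) || any(alpha_grid < 0) || any(alpha_grid > 1))
    stop_tg("`alpha_grid` must be non-empty with values in [0, 1]")
  structure(list(alpha_grid = sort(alpha_grid), n_lambda = as.integer(n_lambda),
                 standardize = isTRUE(standardize)),
            class = "tg_enet_spec")
}

#' Class-balanced Monte-Carlo cross-validation splits
#'
#' Each round draws `round(test_frac * class size)` samples (at least one)
#' from every class into the test set, so both classes keep their prevalence
#' in training and test. The split list is deterministic under the seed and
#' is meant to be reused verbatim across all models being compared.
#'
#' @param labels Binary label vector (0/1, logical or 2-level factor).
#' @param rounds Number of Monte-Carlo rounds.
#' @param test_frac Fraction of each class held out per round.
#' @param seed Master seed.
#' @return List of length `rounds`; each element has integer `train` and
#'   `test` index vectors.
#' @export
make_mc_splits <- function(labels, rounds = 100, test_frac = 0.1, seed = 1) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop_tg("labels must contain exactly two classes")
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  if (length(idx0) < 2 || length(idx1) < 2)
    stop_tg("each class needs at least 2 members for balanced splitting")
  n0 <- max(1L, round(test_frac * length(idx0)))
  n1 <- max(1L, round(test_frac * length(idx1)))
  lapply(seq_len(rounds), function(r) {
    test <- with_substream(seed, 100L + r,
      c(sample(idx0, n0), sample(idx1, n1)))
    list(train = setdiff(seq_along(y), test), test = sort(test))
  })
}

.as01 <- function(y) {
  y01 <- as.integer(factor(y)) - 1L
  if (length(unique(y01)) != 2) stop_tg("response must have exactly two classes")
  y01
}

.binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Fit an elastic-net penalised regression at fixed (alpha, lambda)
#'
#' Minimises the penalised binomial deviance (or squared error for
#' `family = "gaussian"`) with penalty `lambda * (alpha * |b|_1 +
#' (1 - alpha) * |b|_2^2 / 2)` on internally standardised predictors,
#' delegating the solve to glmnet, whose penalty parameterisation matches
#' this contract. Coefficients are reported on the original predictor scale.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Binary response (logistic) or numeric response (gaussian).
#' @param alpha,lambda Penalty mixing and strength.
#' @param family `"binomial"` or `"gaussian"`.
#' @param standardize Standardise predictors internally.
#' @param ... Further arguments passed to [glmnet::glmnet()] (e.g. `thresh`
#'   for a tighter convergence tolerance).
#' @return List of class `tg_enet_model`: `intercept`, named `coefficients`,
#'   `nonzero` (feature IDs with nonzero coefficients), `alpha`, `lambda`,
#'   `family`, `features` (training feature order).
#' @export
fit_elastic_net_logistic <- function(x, y, alpha, lambda,
                                     family = c("binomial", "gaussian"),
                                     standardize = TRUE, ...) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_tg("predictor matrix must be finite")
  if (family == "binomial") y <- .as01(y)
  fit <- glmnet::glmnet(x, y, family = family, alpha = alpha,
                        standardize = standardize, nlambda = 100,
                        lambda.min.ratio = 1e-4, ...)
  cf <- tryCatch(
    as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                          family = family, alpha = alpha,
                          standardize = standardize, ...)),
    error = function(e) as.matrix(stats::coef(fit, s = lambda)))
  beta <- cf[-1, 1]
  structure(list(intercept = cf[1, 1],
                 coefficients = stats::setNames(beta, colnames(x)),
                 nonzero = colnames(x)[beta != 0],
                 alpha = alpha, lambda = lambda, family = family,
                 features = colnames(x)),
            class = "tg_enet_model")
}

#' Predict from a fitted elastic-net model
#'
#' @param object A `tg_enet_model`.
#' @param newdata Matrix with the model's features as columns (extra columns
#'   ignored; missing features are an error).
#' @param ... Unused.
#' @return Probabilities of the positive class (logistic) or fitted values
#'   (gaussian).
#' @export
predict.tg_enet_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop_tg("newdata lacks %d model features (e.g. %s)", length(missing),
            paste(utils::head(missing, 3), collapse = ", "))
  eta <- object$intercept +
    drop(newdata[, object$features, drop = FALSE] %*% object$coefficients)
  if (object$family == "binomial") stats::plogis(eta) else eta
}

## stratified (binomial) or plain (gaussian) fold assignment
.make_folds <- function(y, k, family) {
  n <- length(y)
  fold <- integer(n)
  if (family == "binomial") {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Tune (alpha, lambda) by repeated k-fold cross-validation
#'
#' For each alpha on the grid, the lambda path is taken from a full-data fit
#' (log-spaced from the data-driven maximum down to `1e-4` of it) and
#' evaluated by `inner_reps` repetitions of stratified `inner_folds`-fold
#' cross-validation. The pair minimising the chosen criterion is returned;
#' ties are broken toward larger lambda, then larger alpha. A repetition in
#' which some fold lacks a class is redrawn (with a message).
#'
#' @param x Samples-by-features matrix.
#' @param y Response.
#' @param spec An [elastic_net_spec()].
#' @param inner_reps,inner_folds Repetitions and folds of the inner CV.
#' @param criterion `"misclass"` (error at probability 0.5), `"deviance"`
#'   (mean binomial deviance) or `"mse"` (gaussian).
#' @param family Model family.
#' @param seed Seed for fold assignment.
#' @return List with `alpha`, `lambda`, `value` (criterion at the optimum)
#'   and the full `grid` (data frame alpha/lambda/value).
#' @export
tune_alpha_lambda <- function(x, y, spec = elastic_net_spec(),
                              inner_reps = 10, inner_folds = 10,
                              criterion = c("misclass", "deviance", "mse"),
                              family = c("binomial", "gaussian"), seed = 1) {
  criterion <- match.arg(criterion)
  family <- match.arg(family)
  x <- as.matrix(x)
  if (family == "binomial") y <- .as01(y) else y <- as.numeric(y)
  grid_rows <- vector("list", length(spec$alpha_grid))
  for (ai in seq_along(spec$alpha_grid)) {
    alpha <- spec$alpha_grid[ai]
    ## small inner folds routinely trip glmnet's class-size caution; the
    ## repeated-CV averaging is the guard here
    path <- suppressWarnings(
      glmnet::glmnet(x, y, family = family, alpha = alpha,
                     standardize = spec$standardize,
                     nlambda = spec$n_lambda, lambda.min.ratio = 1e-4))
    lam <- path$lambda
    loss_sum <- numeric(length(lam))
    loss_n <- 0
    set.seed(substream_seed(seed, 500L + ai))
    for (r in seq_len(inner_reps)) {
      ok <- FALSE
      for (attempt in 1:10) {
        fold <- .make_folds(y, inner_folds, family)
        if (family != "binomial" ||
            all(vapply(seq_len(inner_folds), function(f)
              length(unique(y[fold != f])) == 2, TRUE))) { ok <- TRUE; break }
        message("inner CV: redrawing repetition with a single-class fold")
      }
      if (!ok) next
      for (f in seq_len(inner_folds)) {
        tr <- fold != f
        if (!any(!tr)) next
        fit <- suppressWarnings(
          glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                         alpha = alpha, lambda = lam,
                         standardize = spec$standardize))
        pred <- stats::predict(fit, x[!tr, , drop = FALSE],
                               s = lam, type = "response")
        yt <- y[!tr]
        loss <- switch(criterion,
          misclass = colMeans((pred >= 0.5) != yt),
          deviance = apply(pred, 2, function(p) .binomial_deviance(yt, p)),
          mse = colMeans((pred - yt)^2))
        loss_sum <- loss_sum + loss * length(yt)
        loss_n <- loss_n + length(yt)
      }
    }
    grid_rows[[ai]] <- data.frame(alpha = alpha, lambda = lam,
                                  value = loss_sum / loss_n)
  }
  grid <- do.call(rbind, grid_rows)
  cand <- grid[grid$value <= min(grid$value) + 1e-12, ]
  cand <- cand[cand$lambda >= max(cand$lambda) - 1e-12, ]
  cand <- cand[which.max(cand$alpha), ]
  list(alpha = cand$alpha, lambda = cand$lambda, value = cand$value,
       grid = grid)
}

#' Nested Monte-Carlo cross-validation of the transcriptomic grade model
#'
#' For every outer Monte-Carlo round: tune (alpha, lambda) on the training
#' portion by inner repeated k-fold CV, fit the elastic-net logistic model,
#' and record held-out probabilities of the positive (grade 3) class. All
#' held-out predictions are pooled before the ROC is drawn.
#'
#' @param x Samples-by-features normalised expression matrix.
#' @param y Binary grade labels (positive class = high grade).
#' @param spec An [elastic_net_spec()].
#' @param splits Splits from [make_mc_splits()].
#' @param inner_reps,inner_folds Inner-CV shape.
#' @param criterion Inner-CV tuning criterion.
#' @param seed Master seed.
#' @return List of class `tg_cv_result`: `rounds` (per-round alpha, lambda,
#'   selected features, test indices, probabilities), `pooled` (data frame of
#'   all held-out predictions), `roc` (pooled [roc_auc()]), `auc`, `ci`,
#'   `threshold` (top-left cutoff on the pooled ROC).
#' @export
nested_cv <- function(x, y, spec = elastic_net_spec(), splits,
                      inner_reps = 10, inner_folds = 10,
                      criterion = "misclass", seed = 1) {
  x <- as.matrix(x)
  y01 <- .as01(y)
  rounds <- vector("list", length(splits))
  pooled <- list()
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    tuned <- tune_alpha_lambda(x[tr, , drop = FALSE], y01[tr], spec,
                               inner_reps, inner_folds, criterion,
                               family = "binomial",
                               seed = substream_seed(seed, 1000L + r))
    ## small-class warnings are routine at Monte-Carlo training sizes; the
    ## held-out evaluation is the safeguard
    model <- suppressWarnings(
      fit_elastic_net_logistic(x[tr, , drop = FALSE], y01[tr],
                               tuned$alpha, tuned$lambda,
                               standardize = spec$standardize))
    p <- predict(model, x[te, , drop = FALSE])
    rounds[[r]] <- list(train = tr, test = te, alpha = tuned$alpha,
                        lambda = tuned$lambda, nonzero = model$nonzero,
                        prob = p)
    pooled[[r]] <- data.frame(sample = te, label = y01[te], prob = p,
                              round = r)
  }
  pooled <- do.call(rbind, pooled)
  roc <- roc_auc(pooled$prob, pooled$label)
  structure(list(rounds = rounds, pooled = pooled, roc = roc,
                 auc = roc$auc, ci = roc$ci,
                 threshold = select_threshold(roc)),
            class = "tg_cv_result")
}

#' @export
print.tg_cv_result <- function(x, ...) {
  cat(sprintf("nested MC CV: %d rounds, pooled AUC = %.3f (95%% CI %.3f-%.3f), threshold %.3f\n",
              length(x$rounds), x$auc, x$ci[1], x$ci[2], x$threshold))
  invisible(x)
}

#' Dichotomised grade calls
#'
#' @param sample_id Sample identifiers.
#' @param probability Probability of the high-grade class.
#' @param threshold Decision cutoff; a probability greater than or equal to
#'   the cutoff is called high.
#' @param high,low Labels for the two calls.
#' @return Data frame: sample_id, probability, threshold, label.
#' @export
grade_calls <- function(sample_id, probability, threshold,
                        high = "TG-High", low = "TG-Low") {
  assert_prob(probability, "probability")
  data.frame(sample_id = sample_id, probability = probability,
             threshold = threshold,
             label = ifelse(probability >= threshold, high, low),
             stringsAsFactors = FALSE)
}

#' Reclassify intermediate-grade samples
#'
#' Scores grade-2 samples with a model trained on grade 1 versus grade 3 and
#' labels them HG2-High when the predicted probability is greater than or
#' equal to the cutoff, HG2-Low otherwise.
#'
#' @param model A `tg_enet_model` trained on grade 1/3.
#' @param threshold Decision cutoff (typically [select_threshold()] on the
#'   pooled CV ROC).
#' @param x_hg2 Matrix of grade-2 samples (rows) on the model's features.
#' @return [grade_calls()] data frame with HG2-High / HG2-Low labels.
#' @export
reclassify_hg2 <- function(model, threshold, x_hg2) {
  p <- predict(model, x_hg2)
  grade_calls(rownames(x_hg2) %||% seq_along(p), p, threshold,
              high = "HG2-High", low = "HG2-Low")
}

#' Cross-dataset validation of the grade model
#'
#' Restricts both cohorts to their shared feature space, mean-centres each
#' dataset independently, tunes (alpha, lambda) on the training cohort by
#' repeated 10-fold CV minimising the mean binomial deviance, fits once, and
#' scores the test cohort, reporting the AUC on its grade-1/3 samples.
#'
#' @param x_train,y_train Training cohort (samples x features, binary grade).
#' @param x_test,y_test Test cohort.
#' @param spec An [elastic_net_spec()].
#' @param inner_reps,inner_folds Tuning CV shape (the reference analysis uses
#'   100 x 10-fold).
#' @param seed Seed.
#' @return List: `auc`, `ci`, `roc`, `model`, `calls` ([grade_calls()] on the
#'   test cohort with the training-data top-left threshold), `n_shared`,
#'   `n_dropped` features.
#' @export
cross_dataset_validate <- function(x_train, y_train, x_test, y_test,
                                   spec = elastic_net_spec(),
                                   inner_reps = 100, inner_folds = 10,
                                   seed = 1) {
  shared <- intersect(colnames(x_train), colnames(x_test))
  if (length(shared) < 2) stop_tg("fewer than 2 shared features across datasets")
  n_dropped <- (ncol(x_train) - length(shared)) + (ncol(x_test) - length(shared))
  if (n_dropped > 0)
    message(sprintf("cross_dataset_validate: dropped %d unshared features",
                    n_dropped))
  xa <- scale(x_train[, shared, drop = FALSE], center = TRUE, scale = FALSE)
  xb <- scale(x_test[, shared, drop = FALSE], center = TRUE, scale = FALSE)
  tuned <- tune_alpha_lambda(xa, y_train, spec, inner_reps, inner_folds,
                             criterion = "deviance", family = "binomial",
                             seed = substream_seed(seed, 2000L))
  model <- fit_elastic_net_logistic(xa, .as01(y_train), tuned$alpha,
                                    tuned$lambda,
                                    standardize = spec$standardize)
  p_train <- predict(model, xa)
  thr <- select_threshold(roc_auc(p_train, .as01(y_train)))
  p_test <- predict(model, xb)
  roc <- roc_auc(p_test, .as01(y_test))
  list(auc = roc$auc, ci = roc$ci, roc = roc, model = model,
       calls = grade_calls(rownames(xb) %||% seq_along(p_test), p_test, thr),
       threshold = thr, n_shared = length(shared), n_dropped = n_dropped,
       alpha = tuned$alpha, lambda = tuned$lambda)
}
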