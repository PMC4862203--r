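test_that("Monte-Carlo splits are class-balanced and deterministic", {
  y <- c(rep(0, 10), rep(1, 20))
  sp <- make_mc_splits(y, rounds = 25, test_frac = 0.1, seed = 3)
  expect_length(sp, 25)
  for (s in sp) {
    expect_equal(sum(y[s$test] == 0), 1)
    expect_equal(sum(y[s$test] == 1), 2)
    expect_setequal(c(s$train, s$test), seq_along(y))
  }
  expect_identical(sp, make_mc_splits(y, 25, 0.1, seed = 3))
  expect_false(identical(sp, make_mc_splits(y, 25, 0.1, seed = 4)))
  expect_error(make_mc_splits(rep(1, 10)), "two classes")
  expect_error(make_mc_splits(c(0, rep(1, 9))), "at least 2")
})

test_that("elastic-net limits behave as the penalty dictates", {
  set.seed(21)
  x <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(200, 1, 0.35)
  ## full shrinkage: all coefficients zero, intercept = logit prevalence
  m_inf <- fit_elastic_net_logistic(x, y, alpha = 0.5, lambda = 1e6)
  expect_length(m_inf$nonzero, 0)
  expect_equal(m_inf$intercept, qlogis(mean(y)), tolerance = 1e-6)
  ## unpenalised fit separates a separable two-feature toy perfectly
  xs <- cbind(a = c(rnorm(40, -3), rnorm(40, 3)), b = rnorm(80))
  ys <- rep(c(0, 1), each = 40)
  m0 <- fit_elastic_net_logistic(xs, ys, alpha = 0.5, lambda = 0)
  expect_equal(mean((predict(m0, xs) >= 0.5) == ys), 1)
  ## duplicate features: lasso picks at most one, ridge splits evenly
  xd <- cbind(u = c(rnorm(50, -1), rnorm(50, 1)))
  xd <- cbind(xd, v = xd[, "u"], w = rnorm(100))
  yd <- rep(c(0, 1), each = 50)
  m_l1 <- fit_elastic_net_logistic(xd, yd, alpha = 1, lambda = 0.05,
                                   thresh = 1e-12)
  expect_lte(sum(abs(m_l1$coefficients[c("u", "v")]) > 1e-8), 1)
  m_l2 <- fit_elastic_net_logistic(xd, yd, alpha = 0, lambda = 0.05,
                                   thresh = 1e-14)
  expect_equal(m_l2$coefficients[["u"]], m_l2$coefficients[["v"]],
               tolerance = 1e-6)
})

test_that("the regularisation path deactivates features as lambda grows", {
  set.seed(2)
  x <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(80, 1, plogis(x[, 1] - x[, 2]))
  lams <- exp(seq(log(0.001), log(0.5), length.out = 12))
  nz <- vapply(lams, function(l)
    length(fit_elastic_net_logistic(x, y, alpha = 0.9, lambda = l)$nonzero), 0L)
  expect_true(all(diff(nz) <= 0))
})

test_that("tuning finds planted signal and shrinks pure noise", {
  spec <- quick_spec()
  ## pure noise: held-out misclassification ~ minority-class rate
  set.seed(14)
  xn <- matrix(rnorm(120 * 40), 120, 40,
               dimnames = list(NULL, paste0("f", 1:40)))
  yn <- rep(c(0, 1), times = c(40, 80))
  tn <- tune_alpha_lambda(xn, yn, spec, inner_reps = 2, inner_folds = 5,
                          criterion = "misclass", seed = 5)
  expect_lt(abs(tn$value - 1 / 3), 0.12)
  ## single-alpha grid reduces to a lambda-path search
  t1 <- tune_alpha_lambda(xn, yn, elastic_net_spec(alpha_grid = 0.5),
                          inner_reps = 1, inner_folds = 5, seed = 5)
  expect_equal(t1$alpha, 0.5)
  ## planted 5-gene signal is recovered across seeds
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(NULL, paste0("f", 1:60)))
    y <- rbinom(200, 1, plogis(1.5 * rowSums(x[, 1:5])))
    tt <- tune_alpha_lambda(x, y, spec, inner_reps = 1, inner_folds = 5,
                            criterion = "misclass", seed = s)
    m <- fit_elastic_net_logistic(x, y, tt$alpha, tt$lambda)
    sum(paste0("f", 1:5) %in% m$nonzero) >= 4
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("nested CV is deterministic and leaks nothing across the split", {
  co <- small_signal_cohort()
  x <- t(vst_like_transform(co$genes)$values)
  hg13 <- co$clinical$grade %in% c(1, 3)
  y <- as.integer(co$clinical$grade[hg13] == 3)
  spec <- quick_spec()
  sp <- make_mc_splits(y, rounds = 5, test_frac = 0.1, seed = 2)
  cv1 <- nested_cv(x[hg13, ], y, spec, sp, inner_reps = 1, inner_folds = 5,
                   seed = 9)
  cv2 <- nested_cv(x[hg13, ], y, spec, sp, inner_reps = 1, inner_folds = 5,
                   seed = 9)
  expect_identical(cv1$pooled, cv2$pooled)
  expect_true(all(cv1$pooled$prob >= 0 & cv1$pooled$prob <= 1))
  expect_gt(cv1$auc, 0.9)  # strong planted signal

  ## leakage probe: on label-free noise, a feature uniquely identifying each
  ## sample must not lift the held-out AUC above chance
  set.seed(33)
  n <- 60
  xn <- cbind(matrix(rnorm(n * 20), n, 20), id = seq_len(n) / n)
  colnames(xn) <- c(paste0("f", 1:20), "id")
  yn <- sample(rep(c(0, 1), each = 30))  # labels independent of everything
  spn <- make_mc_splits(yn, rounds = 10, test_frac = 0.2, seed = 1)
  cvn <- nested_cv(xn, yn, elastic_net_spec(alpha_grid = c(0.5)), spn,
                   inner_reps = 1, inner_folds = 5, seed = 4)
  expect_gt(cvn$auc, 0.25)
  expect_lt(cvn$auc, 0.75)
})

test_that("probability at the cutoff is called high grade", {
  model <- structure(list(intercept = 0, coefficients = c(f1 = 1),
                          nonzero = "f1", alpha = 0.5, lambda = 0.1,
                          family = "binomial", features = "f1"),
                     class = "tg_enet_model")
  x2 <- matrix(c(0, -2, 2), ncol = 1,
               dimnames = list(c("a", "b", "c"), "f1"))
  calls <- reclassify_hg2(model, threshold = 0.5, x_hg2 = x2)
  expect_equal(calls$label, c("HG2-High", "HG2-Low", "HG2-High"))
  expect_equal(calls$label[calls$probability == 0.5], "HG2-High")
  calls0 <- reclassify_hg2(model, threshold = 0, x_hg2 = x2)
  expect_true(all(calls0$label == "HG2-High"))
  expect_error(reclassify_hg2(model, 0.5,
                              matrix(1, 1, 1, dimnames = list("a", "zz"))),
               "lacks")
})

test_that("mean-centring both datasets rescues a batch-shifted validation", {
  co <- simulate_cohort(simulation_config(n_samples = 240, n_genes = 200,
                                          frac_de = 0.15, lfc_scale = 2,
                                          frac_opposite = 0, seed = 19))
  sp <- split_two_datasets(co, c(0.5, 0.5), offset = 2, seed = 19)
  prep <- function(part) {
    x <- t(vst_like_transform(part$genes)$values)
    hg13 <- part$clinical$grade %in% c(1, 3)
    list(x = x[hg13, , drop = FALSE],
         y = as.integer(part$clinical$grade[hg13] == 3))
  }
  a <- prep(sp$A); b <- prep(sp$B)
  spec <- quick_spec()
  res <- cross_dataset_validate(a$x, a$y, b$x, b$y, spec,
                                inner_reps = 1, inner_folds = 5, seed = 3)
  expect_gt(res$auc, 0.9)
  expect_equal(res$n_shared, 200)
  ## the same transferred model scored without centring does no better
  model <- res$model
  p_raw <- predict(model, b$x)
  auc_raw <- roc_auc(p_raw, b$y)$auc
  expect_gte(res$auc + 1e-9, auc_raw)
  ## resubstitution bound: scoring the training cohort itself is optimistic
  res_self <- roc_auc(predict(model,
                              scale(a$x, center = TRUE, scale = FALSE)),
                      a$y)
  expect_gte(res_self$auc + 0.05, res$auc)
  expect_error(cross_dataset_validate(a$x[, 1, drop = FALSE], a$y,
                                      b$x[, 2, drop = FALSE], b$y, spec),
               "shared")
})
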