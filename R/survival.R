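#' Build recurrence-free-survival records
#'
#' Joins a clinical table with grade calls and prepares the covariates used
#' by the adjusted proportional-hazards model: age (continuous), tumour size
#' dichotomised at 20 mm, nodal status and ER status (binary), plus the
#' dataset label used for stratification. The composite endpoint convention
#' is that any death counts as an event (a death without documented relapse
#' is treated as undetected metastasis), so `event` must already encode the
#' composite indicator.
#'
#' @param clinical Data frame with sample_id, time_years, event, age,
#'   tumour_size_mm, node_positive, er_positive, dataset.
#' @param calls Optional [grade_calls()] data frame joined on sample_id; its
#'   `label` becomes the `group` column.
#' @param group Optional column name in `clinical` to use as the comparison
#'   group instead of `calls`.
#' @return Data frame of RFS records with a `group` factor.
#' @export
rfs_records <- function(clinical, calls = NULL, group = NULL) {
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop_tg("clinical table lacks: %s", paste(miss, collapse = ", "))
  if (any(clinical$time_years <= 0)) stop_tg("follow-up times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop_tg("event must be 0/1")
  rec <- clinical
  if (!is.null(calls)) {
    m <- match(rec$sample_id, calls$sample_id)
    rec$group <- calls$label[m]
    rec <- rec[!is.na(rec$group), , drop = FALSE]
  } else if (!is.null(group)) {
    rec$group <- rec[[group]]
  }
  if (!is.null(rec$tumour_size_mm))
    rec$size_ge20 <- as.integer(rec$tumour_size_mm >= 20)
  rec$group <- factor(rec$group)
  ## low-risk group is the reference when the labels are grade calls
  lv <- levels(rec$group)
  if (length(lv) == 2 && any(grepl("Low$", lv)) && any(grepl("High$", lv)))
    rec$group <- factor(rec$group, levels = c(lv[grepl("Low$", lv)],
                                              lv[grepl("High$", lv)]))
  rec
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the log-rank statistic
#' from observed-minus-expected event counts over the event times
#' (delegated to the survival package).
#'
#' @param records [rfs_records()] data frame with a `group` column.
#' @return List: `fit` (survfit object), `chisq`, `df`, `p`.
#' @export
km_and_logrank <- function(records) {
  if (length(unique(records$group)) < 2)
    stop_tg("need at least two groups")
  if (sum(records$event) < 1)
    stop_tg("no events observed; log-rank test undefined")
  fit <- survival::survfit(survival::Surv(time_years, event) ~ group,
                           data = records)
  lr <- survival::survdiff(survival::Surv(time_years, event) ~ group,
                           data = records)
  df <- length(lr$n) - 1
  list(fit = fit, chisq = lr$chisq, df = df,
       p = stats::pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' Proportional-hazards fit for a group comparison
#'
#' Cox partial-likelihood fit (Efron ties) of the group effect, unadjusted
#' or adjusted for age, tumour size (>= 20 mm), nodal status and ER status,
#' stratified by dataset (separate baseline hazards per dataset). Warns when
#' events are fewer than five per parameter.
#'
#' @param records [rfs_records()] data frame.
#' @param adjusted Include the clinical covariates.
#' @param stratify_dataset Stratify the baseline hazard by `dataset`.
#' @return List of class `tg_hazard`: `hr`, `ci` (95 %), `p_wald`,
#'   `logrank_p` (score test), `adjusted`, `fit`.
#' @export
cox_fit <- function(records, adjusted = FALSE, stratify_dataset = TRUE) {
  terms <- "group"
  if (adjusted) {
    need <- c("age", "size_ge20", "node_positive", "er_positive")
    miss <- setdiff(need, names(records))
    if (length(miss)) stop_tg("adjusted fit lacks covariates: %s",
                              paste(miss, collapse = ", "))
    terms <- c(terms, need)
  }
  if (stratify_dataset && !is.null(records$dataset) &&
      length(unique(records$dataset)) > 1)
    terms <- c(terms, "strata(dataset)")
  n_par <- 1L + if (adjusted) 4L else 0L
  if (sum(records$event) < 5 * n_par)
    warning(sprintf("only %d events for %d parameters (< 5 per parameter)",
                    sum(records$event), n_par))
  f <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = records, ties = "efron")
  s <- summary(fit)
  i <- grep("^group", rownames(s$coefficients))[1]
  if (is.na(i)) stop_tg("group coefficient not estimable")
  structure(list(hr = unname(s$coefficients[i, "exp(coef)"]),
                 ci = unname(c(s$conf.int[i, "lower .95"],
                               s$conf.int[i, "upper .95"])),
                 p_wald = unname(s$coefficients[i, "Pr(>|z|)"]),
                 logrank_p = unname(s$sctest["pvalue"]),
                 adjusted = adjusted, fit = fit),
            class = "tg_hazard")
}

#' @export
print.tg_hazard <- function(x, ...) {
  cat(sprintf("HR %s= %.2f (95%% CI %.2f-%.2f), Wald p = %.3g\n",
              if (x$adjusted) "(adjusted) " else "", x$hr, x$ci[1], x$ci[2],
              x$p_wald))
  invisible(x)
}
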