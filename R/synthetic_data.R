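#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of the generator. Defaults emulate the
#' structure of a breast-cancer RNA-seq cohort of 275 women with Nottingham
#' grade proportions of roughly 14/44/42 %, negative-binomial counts with a
#' common dispersion, grade-associated expression for a fraction of genes,
#' several isoforms per gene (some with opposite-direction effects), grade
#' subcomponent scores whose coupling to the molecular signal is strongest
#' for mitotic count and weakest for tubularity, and grade-dependent
#' recurrence hazards.
#'
#' @param n_samples Samples per cohort.
#' @param n_cohorts 1 or 2 (two cohorts are usually produced by
#'   [split_two_datasets()] on a single larger cohort).
#' @param grade_props Probabilities of histologic grade 1/2/3; must sum to 1.
#' @param n_genes Number of genes.
#' @param n_iso_per_gene Mean isoforms per gene (>= 1); per-gene counts are
#'   `1 + Poisson(n_iso_per_gene - 1)`.
#' @param frac_de Fraction of genes with a grade-associated effect.
#' @param lfc_scale Magnitude of the log2 fold change of grade-3 versus
#'   grade-1 tumours for grade-associated genes.
#' @param frac_opposite Fraction of grade-associated (multi-isoform) genes in
#'   which one isoform carries the opposite-sign effect.
#' @param dispersion Negative-binomial dispersion (1/size), common to all
#'   features.
#' @param lib_size_range Length-2 range of expected library sizes.
#' @param subcomponent_signal Relative molecular signal of the tubularity,
#'   nuclearity and mitotic-count subscores (T, N, M). Higher values couple
#'   the observed subscore more tightly to the latent grade dosage; the
#'   default (0.2, 0.4, 1.0) reproduces the mitotic > nuclearity > tubularity
#'   ordering of classification performance.
#' @param baseline_hazard Recurrence events per year for a grade-1 tumour.
#' @param hr_grade3_vs_1 True hazard ratio of grade 3 versus grade 1.
#' @param censor_rate Exponential censoring rate (events per year); 0 means
#'   no random censoring, `Inf` censors everything immediately.
#' @param follow_up_max Administrative censoring horizon in years.
#' @param iso_mode `"sum"`: gene counts are the sum of their isoforms'
#'   counts; `"independent"`: gene counts are drawn separately from a
#'   negative binomial with the summed mean.
#' @param seed Master seed; all randomness in the generator flows from it
#'   through counter-based substreams.
#' @return A validated list of class `tg_sim_config`.
#' @export
simulation_config <- function(n_samples = 275,
                              n_cohorts = 1,
                              grade_props = c(0.142, 0.440, 0.418),
                              n_genes = 1000,
                              n_iso_per_gene = 2,
                              frac_de = 0.10,
                              lfc_scale = 2,
                              frac_opposite = 0.10,
                              dispersion = 0.1,
                              lib_size_range = c(5e5, 1.5e6),
                              subcomponent_signal = c(T = 0.2, N = 0.4, M = 1.0),
                              baseline_hazard = 0.02,
                              hr_grade3_vs_1 = 2.62,
                              censor_rate = 0.18,
                              follow_up_max = 15,
                              iso_mode = c("sum", "independent"),
                              seed = 1L) {
  iso_mode <- match.arg(iso_mode)
  if (length(n_samples) != 1 || n_samples <= 0 || n_samples != round(n_samples))
    stop_tg("`n_samples` must be a positive integer")
  if (length(n_genes) != 1 || n_genes <= 0 || n_genes != round(n_genes))
    stop_tg("`n_genes` must be a positive integer")
  if (!n_cohorts %in% c(1, 2)) stop_tg("`n_cohorts` must be 1 or 2")
  if (length(grade_props) != 3 || any(grade_props < 0) ||
      abs(sum(grade_props) - 1) > 1e-9)
    stop_tg("`grade_props` must be 3 non-negative values summing to 1")
  assert_prob(frac_de, "frac_de")
  assert_prob(frac_opposite, "frac_opposite")
  if (dispersion <= 0) stop_tg("`dispersion` must be > 0")
  if (hr_grade3_vs_1 <= 0) stop_tg("`hr_grade3_vs_1` must be > 0")
  if (n_iso_per_gene < 1) stop_tg("`n_iso_per_gene` must be >= 1")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    stop_tg("`lib_size_range` must be an increasing positive pair")
  if (length(subcomponent_signal) != 3 || any(subcomponent_signal <= 0))
    stop_tg("`subcomponent_signal` must be 3 positive values (T, N, M)")
  if (baseline_hazard <= 0) stop_tg("`baseline_hazard` must be > 0")
  if (censor_rate < 0) stop_tg("`censor_rate` must be >= 0")
  structure(list(
    n_samples = as.integer(n_samples), n_cohorts = as.integer(n_cohorts),
    grade_props = as.numeric(grade_props), n_genes = as.integer(n_genes),
    n_iso_per_gene = n_iso_per_gene, frac_de = frac_de,
    lfc_scale = lfc_scale, frac_opposite = frac_opposite,
    dispersion = dispersion, lib_size_range = as.numeric(lib_size_range),
    subcomponent_signal = as.numeric(subcomponent_signal),
    baseline_hazard = baseline_hazard, hr_grade3_vs_1 = hr_grade3_vs_1,
    censor_rate = censor_rate, follow_up_max = follow_up_max,
    iso_mode = iso_mode, seed = as.integer(seed)),
    class = "tg_sim_config")
}

## latent grade dosage: HG1 = 0, HG2-low = 0.25, HG2-high = 0.75, HG3 = 1,
## so HG2 reclassification has a recoverable ground truth.
.dosage_for <- function(grade, hg2_subclass) {
  d <- ifelse(grade == 1, 0, ifelse(grade == 3, 1, NA_real_))
  hg2 <- grade == 2
  d[hg2] <- ifelse(hg2_subclass[hg2] == "high", 0.75, 0.25)
  d
}

## subscores 1..3: the latent dosage observed through component-specific
## noise; noise sd is inversely proportional to the component's signal, so
## weak-signal components are weak labels of the molecular state.
.draw_subscores <- function(dosage, signal, miss_prob = 0.015) {
  n <- length(dosage)
  out <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("score_T", "score_N", "score_M")))
  for (k in 1:3) {
    latent <- dosage + stats::rnorm(n, sd = 0.3 / signal[k])
    s <- 1L + (latent > 1 / 3) + (latent > 2 / 3)
    s[stats::runif(n) < miss_prob] <- NA_integer_
    out[, k] <- as.integer(s)
  }
  out
}

#' Simulate a grade-structured RNA-seq cohort
#'
#' Draws histologic grades from the configured proportions, assigns each
#' grade-2 tumour a latent low/high subclass, and generates negative-binomial
#' gene- and isoform-level counts in which grade-associated genes shift their
#' mean expression by `lfc_scale` log2 units between grade 1 and grade 3
#' (grade-2 tumours receive an intermediate dose). A fraction of
#' grade-associated genes carry one isoform with the opposite-sign effect.
#' Grade subcomponent scores, clinical covariates and recurrence-free
#' survival endpoints are generated alongside.
#'
#' @param config A [simulation_config()].
#' @return A list of class `tg_cohort` with elements `genes` and `isoforms`
#'   ([count_matrix()] objects), `clinical` (data frame: sample_id, grade,
#'   score_T/N/M, age, tumour_size_mm, node_positive, er_positive, dataset,
#'   time_years, event) and `truth` (generator ground truth: grade-associated
#'   gene IDs, opposite-direction gene IDs, per-feature true log2 effects,
#'   latent HG2 subclasses, latent dosage, expected gene means, uncensored
#'   event times).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tg_sim_config"))
  n <- config$n_samples
  G <- config$n_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(G))

  grade <- with_substream(config$seed, 1L,
    sample(1:3, n, replace = TRUE, prob = config$grade_props))
  hg2_subclass <- rep(NA_character_, n)
  hg2 <- grade == 2
  hg2_subclass[hg2] <- with_substream(config$seed, 2L,
    sample(c("low", "high"), sum(hg2), replace = TRUE))
  dosage <- .dosage_for(grade, hg2_subclass)

  ## gene baseline abundances (log-normal) and grade effects
  w <- with_substream(config$seed, 3L, exp(stats::rnorm(G, 0, 1.2)))
  n_de <- round(config$frac_de * G)
  de_idx <- with_substream(config$seed, 4L, sort(sample.int(G, n_de)))
  beta <- numeric(G)
  beta[de_idx] <- with_substream(config$seed, 5L,
    sample(c(-1, 1), n_de, replace = TRUE)) * config$lfc_scale

  ## isoform structure
  k_per_gene <- with_substream(config$seed, 6L,
    1L + stats::rpois(G, max(config$n_iso_per_gene - 1, 0)))
  iso_gene <- rep(seq_len(G), k_per_gene)
  n_iso <- length(iso_gene)
  iso_ids <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s.I%02d", gene_ids[g], seq_len(k_per_gene[g]))), use.names = FALSE)
  iso_prop <- with_substream(config$seed, 7L, {
    a <- stats::rgamma(n_iso, shape = 2)
    unlist(lapply(split(a, iso_gene), function(x) x / sum(x)), use.names = FALSE)
  })
  iso_beta <- beta[iso_gene]
  multi_de <- intersect(de_idx, which(k_per_gene >= 2))
  n_opp <- round(config$frac_opposite * length(intersect(de_idx, seq_len(G))))
  n_opp <- min(n_opp, length(multi_de))
  opp_idx <- with_substream(config$seed, 8L,
    sort(sample(multi_de, n_opp)))
  for (g in opp_idx) {
    rows <- which(iso_gene == g)
    minor <- rows[which.min(iso_prop[rows])]  # flip the minor isoform so the
    iso_beta[minor] <- -beta[g]               # gene stays net grade-associated
  }

  lib_size <- with_substream(config$seed, 9L,
    stats::runif(n, config$lib_size_range[1], config$lib_size_range[2]))

  ## expected isoform means: library x baseline share x isoform share x effect
  iso_w <- w[iso_gene] * iso_prop
  fold <- outer(iso_beta, dosage, function(b, d) 2^(b * d))
  iso_mean <- (iso_w / sum(w)) * fold
  iso_mean <- sweep(iso_mean, 2, lib_size, `*`)

  size <- 1 / config$dispersion
  iso_counts <- with_substream(config$seed, 10L,
    matrix(stats::rnbinom(n_iso * n, mu = iso_mean, size = size), n_iso, n))
  dimnames(iso_counts) <- list(iso_ids, sample_ids)

  gene_mean <- rowsum(iso_mean, iso_gene, reorder = TRUE)
  rownames(gene_mean) <- gene_ids
  if (config$iso_mode == "sum") {
    gene_counts <- rowsum(iso_counts, iso_gene, reorder = TRUE)
  } else {
    gene_counts <- with_substream(config$seed, 11L,
      matrix(stats::rnbinom(G * n, mu = gene_mean, size = size), G, n))
  }
  dimnames(gene_counts) <- list(gene_ids, sample_ids)

  subsc <- with_substream(config$seed, 12L,
    .draw_subscores(dosage, config$subcomponent_signal))

  covars <- with_substream(config$seed, 13L, {
    age <- pmin(pmax(round(stats::rnorm(n, 60, 11)), 28), 94)
    size_mm <- round(exp(stats::rnorm(n, log(18) + 0.25 * dosage, 0.45)))
    node <- stats::rbinom(n, 1, 0.10 + 0.15 * dosage)
    er <- stats::rbinom(n, 1, 0.92 - 0.20 * dosage)
    data.frame(age = age, tumour_size_mm = size_mm,
               node_positive = node, er_positive = er)
  })

  clinical <- data.frame(sample_id = sample_ids, grade = grade,
                         subsc, covars, dataset = "cohort1",
                         stringsAsFactors = FALSE)

  truth <- list(
    de_gene_ids = gene_ids[de_idx],
    opposite_gene_ids = gene_ids[opp_idx],
    gene_log2_effect = stats::setNames(beta, gene_ids),
    iso_log2_effect = stats::setNames(iso_beta, iso_ids),
    iso_gene = stats::setNames(gene_ids[iso_gene], iso_ids),
    hg2_subclass = stats::setNames(hg2_subclass, sample_ids),
    dosage = stats::setNames(dosage, sample_ids),
    baseline_weight = stats::setNames(w, gene_ids),
    lib_size = stats::setNames(lib_size, sample_ids),
    expected_gene_mean = gene_mean)

  cohort <- list(
    genes = count_matrix(gene_counts, level = "gene"),
    isoforms = count_matrix(iso_counts, level = "isoform",
                            iso2gene = truth$iso_gene),
    clinical = clinical,
    truth = truth,
    config = config)
  class(cohort) <- "tg_cohort"
  cohort$clinical <- simulate_survival(cohort$clinical, config,
                                       dosage = dosage)
  surv_t <- attr(cohort$clinical, "event_time_uncensored")
  truth$event_time_uncensored <- stats::setNames(surv_t, sample_ids)
  cohort$truth <- truth
  cohort
}

#' @export
print.tg_cohort <- function(x, ...) {
  cat(sprintf("tg_cohort: %d samples, %d genes, %d isoforms (grades %s)\n",
              nrow(x$clinical), nrow(x$genes$values), nrow(x$isoforms$values),
              paste(table(x$clinical$grade), collapse = "/")))
  invisible(x)
}

#' Attach recurrence-free survival endpoints to a clinical table
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hr_grade3_vs_1^dose`, where the dose is the latent grade dosage when
#' supplied and otherwise 0/0.5/1 for grade 1/2/3. The composite endpoint
#' follows the recurrence-free-survival convention: any relapse, metastasis,
#' contralateral tumour or death counts as an event, so the observed time is
#' the minimum of the event draw, an exponential censoring draw and the
#' administrative follow-up horizon.
#'
#' @param clinical Data frame with a `grade` column.
#' @param config A [simulation_config()].
#' @param dosage Optional latent dosage vector overriding the grade mapping.
#' @return `clinical` with `time_years` and `event` columns added; the
#'   uncensored event times are carried in attribute `event_time_uncensored`.
#' @export
simulate_survival <- function(clinical, config, dosage = NULL) {
  stopifnot(inherits(config, "tg_sim_config"))
  if (is.null(clinical$grade) || any(is.na(clinical$grade)))
    stop_tg("`clinical` must carry a complete `grade` column")
  n <- nrow(clinical)
  if (is.null(dosage)) dosage <- c(0, 0.5, 1)[clinical$grade]
  haz <- config$baseline_hazard * config$hr_grade3_vs_1^dosage
  drawn <- with_substream(config$seed, 20L, {
    t_event <- stats::rexp(n, rate = haz)
    t_cens <- if (config$censor_rate == 0) rep(Inf, n) else
      if (is.infinite(config$censor_rate)) rep(1e-9, n) else
        stats::rexp(n, rate = config$censor_rate)
    list(t_event = t_event, t_cens = t_cens)
  })
  t_lim <- pmin(drawn$t_cens, config$follow_up_max)
  clinical$time_years <- pmin(drawn$t_event, t_lim)
  clinical$event <- as.integer(drawn$t_event <= t_lim)
  attr(clinical, "event_time_uncensored") <- drawn$t_event
  clinical
}

#' Split one cohort into two pseudo-datasets
#'
#' Partitions samples into disjoint datasets of sizes given by the
#' nearest-integer rule on `fractions`, relabels the `dataset` column, and
#' optionally adds a global log2 expression offset to the second dataset to
#' emulate a batch difference between cohorts profiled separately.
#'
#' @param cohort A `tg_cohort` from [simulate_cohort()].
#' @param fractions Length-2 positive fractions summing to 1.
#' @param offset Log2 offset added to every feature of dataset B (counts are
#'   scaled by `2^offset` and rounded).
#' @param labels Dataset labels, default `c("A", "B")`.
#' @param seed Seed for the random assignment (defaults to the cohort's).
#' @return A list with `tg_cohort`-like elements `A` and `B`.
#' @export
split_two_datasets <- function(cohort, fractions, offset = 0,
                               labels = c("A", "B"), seed = NULL) {
  stopifnot(inherits(cohort, "tg_cohort"))
  if (length(fractions) != 2 || any(fractions <= 0) || any(fractions >= 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_tg("`fractions` must be two values in (0,1) summing to 1")
  n <- nrow(cohort$clinical)
  n_a <- round(fractions[1] * n)
  seed <- seed %||% cohort$config$seed
  idx_a <- with_substream(seed, 30L, sort(sample.int(n, n_a)))
  idx_b <- setdiff(seq_len(n), idx_a)

  take <- function(idx, label, off) {
    g <- cohort$genes$values[, idx, drop = FALSE]
    i <- cohort$isoforms$values[, idx, drop = FALSE]
    if (off != 0) {
      g <- round(g * 2^off)
      i <- round(i * 2^off)
    }
    cl <- cohort$clinical[idx, , drop = FALSE]
    cl$dataset <- label
    out <- list(genes = count_matrix(g, level = "gene"),
                isoforms = count_matrix(i, level = "isoform",
                                        iso2gene = cohort$isoforms$iso2gene),
                clinical = cl,
                truth = cohort$truth, config = cohort$config)
    class(out) <- "tg_cohort"
    out
  }
  list(A = take(idx_a, labels[1], 0), B = take(idx_b, labels[2], offset))
}
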