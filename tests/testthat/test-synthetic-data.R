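test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulation_config(n_genes = -5), "n_genes")
  expect_error(simulation_config(grade_props = c(0.5, 0.5, 0.5)), "grade_props")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(hr_grade3_vs_1 = -1), "hr_grade3")
  expect_error(simulation_config(frac_de = 1.2), "frac_de")
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- simulation_config(n_samples = 60, n_genes = 80, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genes$values, b$genes$values)
  expect_identical(a$isoforms$values, b$isoforms$values)
  expect_identical(a$clinical, b$clinical)
  c2 <- simulate_cohort(simulation_config(n_samples = 60, n_genes = 80,
                                          seed = 43))
  expect_false(identical(a$genes$values, c2$genes$values))
})

test_that("gene counts equal the sum of isoform counts in sum mode", {
  co <- simulate_cohort(simulation_config(n_samples = 30, n_genes = 50,
                                          n_iso_per_gene = 3, seed = 5))
  by_gene <- rowsum(co$isoforms$values,
                    co$truth$iso_gene[rownames(co$isoforms$values)])
  expect_equal(unname(by_gene[rownames(co$genes$values), ]),
               unname(co$genes$values))
})

test_that("grade frequencies stay within binomial 99 % bounds", {
  props <- c(0.14, 0.44, 0.42)
  co <- simulate_cohort(simulation_config(n_samples = 275, n_genes = 20,
                                          grade_props = props, seed = 9))
  tab <- tabulate(co$clinical$grade, 3)
  for (k in 1:3) {
    bounds <- qbinom(c(0.005, 0.995), 275, props[k])
    expect_gte(tab[k], bounds[1])
    expect_lte(tab[k], bounds[2])
  }
  ## expected grade-2 count at the reference cohort composition
  expect_equal(275 * 0.44, 121, tolerance = 1e-9)
})

test_that("count marginals match the negative-binomial means", {
  ## standardised residuals of counts against the generator's own means
  ## average to zero across seeds
  zs <- vapply(1:50, function(s) {
    co <- simulate_cohort(simulation_config(n_samples = 30, n_genes = 60,
                                            frac_de = 0.1, seed = s))
    mu <- co$truth$expected_gene_mean
    v <- mu + 0.1 * mu^2
    mean((co$genes$values - mu) / sqrt(pmax(v, 1e-9)))
  }, 0)
  n_cells <- 50 * 30 * 60
  expect_lt(abs(mean(zs)), 3 / sqrt(n_cells))
})

test_that("grade-associated genes carry the configured log2 effect", {
  diffs <- vapply(1:20, function(s) {
    co <- simulate_cohort(simulation_config(
      n_samples = 200, n_genes = 300, frac_de = 0.1, lfc_scale = 2,
      frac_opposite = 0, dispersion = 0.1,
      lib_size_range = c(2e6, 4e6), seed = s))
    lc <- log2(cpm(co$genes) + 1)
    de <- co$truth$de_gene_ids
    d <- rowMeans(lc[de, co$clinical$grade == 3, drop = FALSE]) -
      rowMeans(lc[de, co$clinical$grade == 1, drop = FALSE])
    mean(d * sign(co$truth$gene_log2_effect[de]))
  }, 0)
  expect_lt(abs(mean(diffs) - 2), 0.2)
})

test_that("every grade-2 sample has a latent subclass and others do not", {
  co <- simulate_cohort(simulation_config(n_samples = 120, n_genes = 40,
                                          seed = 2))
  sub <- co$truth$hg2_subclass
  expect_true(all(!is.na(sub[co$clinical$grade == 2])))
  expect_true(all(is.na(sub[co$clinical$grade != 2])))
  expect_true(all(co$truth$opposite_gene_ids %in% co$truth$de_gene_ids))
})

test_that("survival generation respects the hazard structure", {
  ## null hazard ratio: log-rank p has no systematic signal
  ps <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_samples = 150, n_genes = 10,
                             hr_grade3_vs_1 = 1, baseline_hazard = 0.2,
                             censor_rate = 0.05, seed = s)
    co <- simulate_cohort(cfg)
    rec <- rfs_records(co$clinical[co$clinical$grade %in% c(1, 3), ],
                       group = "grade")
    km_and_logrank(rec)$p
  }, 0)
  expect_gt(mean(ps), 0.2)  # uniform p-values average 0.5
  expect_gt(min(ps), 0.001)

  ## degenerate censoring: no events, log-rank refuses
  cfg <- simulation_config(n_samples = 50, n_genes = 10,
                           censor_rate = Inf, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$clinical$event), 0)
  rec <- rfs_records(co$clinical, group = "grade")
  expect_error(km_and_logrank(rec), "no events")

  ## missing grade errors
  bad <- co$clinical; bad$grade[1] <- NA
  expect_error(simulate_survival(bad, cfg), "grade")
})

test_that("split_two_datasets partitions by the nearest-integer rule", {
  co <- simulate_cohort(simulation_config(n_samples = 762, n_genes = 30,
                                          seed = 7))
  sp <- split_two_datasets(co, c(0.36, 0.64))
  expect_equal(nrow(sp$A$clinical), 274)
  expect_equal(nrow(sp$B$clinical), 488)
  expect_length(intersect(sp$A$clinical$sample_id, sp$B$clinical$sample_id), 0)
  expect_setequal(c(sp$A$clinical$sample_id, sp$B$clinical$sample_id),
                  co$clinical$sample_id)

  ## offset 0: concatenation equals the original up to column order
  both <- cbind(sp$A$genes$values, sp$B$genes$values)
  expect_equal(both[, colnames(co$genes$values)], co$genes$values)

  ## a log2 offset on B shifts per-gene mean log-expression by about that much
  sp2 <- split_two_datasets(co, c(0.5, 0.5), offset = 1)
  la <- rowMeans(log2(cpm(sp2$A$genes) + 1))
  ## CPM normalisation absorbs a global offset, so check raw log counts
  la <- rowMeans(log2(sp2$A$genes$values + 1))
  lb <- rowMeans(log2(sp2$B$genes$values + 1))
  expect_lt(abs(mean(lb - la) - 1), 0.15)

  expect_error(split_two_datasets(co, c(0.7, 0.2)), "fractions")
})
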