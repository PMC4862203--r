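test_that("precision weights are positive and CPM-invariant", {
  set.seed(10)
  v <- matrix(rnbinom(200 * 12, mu = 100, size = 2), 200, 12,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  g <- rep(c("a", "b"), each = 6)
  vw <- voom_weights(v, g)
  expect_true(all(vw$weights > 0))
  ## doubling all counts leaves log-CPM essentially unchanged
  vw2 <- voom_weights(v * 2L, g)
  expect_equal(vw2$logcpm, vw$logcpm, tolerance = 0.01)
  ## near-constant-variance data gets a nearly flat trend
  vg <- matrix(round(rnorm(300 * 12, 5000, 40)), 300, 12,
               dimnames = list(paste0("g", 1:300), paste0("s", 1:12)))
  vwg <- voom_weights(vg, g)
  expect_lt(max(vwg$weights) / min(vwg$weights), 2)
  ## too few features: unit weights with a warning
  expect_warning(voom_weights(v[1:5, ], g), "unit weights")
})

test_that("weights track limma's voom on the same data", {
  set.seed(40)
  v <- matrix(rnbinom(400 * 16, mu = 80, size = 1), 400, 16,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:16)))
  g <- rep(c("a", "b"), each = 8)
  vw <- voom_weights(v, g)
  ref <- limma::voom(v, model.matrix(~factor(g)))
  expect_gt(cor(as.vector(vw$weights), as.vector(ref$weights)), 0.9)
})

test_that("moderated t reduces to the ordinary t without a prior", {
  set.seed(13)
  y <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(paste0("g", 1:50), NULL))
  g <- rep(c("a", "b"), each = 5)
  de0 <- moderated_t(y, NULL, g, prior = "none")
  tt <- apply(y, 1, function(r)
    t.test(r[6:10], r[1:5], var.equal = TRUE)$statistic)
  expect_equal(de0$t, unname(tt), tolerance = 1e-9)
  expect_equal(attr(de0, "d0"), 0)
  ## with moderation, agreement with limma's empirical Bayes is exact
  fit <- limma::eBayes(limma::lmFit(y, model.matrix(~factor(g))))
  dem <- moderated_t(y, NULL, g)
  expect_equal(dem$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(attr(dem, "d0"), fit$df.prior, tolerance = 1e-4)
  ## monotonicity: a larger effect at equal variance gives a larger |t|
  y2 <- y
  y2[1, 6:10] <- y2[1, 6:10] + 1
  y2[2, 6:10] <- y2[2, 6:10] + 3
  de2 <- moderated_t(y2, NULL, g, prior = "none")
  expect_gt(abs(de2$t[2] - de0$t[2]), abs(de2$t[1] - de0$t[1]) - 1e-9)
  expect_error(moderated_t(y[, 1:2], NULL, c("a", "b")), "at least 2")
})

test_that("planted effects are detected with FDR control", {
  found <- fp <- numeric(0)
  for (s in 1:3) {
    set.seed(600 + s)
    ## planted |lfc| = 2 in both directions (as grade signatures are),
    ## keeping library composition balanced
    mu <- matrix(100, 400, 30)
    mu[1:13, 16:30] <- 400
    mu[14:25, 16:30] <- 25
    v <- matrix(rnbinom(length(mu), mu = mu, size = 10), 400, 30,
                dimnames = list(paste0("g", 1:400), paste0("s", 1:30)))
    g <- rep(c("a", "b"), each = 15)
    vw <- voom_weights(v, g)
    de <- moderated_t(vw$logcpm, vw$weights, g)
    sig <- de$feature_id[de$fdr < 0.05]
    found <- c(found, mean(paste0("g", 1:25) %in% sig))
    fp <- c(fp, sum(!sig %in% paste0("g", 1:25)) / max(length(sig), 1))
  }
  expect_gte(mean(found), 0.9)
  expect_lte(mean(fp), 0.05)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  ## permutation invariance
  p <- c(0.4, 0.001, 0.2, 0.03, 0.9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("opposite-direction genes need one significant isoform each way", {
  de <- data.frame(feature_id = c("i1", "i2", "i3", "i4", "i5"),
                   log2fc = c(2, -2, 1, 2, -1),
                   t = 1, df = 5,
                   p = c(0.001, 0.001, 0.001, 0.001, 0.5),
                   fdr = c(0.01, 0.01, 0.01, 0.01, 0.6),
                   direction = c("up", "down", "up", "up", "down"))
  map <- c(i1 = "gA", i2 = "gA", i3 = "gB", i4 = "gB", i5 = "gC")
  expect_equal(opposite_direction_genes(de, map), "gA")   # gB: both up
  ## gC's down isoform is not significant
  map2 <- c(map, i6 = "gC")
  expect_message(
    opposite_direction_genes(rbind(de, data.frame(
      feature_id = "i9", log2fc = 1, t = 1, df = 5, p = 0.001, fdr = 0.01,
      direction = "up")), map),
    "unmapped")
})

test_that("opposite-direction truth is recovered from a simulated cohort", {
  co <- simulate_cohort(simulation_config(
    n_samples = 100, n_genes = 250, n_iso_per_gene = 3, frac_de = 0.3,
    frac_opposite = 0.2, lfc_scale = 2, dispersion = 0.05,
    lib_size_range = c(2e6, 4e6), seed = 55))
  hg13 <- co$clinical$grade %in% c(1, 3)
  g <- factor(co$clinical$grade[hg13], levels = c(1, 3))
  iso <- suppressMessages(filter_by_cpm(subset_iso <- co$isoforms))
  vw <- voom_weights(iso$values[, hg13, drop = FALSE], g)
  de <- moderated_t(vw$logcpm, vw$weights, g)
  rec <- opposite_direction_genes(de, co$truth$iso_gene)
  truth <- co$truth$opposite_gene_ids
  jac <- length(intersect(rec, truth)) / length(union(rec, truth))
  expect_gte(jac, 0.7)
})

test_that("gene/isoform overlap counts match manual Venn algebra", {
  gde <- data.frame(feature_id = c("gA", "gB", "gC"), fdr = c(0.01, 0.2, 0.01))
  ide <- data.frame(feature_id = paste0("i", 1:6),
                    fdr = c(0.01, 0.01, 0.5, 0.01, 0.6, 0.01))
  map <- c(i1 = "gA", i2 = "gA", i3 = "gB", i4 = "gB", i5 = "gC", i6 = "gD")
  ov <- de_overlap_summary(gde, ide, map)
  ## significant isoforms i1,i2 (gA), i4 (gB), i6 (gD); sig genes gA, gC
  expect_equal(ov$n_iso_sig, 4)
  expect_equal(ov$n_iso_genes, 3)
  expect_equal(ov$genes_both_levels, 1)      # gA
  expect_equal(ov$isoform_only_genes, 2)     # gB, gD
  expect_equal(ov$isoform_only_isoforms, 2)  # i4, i6
  ## identical 1:1 mapped sets leave nothing isoform-only
  ov2 <- de_overlap_summary(
    data.frame(feature_id = "gA", fdr = 0.01),
    data.frame(feature_id = "i1", fdr = 0.01), c(i1 = "gA"))
  expect_equal(ov2$isoform_only_genes, 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  uni <- paste0("g", 1:20)
  ora <- hypergeom_ora(paste0("g", 1:5), uni,
                       list(hit = paste0("g", c(1, 2, 3, 10, 11)),
                        all = uni,
                        none = paste0("g", 15:19)))
  expect_equal(ora$p_hypergeom[ora$set_id == "hit"], 1126 / 15504)
  expect_equal(ora$p_hypergeom[ora$set_id == "all"], 1)    # certainty
  expect_equal(ora$p_hypergeom[ora$set_id == "none"], 1)   # P(X >= 0) = 1
  ## enumeration oracle over random configurations with N <= 25
  set.seed(3)
  for (i in 1:15) {
    N <- sample(5:25, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample.int(N, 1); n <- sample.int(N, 1)
    set <- sample(uni, K); de <- sample(uni, n)
    ov <- length(intersect(set, de))
    enum <- sum(vapply(ov:min(K, n), function(k)
      choose(K, k) * choose(N - K, n - k), 0)) / choose(N, n)
    got <- hypergeom_ora(de, uni, list(s = set))$p_hypergeom
    expect_equal(got, enum, tolerance = 1e-12)
  }
  expect_error(hypergeom_ora("g1", character(0), list(a = "g1")), "universe")
})

test_that("GMT files parse into named gene sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tcell cycle\tg1\tg2\tg3",
               "setB\tdna repair\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g2", "g4"))
  writeLines("broken\tonly-two-fields", f)
  expect_error(read_gmt(f), "malformed")
})
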