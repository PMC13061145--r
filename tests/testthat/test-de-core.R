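test_that("protein-coding filter intersects in original order", {
  m <- count_matrix(matrix(1:20, 10, 2),
                    paste0("g", 1:10), c("s1", "s2"))
  expect_identical(filter_protein_coding(m, rownames(m)), m)
  expect_error(filter_protein_coding(m, c("x", "y")), "no genes")
  sub <- filter_protein_coding(m, c("g7", "g2", "g9", "g4"))
  expect_equal(rownames(sub), c("g2", "g4", "g7", "g9"))
})

test_that("size factors match the median-of-ratios hand computation", {
  m <- count_matrix(rbind(c(10, 20), c(100, 200)),
                    c("g1", "g2"), c("s1", "s2"))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  # identical columns give unit factors
  m2 <- count_matrix(matrix(rep(c(5, 50, 500), 3), 3, 3),
                     paste0("g", 1:3), paste0("s", 1:3))
  expect_equal(unname(size_factors(m2)), rep(1, 3))
  # scaling one column by c scales its factor by c relative to the rest
  # (the geometric-mean reference rescales all factors by c^(1/n))
  set.seed(4)
  m3 <- count_matrix(matrix(rpois(60, 50), 10, 6),
                     paste0("g", 1:10), paste0("s", 1:6))
  sf <- size_factors(m3)
  m3b <- m3; m3b[, 3] <- m3b[, 3] * 4
  sf2 <- size_factors(m3b)
  expect_equal(sf2[3] / sf2[-3], 4 * sf[3] / sf[-3], tolerance = 1e-12)
  expect_equal(unname(sf2), unname(sf * c(1, 1, 4, 1, 1, 1) * 4^(-1 / 6)),
               tolerance = 1e-12)
  # invariance to gene (row) permutation
  perm <- sample(nrow(m3))
  expect_equal(size_factors(m3[perm, ]), size_factors(m3))
  expect_error(size_factors(count_matrix(rbind(c(0, 1), c(1, 0)),
                                         c("a", "b"), c("s1", "s2"))),
               "positive")
})

test_that("method-of-moments dispersion recovers alpha and floors
          degenerate genes", {
  set.seed(6)
  n <- 500
  # NB genes at alpha = 0.5
  y_nb <- t(replicate(40, rnbinom(n, mu = 100, size = 2)))
  m <- count_matrix(y_nb, paste0("g", 1:40), paste0("s", 1:n))
  a <- estimate_dispersion(m, sf = setNames(rep(1, n), colnames(m)))
  expect_lt(abs(mean(a) - 0.5), 0.15)
  # Poisson genes have no overdispersion
  y_p <- t(replicate(40, rpois(n, 100)))
  mp <- count_matrix(y_p, paste0("g", 1:40), paste0("s", 1:n))
  ap <- estimate_dispersion(mp, sf = setNames(rep(1, n), colnames(mp)))
  expect_lt(median(ap), 0.01)
  # constant (zero-variance) and all-zero genes floor with a flag
  mz <- count_matrix(rbind(c(0, 0, 0), c(7, 7, 7), c(1, 5, 9)),
                     c("zero", "const", "ok"), paste0("s", 1:3))
  az <- estimate_dispersion(mz, sf = setNames(rep(1, 3), colnames(mz)))
  expect_equal(unname(az["zero"]), 1e-8)
  expect_true("zero" %in% attr(az, "flagged"))
})

test_that("group-aware dispersion is not inflated by a real mean shift", {
  set.seed(16)
  n <- 200
  grp <- rep(c("LA", "HA"), each = n / 2)
  y <- t(replicate(40, rnbinom(n, mu = ifelse(grp == "HA", 200, 100),
                               size = 10)))
  m <- count_matrix(y, paste0("g", 1:40), paste0("s", 1:n))
  sf <- setNames(rep(1, n), colnames(m))
  a_pooled <- estimate_dispersion(m, sf)
  a_grouped <- estimate_dispersion(m, sf, groups = grp)
  expect_lt(abs(mean(a_grouped) - 0.1), 0.05)
  expect_gt(mean(a_pooled), mean(a_grouped))
})

test_that("NB Wald log2FC equals the closed-form mean ratio on
          deterministic counts", {
  md <- toy_metadata(6, "LE")
  Y <- toy_counts(md, means_la = c(100, 50, 400),
                  means_ha = c(200, 50, 100))
  res <- nb_wald_de(Y, md, "LE",
                    sf = setNames(rep(1, nrow(md)), md$sample_id),
                    alpha = rep(1e-8, 3))
  expect_equal(res$log2fc, c(1, 0, -2), tolerance = 1e-6)
  expect_equal(sign(res$wald_stat), sign(res$log2fc))
  expect_true(all(res$converged))
})

test_that("relabeling LA and HA negates log2FC and preserves p-values", {
  cfg <- small_config(seed = 9L)
  sim <- simulate_counts(cfg)
  md <- sim$metadata
  res1 <- nb_wald_de(sim$counts, md, "LE")
  md2 <- md
  md2$adiposity_class <- chartr("LH", "HL",
                                sub("A$", "", md$adiposity_class))
  md2$adiposity_class <- paste0(md2$adiposity_class, "A")
  res2 <- nb_wald_de(sim$counts, md2, "LE")
  expect_equal(res2$log2fc, -res1$log2fc, tolerance = 1e-6)
  expect_equal(res2$p_value, res1$p_value, tolerance = 1e-6)
})

test_that("results are invariant to sample order", {
  cfg <- small_config(seed = 10L)
  sim <- simulate_counts(cfg)
  res1 <- nb_wald_de(sim$counts, sim$metadata, "OB")
  set.seed(1)
  perm <- sample(ncol(sim$counts))
  res2 <- nb_wald_de(sim$counts[, perm], sim$metadata, "OB")
  expect_equal(res1, res2, tolerance = 1e-9)
})

test_that("in the small-dispersion limit the NB Wald test agrees with a
          Poisson GLM", {
  set.seed(12)
  md <- toy_metadata(10, "LE")
  n <- nrow(md)
  Y <- count_matrix(
    t(replicate(20, rpois(n, ifelse(md$adiposity_class == "HA", 130, 100)))),
    sprintf("g%02d", 1:20), md$sample_id)
  sf <- setNames(rep(1, n), md$sample_id)
  res <- nb_wald_de(Y, md, "LE", sf = sf, alpha = rep(1e-8, 20))
  x <- as.numeric(md$adiposity_class == "HA")
  s <- as.numeric(md$sex == "M")
  p_pois <- vapply(seq_len(20), function(g) {
    fit <- summary(glm(Y[g, ] ~ x + s, family = poisson()))
    fit$coefficients["x", "Pr(>|z|)"]
  }, numeric(1))
  expect_true(all(abs(res$p_value - p_pois) / p_pois < 0.1))
})

test_that("null designs give near-zero effects at large n", {
  cfg <- simulation_config(n_per_group = c(60, 60, 60, 60), n_genes = 120L,
                           n_shared_concordant = 0L,
                           n_shared_discordant = 0L,
                           n_le_unique = 0L, n_ob_unique = 0L,
                           seed = 18L)
  sim <- simulate_counts(cfg)
  res <- nb_wald_de(sim$counts, sim$metadata, "LE")
  expect_lt(median(abs(res$log2fc)), 0.1)
})

test_that("planted effects are recovered with power at the study size", {
  cfg <- simulation_config(n_per_group = c(20, 20, 20, 20), n_genes = 150L,
                           n_shared_concordant = 0L,
                           n_shared_discordant = 0L,
                           n_le_unique = 30L, n_ob_unique = 0L,
                           effect_log2fc = 2.0, seed = 19L)
  sim <- simulate_counts(cfg)
  res <- nb_wald_de(sim$counts, sim$metadata, "LE")
  idx <- sim$truth$lfc_le != 0
  expect_true(mean(abs(res$log2fc[idx] - sim$truth$lfc_le[idx]) < 0.4) >= 0.9)
  expect_true(mean(res$p_value[idx] < 0.05) >= 0.9)
})

test_that("single-level sex drops the covariate with a warning", {
  md <- toy_metadata(4, "LE")
  md$sex <- "F"
  Y <- toy_counts(md, rep(100, 3), rep(150, 3))
  expect_warning(res <- nb_wald_de(Y, md, "LE",
                                   sf = setNames(rep(1, 8), md$sample_id),
                                   alpha = rep(0.01, 3)),
                 "sex")
  expect_true(all(is.finite(res$log2fc)))
})

test_that("PCA outlier screen flags planted outliers and nothing in
          homogeneous data", {
  flags <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_per_group = c(8, 8, 8, 8), n_genes = 300L,
                             n_shared_concordant = 0L,
                             n_shared_discordant = 0L, n_le_unique = 0L,
                             n_ob_unique = 0L, seed = 100L + s)
    length(pca_outliers(simulate_counts(cfg)$counts, k = 5, n_top = 200))
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.9)
  # composition outlier: a third of genes perturbed strongly in one sample
  cfg <- simulation_config(n_per_group = c(8, 8, 8, 8), n_genes = 300L,
                           n_shared_concordant = 0L, n_shared_discordant = 0L,
                           n_le_unique = 0L, n_ob_unique = 0L, seed = 23L)
  counts <- simulate_counts(cfg)$counts
  bad <- colnames(counts)[5]
  counts[1:100, bad] <- counts[1:100, bad] * 20
  expect_true(bad %in% pca_outliers(counts, k = 5, n_top = 200))
  # infinite threshold flags nothing
  expect_length(pca_outliers(counts, k = Inf, n_top = 200), 0)
  expect_warning(pca_outliers(counts, n_top = 1e6), "clamp")
})

test_that("size factors and fold changes agree with an independent
          DESeq2 reference on simulated data", {
  skip_if_not_installed("DESeq2")
  cfg <- small_config(seed = 33L)
  sim <- simulate_counts(cfg)
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(size_factors(sim$counts)), unname(sf_ref),
               tolerance = 1e-6)
  md <- sim$metadata[sim$metadata$maternal_group == "LE" &
                       sim$metadata$adiposity_class %in% c("LA", "HA"), ]
  cts <- sim$counts[, md$sample_id]
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cts, data.frame(adip = factor(md$adiposity_class,
                                    levels = c("LA", "HA")),
                      sex = factor(md$sex)),
      design = ~ sex + adip)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  ours <- nb_wald_de(sim$counts, sim$metadata, "LE")
  expect_gt(cor(ours$log2fc, ref$log2FoldChange), 0.95)
})
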