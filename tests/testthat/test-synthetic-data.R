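test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_config(seed = 42L)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_anthropometrics(cfg),
                   simulate_anthropometrics(cfg))
  expect_identical(simulate_annotation(cfg, s1$truth),
                   simulate_annotation(cfg, s1$truth))
  expect_identical(simulate_network(cfg, s1$truth),
                   simulate_network(cfg, s1$truth))
  expect_identical(simulate_reference(cfg, s1$truth),
                   simulate_reference(cfg, s1$truth))
  g <- s1$truth$gene_id[1]
  expect_identical(simulate_qpcr(cfg, s1$counts, g),
                   simulate_qpcr(cfg, s1$counts, g))
})

test_that("default design reproduces the cohort group sizes 20/19/20/20", {
  cfg <- simulation_config(n_genes = 30L, n_shared_concordant = 2L,
                           n_shared_discordant = 2L, n_le_unique = 2L,
                           n_ob_unique = 2L, seed = 3L)
  md <- simulate_anthropometrics(cfg)
  tab <- table(md$study_group)
  expect_equal(unname(tab[c("LELA", "LEHA", "OBLA", "OBHA")]),
               c(20L, 19L, 20L, 20L), ignore_attr = TRUE)
  sim <- simulate_counts(cfg, md)
  expect_equal(ncol(sim$counts), 79L)
})

test_that("no planted effects gives an all-null truth", {
  cfg <- simulation_config(n_per_group = c(5, 5, 5, 5), n_genes = 40L,
                           n_shared_concordant = 0L,
                           n_shared_discordant = 0L,
                           n_le_unique = 0L, n_ob_unique = 0L, seed = 1L)
  tr <- simulate_counts(cfg)$truth
  expect_true(all(tr$class == "null"))
  expect_true(all(tr$lfc_le == 0) && all(tr$lfc_ob == 0))
})

test_that("config validation rejects inconsistent plans", {
  expect_error(simulation_config(n_genes = 10L, n_shared_concordant = 10L),
               "planted-class")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(depth_range = c(2, 1)), "depth_range")
  expect_error(simulation_config(designated_fraction = 0),
               "designated_fraction")
})

test_that("near-Poisson counts concentrate on the baseline mean", {
  # dispersion ~ 0, unit depth, constant baseline 100, 200 samples:
  # each per-gene sample mean should sit within 3 standard errors of 100
  cfg <- simulation_config(n_per_group = c(50, 50, 50, 50), n_genes = 20L,
                           n_shared_concordant = 0L,
                           n_shared_discordant = 0L, n_le_unique = 0L,
                           n_ob_unique = 0L, dispersion = 1e-6,
                           depth_range = c(1, 1),
                           baseline_meanlog = log(100), baseline_sdlog = 0,
                           sex_effect_fraction = 0, seed = 5L)
  counts <- simulate_counts(cfg)$counts
  se <- sqrt(100 / ncol(counts))
  expect_true(all(abs(rowMeans(counts) - 100) < 3 * se))
})

test_that("simulated counts follow the NB mean-variance relation", {
  # 25 iid genes x 400 samples = 1e4 draws at mu = 100, alpha = 0.5
  cfg <- simulation_config(n_per_group = c(100, 100, 100, 100),
                           n_genes = 25L, n_shared_concordant = 0L,
                           n_shared_discordant = 0L, n_le_unique = 0L,
                           n_ob_unique = 0L, dispersion = 0.5,
                           depth_range = c(1, 1),
                           baseline_meanlog = log(100), baseline_sdlog = 0,
                           sex_effect_fraction = 0, seed = 8L)
  y <- as.vector(simulate_counts(cfg)$counts)
  mu <- mean(y)
  expected_var <- mu + 0.5 * mu^2
  expect_lt(abs(var(y) / expected_var - 1), 0.15)
})

test_that("a naive group-mean estimator recovers planted log2FC", {
  cfg <- simulation_config(n_per_group = c(20, 20, 20, 20), n_genes = 300L,
                           seed = 13L)
  sim <- simulate_counts(cfg)
  md <- sim$metadata
  le_la <- md$sample_id[md$study_group == "LELA"]
  le_ha <- md$sample_id[md$study_group == "LEHA"]
  q <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
  est <- log2(rowMeans(q[, le_ha]) / rowMeans(q[, le_la]))
  idx <- sim$truth$lfc_le != 0
  expect_lt(mean(abs(est[idx] - sim$truth$lfc_le[idx])), 0.3)
})

test_that("tertile assignment recovers the intended adiposity classes", {
  acc <- vapply(1:100, function(s) {
    cfg <- simulation_config(n_genes = 30L, n_shared_concordant = 2L,
                             n_shared_discordant = 2L, n_le_unique = 2L,
                             n_ob_unique = 2L, seed = s)
    md <- simulate_anthropometrics(cfg)
    got <- cohort_assign(md)
    ha <- md$adiposity_class == "HA"
    mean(got$adiposity_class[ha] == "HA")
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("percentage body fat ordering tracks birth weight when other
          anthropometrics are constant", {
  bw <- c(2.6, 3.1, 3.6, 4.1)
  bc <- body_composition(bw, rep(5, 4), rep(49, 4))
  expect_equal(order(bc$pct_body_fat), order(bw))
})

test_that("designated gene set is enriched for the true shared genes", {
  cfg <- small_config(seed = 21L)
  sim <- simulate_counts(cfg)
  sets <- simulate_annotation(cfg, sim$truth)
  expect_gte(length(sets), 5L)
  designated <- attr(sets, "designated")
  expect_false(is.null(designated))
  shared <- sim$truth$gene_id[sim$truth$class %in%
                                c("shared_concordant", "shared_discordant")]
  res <- go_enrichment(shared, sim$truth$gene_id, sets)
  expect_lt(res$p_hypergeometric[res$term_id == designated], 0.05)
  expect_equal(res$term_id[1], designated)
})

test_that("annotation without shared planted genes has no designated set", {
  cfg <- simulation_config(n_per_group = c(5, 5, 5, 5), n_genes = 60L,
                           n_shared_concordant = 0L,
                           n_shared_discordant = 0L,
                           n_le_unique = 3L, n_ob_unique = 3L, seed = 2L)
  sim <- simulate_counts(cfg)
  sets <- simulate_annotation(cfg, sim$truth)
  expect_null(attr(sets, "designated"))
  expect_gte(length(sets), 5L)
})

test_that("planted clique members have clique degrees; zero background
          density gives exactly the clique edges", {
  cfg <- small_config(seed = 31L, background_edge_density = 0)
  sim <- simulate_counts(cfg)
  edges <- simulate_network(cfg, sim$truth)
  k <- cfg$clique_size
  expect_equal(nrow(edges), k * (k - 1) / 2)
  deg <- table(c(edges$node1, edges$node2))
  clique <- attr(edges, "clique")
  expect_true(all(deg[clique] == k - 1))
  cfg1 <- simulation_config(n_per_group = c(5, 5, 5, 5), n_genes = 60L,
                            n_shared_concordant = 1L,
                            n_shared_discordant = 0L,
                            n_le_unique = 0L, n_ob_unique = 0L,
                            clique_size = 5L, seed = 1L)
  expect_error(simulate_network(cfg1, simulate_counts(cfg1)$truth),
               "clique_size")
})

test_that("designated cell type dominates expression of planted shared
          genes in the simulated reference", {
  cfg <- small_config(seed = 41L)
  sim <- simulate_counts(cfg)
  ref <- simulate_reference(cfg, sim$truth)
  shared <- sim$truth$gene_id[sim$truth$class %in%
                                c("shared_concordant", "shared_discordant")]
  prof <- reference_profile(shared, ref)
  expect_gte(mean(prof$argmax_type == attr(ref, "designated_type")), 0.9)
})

test_that("noise-free Ct values are an exact monotone map of expression", {
  cfg <- small_config(seed = 51L)
  sim <- simulate_counts(cfg)
  g <- sim$truth$gene_id[1]
  ct <- simulate_qpcr(cfg, sim$counts, g, noise_sd = 0)
  tg <- ct[ct$gene == g, ]
  q <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
  expr <- log2(q[g, tg$sample_id] + 1)
  expect_equal(spearman_corr(-tg$ct, expr, exact_max = 0)$rho, 1)
  # heavy noise attenuates the correlation
  rho_noisy <- vapply(1:10, function(s) {
    cfgn <- small_config(seed = 60L + s)
    simn <- simulate_counts(cfgn)
    gn <- simn$truth$gene_id[1]
    ctn <- simulate_qpcr(cfgn, simn$counts, gn, noise_sd = 25)
    tgn <- ctn[ctn$gene == gn, ]
    qn <- sweep(simn$counts, 2, size_factors(simn$counts), "/")
    spearman_corr(-tgn$ct, log2(qn[gn, tgn$sample_id] + 1),
                  exact_max = 0)$rho
  }, numeric(1))
  expect_lt(mean(abs(rho_noisy)), 0.5)
})
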