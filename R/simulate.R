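# Synthetic-data generators: cohort metadata with anthropometrics,
# negative-binomial counts with planted adiposity effects, gene sets,
# interaction edge lists, cell-type references and qPCR Ct tables, all
# with recorded ground truth.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort and expression model.
#' Defaults emulate the study design: four groups (LELA/LEHA/OBLA/OBHA)
#' of sizes 20/19/20/20, NB counts with dispersion 0.1 under
#' `var = mu + alpha mu^2`, sample depth factors log-uniform on
#' \[0.5, 2\], planted adiposity effects of magnitude 1 log2FC in the
#' classes shared-concordant / shared-discordant / LE-unique / OB-unique,
#' and a small sex effect (log2FC 0.2 on 5\% of genes) so the sex
#' covariate is non-degenerate.
#'
#' @param n_per_group sizes of LELA, LEHA, OBLA, OBHA.
#' @param n_genes total number of genes.
#' @param n_shared_concordant,n_shared_discordant,n_le_unique,n_ob_unique
#'   planted-class gene counts (must sum to < `n_genes`).
#' @param effect_log2fc planted effect magnitude; scalar or named vector
#'   with entries `shared_concordant`, `shared_discordant`, `le_unique`,
#'   `ob_unique`. Signs are drawn per gene.
#' @param dispersion NB dispersion alpha (> 0); scalar or length
#'   `n_genes`.
#' @param depth_range positive interval for log-uniform size factors.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression.
#' @param sex_effect_log2fc,sex_effect_fraction magnitude and gene
#'   fraction of the sex effect.
#' @param clique_size size of the planted interaction clique among
#'   shared planted genes.
#' @param background_edge_density probability of a background edge
#'   between any other node pair.
#' @param n_network_background number of null genes added as network
#'   nodes.
#' @param designated_fraction fraction of shared planted genes placed in
#'   the designated enriched gene set (in (0, 1]).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = c(LELA = 20L, LEHA = 19L,
                                              OBLA = 20L, OBHA = 20L),
                              n_genes = 2000L,
                              n_shared_concordant = 20L,
                              n_shared_discordant = 20L,
                              n_le_unique = 20L,
                              n_ob_unique = 20L,
                              effect_log2fc = 1.0,
                              dispersion = 0.1,
                              depth_range = c(0.5, 2),
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1,
                              sex_effect_log2fc = 0.2,
                              sex_effect_fraction = 0.05,
                              clique_size = 8L,
                              background_edge_density = 0.01,
                              n_network_background = 100L,
                              designated_fraction = 0.8,
                              seed = 1L) {
  cfg <- list(n_per_group = stats::setNames(as.integer(n_per_group),
                                            c("LELA", "LEHA", "OBLA", "OBHA")),
              n_genes = as.integer(n_genes),
              n_shared_concordant = as.integer(n_shared_concordant),
              n_shared_discordant = as.integer(n_shared_discordant),
              n_le_unique = as.integer(n_le_unique),
              n_ob_unique = as.integer(n_ob_unique),
              effect_log2fc = effect_log2fc,
              dispersion = dispersion,
              depth_range = depth_range,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              sex_effect_log2fc = sex_effect_log2fc,
              sex_effect_fraction = sex_effect_fraction,
              clique_size = as.integer(clique_size),
              background_edge_density = background_edge_density,
              n_network_background = as.integer(n_network_background),
              designated_fraction = designated_fraction,
              seed = as.integer(seed))
  n_planted <- with(cfg, n_shared_concordant + n_shared_discordant +
                      n_le_unique + n_ob_unique)
  if (n_planted >= cfg$n_genes)
    stop("planted-class counts must sum to less than n_genes")
  if (any(cfg$dispersion <= 0)) stop("dispersion must be positive")
  if (length(cfg$depth_range) != 2L || any(cfg$depth_range <= 0) ||
      cfg$depth_range[1] > cfg$depth_range[2])
    stop("depth_range must be a positive interval")
  if (any(cfg$n_per_group < 1L)) stop("group sizes must be >= 1")
  if (cfg$designated_fraction <= 0 || cfg$designated_fraction > 1)
    stop("designated_fraction must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Inverse-CDF draw from a tertile-truncated normal: u is uniform on the
# stated quantile band of N(mean, sd). Intended adiposity classes are the
# population tertiles of percentage body fat, so rank-based tertile
# assignment recovers them by construction (no between-class overlap).
#' @keywords internal
.truncnorm_band <- function(n, mean, sd, lo_q, hi_q) {
  u <- stats::runif(n, lo_q, hi_q)
  mean + sd * stats::qnorm(u)
}

#' Simulate cohort metadata with anthropometrics
#'
#' Generates the maternal cohorts (lean and obese) including the excluded
#' middle adiposity tertile, so that tertile assignment on the simulated
#' percentage body fat is meaningful. Percentage body fat is drawn from
#' the tertile bands of a population distribution (mean 12.2\%, SD 3.9\%,
#' central 6-18\% span), birth weight and length from correlated positive
#' distributions, and the flank skinfold is then solved from the
#' body-composition equation so the computed body fat equals the drawn
#' target exactly. Pregravid BMI is drawn within the lean (18-24.9) or
#' obese (30-40) bin.
#'
#' @param config a [simulation_config()].
#' @return data.frame with `sample_id`, `maternal_group`,
#'   `adiposity_class` (intended LA/MID/HA), `sex`, `birth_weight_kg`,
#'   `length_cm`, `flank_skinfold_mm`, `pregravid_bmi`, `pct_body_fat`,
#'   `study_group`.
#' @export
simulate_anthropometrics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  npg <- config$n_per_group
  groups <- list(
    LE = c(LA = npg[["LELA"]], MID = npg[["LELA"]], HA = npg[["LEHA"]]),
    OB = c(LA = npg[["OBLA"]], MID = npg[["OBLA"]], HA = npg[["OBHA"]]))
  rows <- list()
  for (mg in names(groups)) {
    sizes <- groups[[mg]]
    cls <- rep(names(sizes), sizes)
    n <- length(cls)
    band <- list(LA = c(0.06, 1 / 3), MID = c(1 / 3, 2 / 3),
                 HA = c(2 / 3, 0.94))
    pfat <- numeric(n)
    for (cl in names(sizes)) {
      idx <- cls == cl
      pfat[idx] <- .truncnorm_band(sum(idx), 12.2, 3.9,
                                   band[[cl]][1], band[[cl]][2])
    }
    bw <- 3.3 + 0.105 * (pfat - 12.2) + stats::rnorm(n, 0, 0.15)
    bw <- pmax(bw, 2.0)
    len <- 49 + 0.8 * (bw - 3.3) + stats::rnorm(n, 0, 1.5)
    # solve the skinfold that makes the equation reproduce the target pfat
    fm <- pfat / 100 * bw
    sf <- (fm - .fm_coef[["birth_weight"]] * bw -
             .fm_coef[["length"]] * len - .fm_coef[["intercept"]]) /
      .fm_coef[["skinfold"]]
    sf <- pmax(sf, 0.5)
    bmi <- if (mg == "LE") pmin(pmax(stats::rnorm(n, 22.3, 1.6), 18), 24.9)
           else pmin(pmax(stats::rnorm(n, 34.3, 3.1), 30), 40)
    sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    rows[[mg]] <- data.frame(
      sample_id = sprintf("%s%03d", mg, seq_len(n)),
      maternal_group = mg,
      adiposity_class = cls,
      sex = sex,
      birth_weight_kg = bw,
      length_cm = len,
      flank_skinfold_mm = sf,
      pregravid_bmi = bmi,
      stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  bc <- body_composition(md$birth_weight_kg, md$flank_skinfold_mm,
                         md$length_cm)
  md$pct_body_fat <- bc$pct_body_fat
  md$study_group <- ifelse(md$adiposity_class %in% c("LA", "HA"),
                           paste0(md$maternal_group, md$adiposity_class),
                           "NONE")
  md
}

#' @keywords internal
.effect_magnitude <- function(effect, class) {
  if (length(effect) == 1L && is.null(names(effect))) return(abs(effect))
  if (!class %in% names(effect))
    stop("effect_log2fc must be scalar or named per planted class")
  abs(effect[[class]])
}

#' Simulate a count matrix with planted adiposity effects
#'
#' Counts for the sequenced samples (the LA and HA tertiles) are drawn
#' from a negative-binomial model: for gene g and sample j the mean is
#' `depth_j * baseline_g * 2^(lfc_{g,stratum} * HA_j + sexlfc_g * M_j)`
#' with variance `mu + alpha_g mu^2`. Planted classes: shared-concordant
#' (same signed effect in both strata), shared-discordant (opposite
#' signs), LE-unique, OB-unique, and null (no effect). The returned truth
#' table records the class and the true log2 fold change per stratum for
#' every gene.
#'
#' @param config a [simulation_config()].
#' @param metadata optional precomputed [simulate_anthropometrics()]
#'   output (regenerated from the config seed when NULL).
#' @return list with `counts` (count matrix over sequenced samples),
#'   `metadata` (full cohort data.frame), `truth` (data.frame `gene_id`,
#'   `class`, `lfc_le`, `lfc_ob`, `sex_log2fc`).
#' @export
simulate_counts <- function(config, metadata = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(metadata)) metadata <- simulate_anthropometrics(config)
  seq_md <- metadata[metadata$adiposity_class %in% c("LA", "HA"), ,
                     drop = FALSE]
  set.seed(config$seed + 202L)
  G <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(G))
  baseline <- stats::rlnorm(G, config$baseline_meanlog,
                            config$baseline_sdlog)
  alpha <- rep_len(config$dispersion, G)

  cls_counts <- c(shared_concordant = config$n_shared_concordant,
                  shared_discordant = config$n_shared_discordant,
                  le_unique = config$n_le_unique,
                  ob_unique = config$n_ob_unique)
  planted_idx <- sample.int(G, sum(cls_counts))
  class <- rep("null", G)
  class[planted_idx] <- rep(names(cls_counts), cls_counts)
  sign_g <- sample(c(-1, 1), G, replace = TRUE)
  lfc_le <- numeric(G); lfc_ob <- numeric(G)
  for (cl in names(cls_counts)) {
    idx <- class == cl
    if (!any(idx)) next
    e <- .effect_magnitude(config$effect_log2fc, cl)
    if (cl == "shared_concordant") {
      lfc_le[idx] <- sign_g[idx] * e; lfc_ob[idx] <- sign_g[idx] * e
    } else if (cl == "shared_discordant") {
      lfc_le[idx] <- sign_g[idx] * e; lfc_ob[idx] <- -sign_g[idx] * e
    } else if (cl == "le_unique") {
      lfc_le[idx] <- sign_g[idx] * e
    } else {
      lfc_ob[idx] <- sign_g[idx] * e
    }
  }
  sex_lfc <- numeric(G)
  n_sex <- round(config$sex_effect_fraction * G)
  if (n_sex > 0) {
    sex_idx <- sample.int(G, n_sex)
    sex_lfc[sex_idx] <- sample(c(-1, 1), n_sex, replace = TRUE) *
      config$sex_effect_log2fc
  }

  n <- nrow(seq_md)
  depth <- exp(stats::runif(n, log(config$depth_range[1]),
                            log(config$depth_range[2])))
  is_ha <- as.numeric(seq_md$adiposity_class == "HA")
  is_m <- as.numeric(seq_md$sex == "M")
  lfc_strat <- ifelse(seq_md$maternal_group == "LE", 1, 0)
  # gene x sample log2 effect
  eff <- outer(lfc_le, is_ha * lfc_strat) +
    outer(lfc_ob, is_ha * (1 - lfc_strat)) +
    outer(sex_lfc, is_m)
  mu <- (baseline %o% depth) * 2^eff
  counts <- matrix(stats::rnbinom(G * n, size = 1 / alpha, mu = mu), G, n)
  counts <- count_matrix(counts, gene_ids, seq_md$sample_id)
  truth <- data.frame(gene_id = gene_ids, class = class,
                      lfc_le = lfc_le, lfc_ob = lfc_ob,
                      sex_log2fc = sex_lfc, stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Emits at least five gene sets in GMT-ready form. One designated set
#' contains `designated_fraction` of the shared planted genes (concordant
#' plus discordant) plus background genes; the remaining sets are random
#' background draws. With no shared planted genes in the truth, no
#' designated set is created.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_counts()].
#' @param n_background_sets number of random background sets (default 5).
#' @return named list of character vectors; the designated set's name is
#'   in `attr(, "designated")` (NULL when absent).
#' @export
simulate_annotation <- function(config, truth, n_background_sets = 5L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  genes <- truth$gene_id
  shared <- truth$gene_id[truth$class %in%
                            c("shared_concordant", "shared_discordant")]
  sets <- list()
  designated <- NULL
  if (length(shared)) {
    n_in <- max(1L, round(config$designated_fraction * length(shared)))
    members <- sample(shared, n_in)
    bg <- sample(setdiff(genes, shared), max(5L, round(n_in / 2)))
    designated <- "planted_shared_response"
    sets[[designated]] <- sample(c(members, bg))
  }
  for (i in seq_len(n_background_sets)) {
    sets[[sprintf("background_set_%02d", i)]] <-
      sample(genes, min(sample(30:80, 1), length(genes)))
  }
  attr(sets, "designated") <- designated
  sets
}

#' Simulate a STRING-format interaction edge list
#'
#' Plants a clique among `clique_size` shared planted genes and adds
#' random background edges between the node universe (planted genes plus
#' `n_network_background` null genes) at `background_edge_density`.
#' Clique edges get combined scores in \[900, 999\], background edges in
#' \[400, 900\].
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_counts()].
#' @return data.frame with `node1`, `node2`, `combined_score`; clique
#'   members in `attr(, "clique")`.
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  shared <- truth$gene_id[truth$class %in%
                            c("shared_concordant", "shared_discordant")]
  if (config$clique_size > length(shared))
    stop("clique_size exceeds the number of shared planted genes")
  clique <- sample(shared, config$clique_size)
  planted <- truth$gene_id[truth$class != "null"]
  nulls <- truth$gene_id[truth$class == "null"]
  nodes <- c(planted, sample(nulls, min(config$n_network_background,
                                        length(nulls))))
  pairs <- utils::combn(sort(nodes), 2)
  in_clique <- pairs[1, ] %in% clique & pairs[2, ] %in% clique
  keep_bg <- !in_clique &
    stats::runif(ncol(pairs)) < config$background_edge_density
  keep <- in_clique | keep_bg
  score <- ifelse(in_clique[keep],
                  stats::runif(sum(keep), 900, 999),
                  stats::runif(sum(keep), 400, 900))
  edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep],
                      combined_score = round(score),
                      stringsAsFactors = FALSE)
  attr(edges, "clique") <- sort(clique)
  edges
}

#' Simulate a cell-type reference expression matrix
#'
#' Cell types emulate term placenta plus immune populations. One
#' designated cell type expresses the shared planted genes at a strongly
#' elevated, marker-like level (16x over the baseline spread), so those
#' genes arg-max there.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_counts()].
#' @param cell_types character vector of cell-type names.
#' @param designated_type the elevated cell type (must be in
#'   `cell_types`).
#' @return numeric matrix cell types x genes with
#'   `attr(, "designated_type")`.
#' @export
simulate_reference <- function(config, truth,
                               cell_types = c("cytotrophoblast",
                                              "syncytiotrophoblast",
                                              "extravillous_trophoblast",
                                              "stromal_cell",
                                              "endothelial_cell",
                                              "hofbauer_cell",
                                              "neutrophil", "monocyte",
                                              "t_cell", "b_cell"),
                               designated_type = "neutrophil") {
  stopifnot(inherits(config, "sim_config"))
  if (!designated_type %in% cell_types)
    stop("designated_type must be one of cell_types")
  set.seed(config$seed + 505L)
  genes <- truth$gene_id
  m <- matrix(stats::rlnorm(length(cell_types) * length(genes),
                            log(10), 0.5),
              length(cell_types), length(genes),
              dimnames = list(cell_types, genes))
  shared <- truth$gene_id[truth$class %in%
                            c("shared_concordant", "shared_discordant")]
  m[designated_type, shared] <- m[designated_type, shared] * 16
  attr(m, "designated_type") <- designated_type
  m
}

#' Simulate a qPCR Ct table from a count matrix
#'
#' Target-gene Ct values follow `a - b * log2(normalized count + 1)` plus
#' Gaussian noise, so lower Ct tracks higher expression; the reference
#' (housekeeping) gene's Ct is independent of expression and adiposity.
#'
#' @param config a [simulation_config()].
#' @param counts count matrix containing `genes`.
#' @param genes target gene ids to assay.
#' @param reference_gene name given to the housekeeping gene row in the
#'   output.
#' @param a,b intercept and slope of the Ct model.
#' @param noise_sd Gaussian Ct noise SD (default 0.25 cycles).
#' @return data.frame `sample_id`, `gene`, `ct` (long format).
#' @export
simulate_qpcr <- function(config, counts, genes,
                          reference_gene = "REFG",
                          a = 34, b = 1, noise_sd = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(genes, rownames(counts))
  if (length(missing)) stop("genes not in counts: ",
                            paste(missing, collapse = ", "))
  set.seed(config$seed + 606L)
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  n <- ncol(counts)
  rows <- lapply(genes, function(g) {
    data.frame(sample_id = colnames(counts), gene = g,
               ct = a - b * log2p1(q[g, ]) +
                 stats::rnorm(n, 0, noise_sd),
               stringsAsFactors = FALSE)
  })
  ref <- data.frame(sample_id = colnames(counts), gene = reference_gene,
                    ct = 22 + stats::rnorm(n, 0, noise_sd),
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(ref)))
  rownames(out) <- NULL
  out
}
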