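# End-to-end orchestration: configuration validation and the full
# cohort -> QC -> bootstrap DE -> selection -> concordance -> enrichment
# -> network -> reference/qPCR pipeline with a reproducible output bundle.

#' Build a pipeline configuration
#'
#' Exactly one of the two modes must be active: synthetic mode (a
#' [simulation_config()] in `sim`) or real-input mode (file paths in
#' `paths`: `counts`, `metadata`, and optionally `gmt`, `edges`,
#' `reference`, `ct`, `coding_list`). Thresholds default to the study's
#' printed values: B = 100 bootstrap iterations, nominal p < .05, linear
#' fold change > 1.5, direction consistency >= 0.5, correlation threshold
#' 0.3, FDR threshold 0.1, STRING score minimum 400, hub quantile 0.9.
#'
#' @param sim a [simulation_config()] or NULL.
#' @param paths named list of input paths or NULL.
#' @param out_dir output directory.
#' @param B bootstrap iterations.
#' @param p_thr,fc_thr,consistency,r_thr,fdr_thr,score_min,hub_q
#'   thresholds (see description).
#' @param pca_k robust-z threshold of the PCA outlier screen.
#' @param perm_M permutations for the interaction-enrichment test.
#' @param seed integer seed (mandatory).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, out_dir = tempfile("naag_run_"),
                            B = 100L, p_thr = 0.05, fc_thr = 1.5,
                            consistency = 0.5, r_thr = 0.3, fdr_thr = 0.1,
                            score_min = 400, hub_q = 0.9, pca_k = 5,
                            perm_M = 999L, seed = 1L) {
  cfg <- list(sim = sim, paths = paths, out_dir = out_dir, B = as.integer(B),
              p_thr = p_thr, fc_thr = fc_thr, consistency = consistency,
              r_thr = r_thr, fdr_thr = fdr_thr, score_min = score_min,
              hub_q = hub_q, pca_k = pca_k, perm_M = as.integer(perm_M),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate and normalize a pipeline configuration
#'
#' Range-checks every threshold, enforces mode exclusivity, checks input
#' paths exist in real-input mode, and echoes the filled configuration.
#' Accepts a `pipeline_config`, a plain list, or a YAML/JSON file path.
#'
#' @param config configuration (object, list, or file path).
#' @return normalized `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!inherits(config, "pipeline_config")) {
    if (!is.list(config)) stop("config must be a list or file path")
    sim <- config$sim
    if (!is.null(sim) && !inherits(sim, "sim_config"))
      sim <- do.call(simulation_config, sim)
    args <- config[setdiff(names(config), "sim")]
    config <- do.call(pipeline_config, c(list(sim = sim), args))
  }
  synthetic <- !is.null(config$sim)
  real <- !is.null(config$paths)
  if (synthetic == real)
    stop("exactly one of synthetic mode (sim) or real-input mode (paths) ",
         "must be active")
  if (real) {
    need <- c("counts", "metadata")
    miss <- setdiff(need, names(config$paths))
    if (length(miss)) stop("paths missing required entries: ",
                           paste(miss, collapse = ", "))
    for (nm in names(config$paths)) {
      if (!file.exists(config$paths[[nm]]))
        stop("input path does not exist: ", nm, " = ", config$paths[[nm]])
    }
  }
  check_thresholds(p_thr = config$p_thr, fc_thr = config$fc_thr,
                   consistency = config$consistency, r_thr = config$r_thr,
                   fdr_thr = config$fdr_thr, hub_q = config$hub_q)
  if (config$B < 1L) stop("B must be >= 1")
  if (is.na(config$seed)) stop("seed is mandatory")
  config$mode <- if (synthetic) "synthetic" else "real"
  config
}

#' @keywords internal
stage_log <- function(manifest, stage, ...) {
  info <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = " ")))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes cohort assignment, protein-coding filtering, PCA outlier
#' removal, per-stratum bootstrap differential expression, NAAG
#' selection, CNAAG/unique derivation, gene-set over-representation,
#' network confirmation with hub calling and interaction-enrichment
#' permutation, reference profiling and qPCR validation statistics,
#' writing every stage's table plus a JSON run manifest into
#' `config$out_dir`. Identical configuration and seed give an identical
#' bundle. A stage failure aborts with a stage-labeled error; tables
#' written before the failure are retained for debugging.
#'
#' @param config a validated [pipeline_config()] (or anything
#'   [validate_config()] accepts).
#' @return invisibly, a list with the main result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "sim")],
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("placentaNAAG")),
                   stages = list())
  if (!is.null(config$sim))
    manifest$config$sim <- unclass(config$sim)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  inputs <- run_stage("inputs", {
    if (config$mode == "synthetic") {
      sim <- simulate_counts(config$sim)
      annot <- simulate_annotation(config$sim, sim$truth)
      edges_raw <- simulate_network(config$sim, sim$truth)
      reference <- simulate_reference(config$sim, sim$truth)
      qpcr_genes <- utils::head(
        sim$truth$gene_id[sim$truth$class == "shared_concordant"], 2)
      ct <- if (length(qpcr_genes))
        simulate_qpcr(config$sim, sim$counts, qpcr_genes) else NULL
      list(counts = sim$counts, metadata = sim$metadata,
           truth = sim$truth, gene_sets = annot, edges_raw = edges_raw,
           reference = reference, ct = ct, qpcr_genes = qpcr_genes,
           coding_list = rownames(sim$counts))
    } else {
      p <- config$paths
      list(counts = read_counts_tsv(p$counts),
           metadata = read_metadata_csv(p$metadata),
           truth = NULL,
           gene_sets = if (!is.null(p$gmt)) read_gmt(p$gmt) else NULL,
           edges_raw = if (!is.null(p$edges))
             load_string_edges(p$edges, config$score_min) else NULL,
           reference = if (!is.null(p$reference))
             read_reference_tsv(p$reference) else NULL,
           ct = if (!is.null(p$ct)) read_ct_csv(p$ct) else NULL,
           qpcr_genes = NULL,
           coding_list = if (!is.null(p$coding_list))
             readLines(p$coding_list) else rownames(read_counts_tsv(p$counts)))
    }
  })
  manifest <- stage_log(manifest, "inputs",
                        n_genes = nrow(inputs$counts),
                        n_samples = ncol(inputs$counts))

  # --- cohort -------------------------------------------------------------
  metadata <- run_stage("cohort", {
    md <- inputs$metadata
    if (all(c("birth_weight_kg", "flank_skinfold_mm", "length_cm",
              "pregravid_bmi") %in% names(md))) {
      md <- cohort_assign(md)
    }
    md
  })
  write_metadata_csv(metadata, file.path(config$out_dir, "cohort.csv"))
  manifest <- stage_log(manifest, "cohort", n_samples = nrow(metadata),
                        n_in_groups = sum(metadata$study_group != "NONE"))

  # --- QC / filter --------------------------------------------------------
  counts <- run_stage("filter", {
    cc <- filter_protein_coding(inputs$counts, inputs$coding_list)
    out <- pca_outliers(cc, k = config$pca_k)
    if (length(out)) {
      message("removing PCA outlier samples: ", paste(out, collapse = ", "))
      cc <- cc[, !colnames(cc) %in% out, drop = FALSE]
    }
    attr(cc, "outliers") <- out
    cc
  })
  manifest <- stage_log(manifest, "filter", n_genes = nrow(counts),
                        n_outliers = length(attr(counts, "outliers")))

  # --- bootstrap DE + NAAG selection per stratum --------------------------
  naags <- list(); boots <- list()
  for (stratum in c("LE", "OB")) {
    boots[[stratum]] <- run_stage(paste0("bootstrap_", stratum),
      bootstrap_de(counts, metadata, stratum, B = config$B,
                   seed = config$seed + match(stratum, c("LE", "OB"))))
    naags[[stratum]] <- run_stage(paste0("select_", stratum),
      select_naags(boots[[stratum]], p_thr = config$p_thr,
                   fc_thr = config$fc_thr,
                   consistency = config$consistency))
    utils::write.table(naags[[stratum]],
                       file.path(config$out_dir,
                                 sprintf("naags_%s.tsv", stratum)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, paste0("naags_", stratum),
                          n_naags = nrow(naags[[stratum]]))
  }

  # --- concordance + unique sets ------------------------------------------
  cnaags <- run_stage("cnaags", derive_cnaags(naags$LE, naags$OB))
  uniq <- unique_naags(naags$LE, naags$OB)
  utils::write.table(cnaags, file.path(config$out_dir, "cnaags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- stage_log(manifest, "cnaags", n_cnaags = nrow(cnaags),
                        n_concordant = sum(cnaags$concordance == "concordant"),
                        n_le_only = length(uniq$le_only),
                        n_ob_only = length(uniq$ob_only))

  # --- enrichment ---------------------------------------------------------
  enrich <- NULL
  if (!is.null(inputs$gene_sets) && nrow(cnaags) > 0) {
    enrich <- run_stage("enrichment",
      go_enrichment(cnaags$gene_id, rownames(counts), inputs$gene_sets,
                    fdr_thr = config$fdr_thr))
    utils::write.table(enrich, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, "enrichment", n_terms = nrow(enrich),
                          n_significant = sum(enrich$significant))
  }

  # --- network ------------------------------------------------------------
  network <- NULL
  if (!is.null(inputs$edges_raw)) {
    network <- run_stage("network", {
      edges <- canonicalize_edges(data.frame(
        node1 = inputs$edges_raw$node1, node2 = inputs$edges_raw$node2,
        combined_score = inputs$edges_raw$combined_score),
        config$score_min)
      edges <- edges[edges$gene_a %in% rownames(counts) &
                       edges$gene_b %in% rownames(counts), , drop = FALSE]
      ann <- list()
      for (grp in c("LE", "OB")) {
        ann[[grp]] <- confirm_edges(edges, counts, metadata, grp,
                                    r_thr = config$r_thr,
                                    p_thr = config$p_thr)
      }
      ann$pooled <- confirm_edges(edges, counts, r_thr = config$r_thr,
                                  p_thr = config$p_thr)
      summ <- network_summary(ann$pooled, hub_q = config$hub_q)
      all_naags <- union(naags$LE$gene_id, naags$OB$gene_id)
      summ$enrichment <- if (length(all_naags) >= 2)
        ppi_enrichment(intersect(all_naags,
                                 unique(c(edges$gene_a, edges$gene_b))),
                       edges, rownames(counts), M = config$perm_M,
                       seed = config$seed)
      list(edges = ann, summary = summ)
    })
    utils::write.table(network$edges$pooled,
                       file.path(config$out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, "network",
                          n_edges = network$summary$n_edges,
                          n_confirmed = network$summary$n_confirmed,
                          n_hubs = length(network$summary$hubs))
  }

  # --- reference profiling ------------------------------------------------
  ref_profile <- NULL
  if (!is.null(inputs$reference) && nrow(cnaags) > 0) {
    ref_profile <- run_stage("reference",
      reference_profile(cnaags$gene_id, inputs$reference))
    utils::write.table(
      data.frame(gene = colnames(ref_profile$profile),
                 argmax_type = ref_profile$argmax_type,
                 t(ref_profile$zscores), check.names = FALSE),
      file.path(config$out_dir, "reference_profile.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, "reference",
                          n_profiled = ncol(ref_profile$profile),
                          n_missing = length(ref_profile$missing))
  }

  # --- qPCR validation ----------------------------------------------------
  qpcr <- NULL
  if (!is.null(inputs$ct)) {
    qpcr <- run_stage("qpcr",
      qpcr_validation(inputs$ct, counts, metadata,
                      reference_gene = "REFG"))
    jsonlite::write_json(qpcr, file.path(config$out_dir, "qpcr_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- stage_log(manifest, "qpcr", n_genes = length(qpcr))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(metadata = metadata, counts = counts, boots = boots,
                 naags = naags, cnaags = cnaags, unique = uniq,
                 enrichment = enrich, network = network,
                 reference_profile = ref_profile, qpcr = qpcr,
                 manifest = manifest,
                 truth = inputs$truth))
}

#' qPCR validation statistics for assayed genes
#'
#' For each non-reference gene in the Ct table: relative expression (the
#' target:reference ratio per sample), a two-sided rank-sum test of the
#' ratio between HA and LA samples, and the Spearman correlation of the
#' ratio against the gene's log2 normalized RNA-seq counts.
#'
#' @param ct_table long data.frame `sample_id`, `gene`, `ct`.
#' @param counts count matrix (for the RNA-seq correlation; genes missing
#'   from it skip the correlation).
#' @param metadata sample metadata with `adiposity_class`.
#' @param reference_gene housekeeping gene name in `ct_table`.
#' @return named list per gene with `ratio_by_class`, `rank_sum_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
qpcr_validation <- function(ct_table, counts, metadata,
                            reference_gene = "REFG") {
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!nrow(ref)) stop("reference gene not found in Ct table")
  targets <- setdiff(unique(ct_table$gene), reference_gene)
  out <- list()
  for (g in targets) {
    tg <- ct_table[ct_table$gene == g, ]
    m <- merge(tg, ref, by = "sample_id", suffixes = c("_target", "_ref"))
    ratio <- qpcr_ratio(m$ct_target, m$ct_ref)
    cls <- metadata$adiposity_class[match(m$sample_id, metadata$sample_id)]
    res <- list(ratio_by_class = tapply(ratio, cls, stats::median))
    if (all(c("LA", "HA") %in% cls)) {
      res$rank_sum_p <- rank_sum_test(ratio[cls == "HA"],
                                      ratio[cls == "LA"])$p_value
    }
    if (g %in% rownames(counts)) {
      ids <- intersect(m$sample_id, colnames(counts))
      if (length(ids) >= 3) {
        sf <- size_factors(counts[, ids, drop = FALSE])
        expr <- log2p1(counts[g, ids] / sf)
        sc <- spearman_corr(ratio[match(ids, m$sample_id)], expr,
                            exact_max = 8L)
        res$spearman_rho <- sc$rho
        res$spearman_p <- sc$p_value
      }
    }
    out[[g]] <- res
  }
  out
}
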