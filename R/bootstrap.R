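# Bootstrap-consistency gene selection: resample the stratum with
# replacement B times, rerun the NB Wald DE fit each time, and retain
# genes that are significant with consistent direction in a stated
# fraction of iterations.

#' Bootstrap the differential-expression analysis within one stratum
#'
#' Draws `B` resamples with replacement and reruns the full DE fit (size
#' factors, dispersion, NB Wald regression) on each. By default the
#' resampling is stratified within the LA and HA classes, preserving the
#' class sizes, which keeps the adiposity factor estimable in every
#' iteration; `stratified = FALSE` resamples the whole stratum jointly.
#' Iterations whose resample contains a single sex level drop the sex
#' covariate for that iteration (counted in `n_sex_dropped`).
#'
#' @param counts count matrix.
#' @param metadata sample metadata (see [nb_wald_de()]).
#' @param stratum "LE" or "OB".
#' @param B number of bootstrap iterations (>= 1; default 100).
#' @param seed integer seed fixing the resampling.
#' @param stratified resample within adiposity class (default TRUE).
#' @return object of class `naag_bootstrap`: list with matrices `log2fc`,
#'   `p_value`, `converged` (genes x B), the resample index matrix, and
#'   call metadata.
#' @export
bootstrap_de <- function(counts, metadata, stratum = c("LE", "OB"),
                         B = 100L, seed = 1L, stratified = TRUE) {
  stratum <- match.arg(stratum)
  if (B < 1L) stop("B must be >= 1")
  md <- de_design_frame(metadata)
  md <- md[md$maternal_group == stratum &
             md$adiposity_class %in% c("LA", "HA"), , drop = FALSE]
  md <- md[md$sample_id %in% colnames(counts), , drop = FALSE]
  if (!all(c("LA", "HA") %in% md$adiposity_class))
    stop("stratum must contain both LA and HA samples")
  Y <- counts[, md$sample_id, drop = FALSE]
  n <- nrow(md)
  idx_la <- which(md$adiposity_class == "LA")
  idx_ha <- which(md$adiposity_class == "HA")

  set.seed(seed)
  draws <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    if (stratified) {
      draws[, b] <- c(sample(idx_la, length(idx_la), replace = TRUE),
                      sample(idx_ha, length(idx_ha), replace = TRUE))
    } else {
      draws[, b] <- sample.int(n, n, replace = TRUE)
    }
  }

  G <- nrow(Y)
  lfc <- matrix(NA_real_, G, B, dimnames = list(rownames(Y), NULL))
  pv <- matrix(NA_real_, G, B, dimnames = list(rownames(Y), NULL))
  conv <- matrix(FALSE, G, B, dimnames = list(rownames(Y), NULL))
  n_sex_dropped <- 0L
  for (b in seq_len(B)) {
    take <- draws[, b]
    Yb <- Y[, take, drop = FALSE]
    colnames(Yb) <- paste0("r", seq_len(n))  # resampled columns duplicate ids
    mdb <- md[take, , drop = FALSE]
    mdb$sample_id <- colnames(Yb)
    if (length(unique(mdb$sex)) == 1L) n_sex_dropped <- n_sex_dropped + 1L
    res <- suppressWarnings(nb_wald_de(Yb, mdb, stratum))
    lfc[, b] <- res$log2fc
    pv[, b] <- res$p_value
    conv[, b] <- res$converged
  }
  structure(list(log2fc = lfc, p_value = pv, converged = conv,
                 draws = draws, stratum = stratum, B = B, seed = seed,
                 stratified = stratified, n_sex_dropped = n_sex_dropped),
            class = "naag_bootstrap")
}

#' Tally bootstrap iterations against the significance and fold-change rule
#'
#' Per gene, counts iterations that are significant upward (`p < p_thr`,
#' `|log2fc| > log2(fc_thr)`, `log2fc > 0`) and downward, and computes the
#' median log2 fold change and median p over iterations. Non-converged
#' iterations count as non-significant; by default medians are taken over
#' all converged iterations, or over significant iterations only when
#' `median_over = "significant"`.
#'
#' @param boot a `naag_bootstrap` object.
#' @param p_thr nominal p-value threshold (default .05).
#' @param fc_thr linear fold-change threshold (default 1.5, i.e.
#'   `|log2fc| > log2(1.5)`).
#' @param median_over "all" (default) or "significant".
#' @return data.frame with `gene_id`, `B`, `n_up_sig`, `n_down_sig`,
#'   `median_log2fc`, `median_p`.
#' @export
bootstrap_tally <- function(boot, p_thr = 0.05, fc_thr = 1.5,
                            median_over = c("all", "significant")) {
  median_over <- match.arg(median_over)
  check_thresholds(p_thr = p_thr, fc_thr = fc_thr)
  lthr <- log2(fc_thr)
  sig <- boot$converged & !is.na(boot$p_value) & boot$p_value < p_thr &
    abs(boot$log2fc) > lthr
  up <- sig & boot$log2fc > 0
  down <- sig & boot$log2fc < 0
  med_src_l <- boot$log2fc
  med_src_p <- boot$p_value
  if (median_over == "all") {
    med_src_l[!boot$converged] <- NA
    med_src_p[!boot$converged] <- NA
  } else {
    med_src_l[!sig] <- NA
    med_src_p[!sig] <- NA
  }
  data.frame(gene_id = rownames(boot$log2fc),
             B = boot$B,
             n_up_sig = rowSums(up),
             n_down_sig = rowSums(down),
             median_log2fc = apply(med_src_l, 1, stats::median, na.rm = TRUE),
             median_p = apply(med_src_p, 1, stats::median, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Select neonatal adiposity-associated genes (NAAGs)
#'
#' A gene is retained when the larger of its up- and down-significant
#' iteration counts reaches `consistency * B` ("significant with
#' consistent direction in 50% or more of the bootstrap iterations" at the
#' default). The retained direction is the majority side; exact
#' directional ties are rejected as inconsistent. The consistency
#' denominator is all `B` iterations (`denominator = "significant"` uses
#' the per-gene significant-iteration count instead).
#'
#' @param boot a `naag_bootstrap` object, or a tally data.frame from
#'   [bootstrap_tally()].
#' @param p_thr,fc_thr thresholds passed to [bootstrap_tally()] when
#'   `boot` is a bootstrap object.
#' @param consistency minimum consistent fraction (default 0.5).
#' @param denominator "B" (default) or "significant".
#' @param stratum label stored in the output (default from `boot`).
#' @param median_over passed to [bootstrap_tally()].
#' @return data.frame of NAAG records: `gene_id`, `direction`,
#'   `consistency_fraction`, `median_log2fc`, `median_p`, `stratum`.
#' @export
select_naags <- function(boot, p_thr = 0.05, fc_thr = 1.5,
                         consistency = 0.5,
                         denominator = c("B", "significant"),
                         stratum = NULL,
                         median_over = c("all", "significant")) {
  denominator <- match.arg(denominator)
  check_thresholds(p_thr = p_thr, fc_thr = fc_thr,
                   consistency = consistency)
  if (inherits(boot, "naag_bootstrap")) {
    if (is.null(stratum)) stratum <- boot$stratum
    tally <- bootstrap_tally(boot, p_thr, fc_thr, match.arg(median_over))
  } else {
    tally <- boot
    if (is.null(stratum)) stratum <- NA_character_
  }
  den <- if (denominator == "B") tally$B else
    pmax(tally$n_up_sig + tally$n_down_sig, 1L)
  best <- pmax(tally$n_up_sig, tally$n_down_sig)
  frac <- best / den
  keep <- frac >= consistency & tally$n_up_sig != tally$n_down_sig
  out <- data.frame(gene_id = tally$gene_id[keep],
                    direction = ifelse(tally$n_up_sig[keep] >
                                         tally$n_down_sig[keep],
                                       "up", "down"),
                    consistency_fraction = frac[keep],
                    median_log2fc = tally$median_log2fc[keep],
                    median_p = tally$median_p[keep],
                    stratum = stratum,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Median effect summary for one gene's bootstrap tally
#'
#' Medians of the per-iteration log2 fold changes and p-values, excluding
#' non-converged iterations; the even-count median is the midpoint of the
#' central pair.
#'
#' @param log2fc,p_value per-iteration values for one gene.
#' @param converged logical vector of per-iteration convergence flags.
#' @return list with `median_log2fc` and `median_p`.
#' @export
summarize_naag <- function(log2fc, p_value, converged = NULL) {
  if (is.null(converged)) converged <- rep(TRUE, length(log2fc))
  if (!any(converged)) stop("no converged iterations")
  list(median_log2fc = stats::median(log2fc[converged]),
       median_p = stats::median(p_value[converged]))
}

#' @keywords internal
check_thresholds <- function(p_thr = NULL, fc_thr = NULL,
                             consistency = NULL, r_thr = NULL,
                             fdr_thr = NULL, hub_q = NULL) {
  bad <- function(x, lo, hi) !is.null(x) &&
    (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
  if (bad(p_thr, 0, 1)) stop("p_thr must be in [0, 1]")
  if (bad(fdr_thr, 0, 1)) stop("fdr_thr must be in [0, 1]")
  if (bad(consistency, 0, 1)) stop("consistency must be in [0, 1]")
  if (bad(r_thr, 0, 1)) stop("r_thr must be in [0, 1]")
  if (bad(hub_q, 0, 1)) stop("hub_q must be in [0, 1]")
  if (!is.null(fc_thr) &&
      (!is.numeric(fc_thr) || length(fc_thr) != 1L || is.na(fc_thr) ||
       fc_thr < 1)) stop("fc_thr must be a linear fold change >= 1")
  invisible(TRUE)
}
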