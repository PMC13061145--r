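# Cell-type reference profiling and qPCR-style validation statistics.

#' Profile genes against a cell-type reference expression matrix
#'
#' Slices the reference (cell types x genes) to the requested genes,
#' reports the arg-max cell type per gene, and z-scores each gene's
#' expression across cell types. Genes absent from the reference are
#' listed under `missing` rather than being fatal; a gene whose expression
#' is identical in every cell type gets all-zero z-scores and an NA
#' arg-max.
#'
#' @param genes character vector of gene symbols.
#' @param reference numeric matrix, cell types x genes (see
#'   [read_reference_tsv()]).
#' @return list with `profile` (cell types x found genes), `argmax_type`
#'   (named character), `zscores` (same shape as profile), `missing`.
#' @export
reference_profile <- function(genes, reference) {
  genes <- unique(genes)
  found <- intersect(genes, colnames(reference))
  if (!length(found)) stop("none of the requested genes are in the reference")
  prof <- reference[, found, drop = FALSE]
  argmax <- apply(prof, 2, function(x) {
    if (max(x) == min(x)) NA_character_ else rownames(prof)[which.max(x)]
  })
  z <- apply(prof, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  rownames(z) <- rownames(prof)
  list(profile = prof, argmax_type = argmax, zscores = z,
       missing = setdiff(genes, found))
}

#' qPCR relative expression ratio
#'
#' Expression of the gene of interest relative to the reference
#' (housekeeping) gene, assuming amplification efficiency 2:
#' `2^(ct_reference - ct_target)`. With `method = "linear"` the raw
#' linearized expression ratio `2^(-ct_target) / 2^(-ct_reference)` is
#' returned, which is the same quantity; the flag exists so an explicitly
#' linearized pathway is available.
#'
#' @param ct_target Ct of the gene of interest.
#' @param ct_reference Ct of the reference gene.
#' @param method "delta_ct" (default) or "linear".
#' @return relative expression (> 0), vectorized.
#' @export
qpcr_ratio <- function(ct_target, ct_reference,
                       method = c("delta_ct", "linear")) {
  method <- match.arg(method)
  stopifnot_finite(ct_target, "ct_target")
  stopifnot_finite(ct_reference, "ct_reference")
  if (method == "delta_ct") 2^(ct_reference - ct_target)
  else 2^(-ct_target) / 2^(-ct_reference)
}

#' Wilcoxon-Mann-Whitney rank-sum test (exact for small samples)
#'
#' Two-sided test comparing two independent samples. For combined sizes up
#' to `exact_max` the p-value is exact: all assignments of the pooled
#' mid-ranks to the two groups are enumerated and the two-sided p is the
#' probability of a rank-sum deviation from its mean at least as large as
#' observed. Larger samples use the normal approximation with continuity
#' and tie corrections.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param exact_max combined-size cutoff for exact enumeration
#'   (default 20).
#' @return list with `statistic` (rank-sum W of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))  # mid-ranks for ties
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- abs(w_obs - mu)
    z <- max(0, dev - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation"
  }
  list(statistic = w_obs, p_value = p, method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Companion to [rank_sum_test()] for paired designs; delegates to
#' [stats::wilcox.test()] with `paired = TRUE`.
#'
#' @param x,y paired numeric samples of equal length.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  ht <- stats::wilcox.test(x, y, paired = TRUE, exact = NULL)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Wilcoxon signed rank")
}

#' Spearman rank correlation (exact for small samples)
#'
#' The coefficient is the Pearson correlation of mid-ranks. For `n <=
#' exact_max` the two-sided p-value is exact by enumerating all
#' permutations of one margin's ranks; larger n uses the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))` with df `n-2`.
#'
#' @param x,y numeric vectors (n >= 3); constant vectors leave rho
#'   undefined (NA, flagged in `method`).
#' @param exact_max exact-enumeration cutoff (default 8).
#' @return list with `rho`, `p_value`, `method`.
#' @export
spearman_corr <- function(x, y, exact_max = 8L) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need vectors of equal length n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_,
                method = "undefined: constant input"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  eps <- sqrt(.Machine$double.eps)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # correlation of rx with every permutation of ry, vectorized
    rxc <- rx - mean(rx)
    rym <- matrix(ry[perms], nrow(perms), n)
    rymc <- rym - mean(ry)
    num <- as.vector(rymc %*% rxc)
    den <- sqrt(sum(rxc^2) * rowSums(rymc^2))
    rho_all <- num / den
    p <- mean(abs(rho_all) >= abs(rho) - eps)
    method <- "exact enumeration"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, method = method)
}
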