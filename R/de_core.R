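# Negative-binomial Wald differential-expression engine:
# protein-coding filter, PCA outlier screen, median-of-ratios size factors,
# method-of-moments dispersion, and a vectorized IRLS NB regression with a
# Wald test on the adiposity coefficient.

#' Restrict a count matrix to protein-coding genes
#'
#' @param counts count matrix (genes x samples).
#' @param coding_list character vector of protein-coding gene symbols.
#' @return the subset of rows whose gene id is in `coding_list`, original
#'   order preserved.
#' @export
filter_protein_coding <- function(counts, coding_list) {
  keep <- rownames(counts) %in% coding_list
  if (!any(keep)) stop("no genes left after protein-coding filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample depth factors estimated as the median, over genes positive in
#' every sample, of the ratio of the sample's count to the gene's geometric
#' mean across samples. Dividing counts by these factors corrects for
#' sequencing depth.
#'
#' @param counts count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in all samples")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
  names(sf) <- colnames(counts)
  sf
}

#' Per-gene negative-binomial dispersion by method of moments
#'
#' On depth-normalized counts `q = counts / sf`, the moment estimator is
#' `alpha_g = max(floor, (var_g - mean_g) / mean_g^2)` under the NB
#' variance function `var = mu + alpha mu^2`. When a grouping factor is
#' supplied, moments are computed within each group and combined with
#' weights `n_k - 1`, so a real between-group expression difference does
#' not inflate the dispersion. An optional shrinkage pulls log-dispersions
#' halfway toward a fitted `a0 + a1/mean` trend.
#'
#' @param counts count matrix.
#' @param sf size factors (default recomputed).
#' @param groups optional factor of length `ncol(counts)`.
#' @param floor lower bound for the estimate (default 1e-8).
#' @param shrink logical; shrink toward a mean-dispersion trend.
#' @return numeric vector of dispersions with attribute `flagged`, the ids
#'   of zero-mean genes forced to the floor.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                groups = NULL, floor = 1e-8,
                                shrink = FALSE) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (floor <= 0) stop("floor must be positive")
  q <- sweep(counts, 2, sf, "/")
  if (is.null(groups)) {
    m <- rowMeans(q)
    v <- apply(q, 1, stats::var)
    raw <- (v - m) / m^2
  } else {
    groups <- as.factor(groups)
    num <- 0; den <- 0
    raw <- 0
    wsum <- 0
    for (lev in levels(groups)) {
      idx <- which(groups == lev)
      if (length(idx) < 2L) next
      mk <- rowMeans(q[, idx, drop = FALSE])
      vk <- apply(q[, idx, drop = FALSE], 1, stats::var)
      ak <- (vk - mk) / mk^2
      w <- length(idx) - 1L
      raw <- raw + w * ifelse(is.finite(ak), ak, 0)
      wsum <- wsum + w
    }
    raw <- raw / wsum
    m <- rowMeans(q)
  }
  zero_mean <- !is.finite(raw) | m == 0
  alpha <- pmax(floor, ifelse(zero_mean, floor, raw))
  if (shrink) {
    ok <- alpha > floor & m > 0
    if (sum(ok) >= 10L) {
      fit <- stats::lm(alpha[ok] ~ I(1 / m[ok]))
      trend <- pmax(floor, fit$coefficients[1] + fit$coefficients[2] / m)
      alpha <- exp((log(alpha) + log(trend)) / 2)
    }
  }
  names(alpha) <- rownames(counts)
  attr(alpha, "flagged") <- rownames(counts)[zero_mean]
  alpha
}

#' PCA-based outlier sample screen
#'
#' Samples are embedded by principal components of `log2(normalized count
#' + 1)` over the most variable genes; a sample is flagged when its
#' coordinate on PC1 or PC2 lies more than `k` MAD-scaled units from the
#' coordinate-wise median.
#'
#' @param counts count matrix (>= 4 samples).
#' @param k robust-z threshold (default 5).
#' @param n_top number of most-variable genes used (default 500; clamped
#'   to the gene count with a warning).
#' @param sf size factors (default recomputed).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
pca_outliers <- function(counts, k = 5, n_top = 500,
                         sf = size_factors(counts)) {
  if (ncol(counts) < 4L) stop("need at least 4 samples")
  x <- log2p1(sweep(counts, 2, sf, "/"))
  if (n_top > nrow(x)) {
    warning("n_top larger than gene count; clamping")
    n_top <- nrow(x)
  }
  v <- apply(x, 1, stats::var)
  x <- x[order(v, decreasing = TRUE)[seq_len(n_top)], , drop = FALSE]
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  flagged <- rep(FALSE, nrow(scores))
  for (j in seq_len(ncol(scores))) {
    med <- stats::median(scores[, j])
    s <- stats::mad(scores[, j])
    if (s == 0) next
    flagged <- flagged | abs(scores[, j] - med) / s > k
  }
  colnames(counts)[flagged]
}

# Vectorized IRLS fit of per-gene NB GLMs with log link, shared design.
# Y: G x n counts; X: n x p design; offset: length-n log size factors;
# alpha: length-G dispersions. Returns beta, se (natural-log scale), and a
# convergence flag per gene.
#' @keywords internal
nb_fit_genes <- function(Y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  alpha <- rep_len(alpha, G)
  tri <- do.call(rbind, lapply(seq_len(p), function(i) cbind(i, i:p)))
  XX <- X[, tri[, 1], drop = FALSE] * X[, tri[, 2], drop = FALSE]  # n x p(p+1)/2

  beta <- matrix(0, G, p)
  beta[, 1] <- log(pmax(rowMeans(sweep(Y, 2, exp(offset), "/")), 1e-8))
  eta_lin <- beta %*% t(X)                       # G x n, without offset
  off <- matrix(offset, G, n, byrow = TRUE)
  dev_old <- rep(Inf, G)
  converged <- rep(FALSE, G)
  A_last <- NULL
  for (it in seq_len(max_iter)) {
    eta_lin <- pmin(pmax(eta_lin, -30), 30)
    mu <- exp(eta_lin + off)
    mu <- pmax(mu, 1e-10)
    W <- mu / (1 + alpha * mu)
    Z <- eta_lin + (Y - mu) / mu
    active <- which(!converged)
    if (!length(active)) break
    A <- W %*% XX                                 # G x p(p+1)/2
    B <- (W * Z) %*% X                            # G x p
    sol <- solve_sym_batch(A, B, p)
    beta_new <- sol$x
    bad <- !is.finite(rowSums(beta_new))
    beta_new[bad, ] <- beta[bad, ]
    beta <- beta_new
    eta_lin <- beta %*% t(X)
    mu_new <- pmax(exp(pmin(pmax(eta_lin, -30), 30) + off), 1e-10)
    dev <- nb_deviance(Y, mu_new, alpha)
    newly <- abs(dev - dev_old) / (abs(dev) + 0.1) < tol
    converged <- converged | (newly & !bad)
    dev_old <- dev
    A_last <- A
  }
  # standard errors from the final weighted information matrix
  mu <- pmax(exp(pmin(pmax(eta_lin, -30), 30) + off), 1e-10)
  W <- mu / (1 + alpha * mu)
  A <- W %*% XX
  sol <- solve_sym_batch(A, beta, p)  # reuse for diag of inverse
  se <- sqrt(pmax(sol$diag_inv, 0))
  list(beta = beta, se = se, converged = converged)
}

#' @keywords internal
nb_deviance <- function(Y, mu, alpha) {
  alpha <- rep_len(alpha, nrow(Y))
  t1 <- Y * log(ifelse(Y > 0, Y / mu, 1))
  am <- alpha * mu
  ay <- alpha * Y
  t2 <- (Y + 1 / alpha) * log((1 + ay) / (1 + am))
  2 * rowSums(t1 - t2)
}

#' Negative-binomial Wald differential expression within one stratum
#'
#' Within one maternal BMI stratum, neonatal adiposity (HA vs LA) is
#' modeled as a binary factor adjusted for child sex, through per-gene NB
#' regressions with a log link and `log(size factor)` offsets. The
#' coefficient design is (intercept, adiposity HA=1, sex M=1;
#' female-reference coding). The reported `log2fc` is the adiposity
#' coefficient divided by `ln 2`, `wald_stat` its z statistic, and
#' `p_value` the two-sided normal tail. Genes whose fit does not converge
#' carry `converged = FALSE` and should be treated as non-significant.
#'
#' @param counts count matrix.
#' @param metadata data.frame with `sample_id`, `bmi_category` (or
#'   `maternal_group`), `adiposity_class`, `sex`.
#' @param stratum "LE" or "OB".
#' @param sf optional precomputed size factors for the stratum samples.
#' @param alpha optional precomputed per-gene dispersions.
#' @param tol IRLS deviance-change convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return data.frame with `gene_id`, `log2fc`, `se` (log2 scale),
#'   `wald_stat`, `p_value`, `converged`.
#' @export
nb_wald_de <- function(counts, metadata, stratum = c("LE", "OB"),
                       sf = NULL, alpha = NULL, tol = 1e-8,
                       max_iter = 100L) {
  stratum <- match.arg(stratum)
  md <- de_design_frame(metadata)
  md <- md[md$maternal_group == stratum &
             md$adiposity_class %in% c("LA", "HA"), , drop = FALSE]
  md <- md[md$sample_id %in% colnames(counts), , drop = FALSE]
  if (!all(c("LA", "HA") %in% md$adiposity_class))
    stop("stratum must contain both LA and HA samples")
  Y <- counts[, md$sample_id, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(Y)
  adip <- as.numeric(md$adiposity_class == "HA")
  sex <- as.numeric(md$sex == "M")
  X <- cbind(intercept = 1, adiposity = adip)
  if (length(unique(sex)) > 1L) {
    X <- cbind(X, sex = sex)
  } else {
    warning("single sex level in stratum; dropping sex covariate")
  }
  if (is.null(alpha))
    alpha <- estimate_dispersion(Y, sf, groups = md$adiposity_class)
  fit <- nb_fit_genes(Y, X, log(sf), alpha, tol = tol, max_iter = max_iter)
  b <- fit$beta[, 2]
  se <- fit$se[, 2]
  z <- b / se
  data.frame(gene_id = rownames(counts),
             log2fc = b / log(2),
             se = se / log(2),
             wald_stat = z,
             p_value = ifelse(fit$converged, 2 * stats::pnorm(-abs(z)),
                              NA_real_),
             converged = fit$converged,
             stringsAsFactors = FALSE)
}

# Normalize metadata column naming: accept maternal_group or bmi_category.
#' @keywords internal
de_design_frame <- function(metadata) {
  md <- as.data.frame(metadata)
  if (!"maternal_group" %in% names(md)) {
    if ("bmi_category" %in% names(md)) md$maternal_group <- md$bmi_category
    else stop("metadata needs maternal_group or bmi_category")
  }
  need <- c("sample_id", "maternal_group", "adiposity_class", "sex")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing: ", paste(miss, collapse = ", "))
  md
}
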