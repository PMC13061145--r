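# Interaction-network mapping: STRING-style edge lists, coexpression
# confirmation, hub calling, and a permutation interaction-enrichment test.

#' Load a STRING-format edge list
#'
#' Reads a 3-column TSV (`node1`, `node2`, `combined_score`; header
#' optional), drops edges below `score_min`, canonicalizes endpoint order
#' (`gene_a < gene_b`), removes self-loops, and deduplicates (keeping the
#' maximum score for repeated pairs).
#'
#' @param path TSV path.
#' @param score_min minimum combined score retained (default 400,
#'   medium confidence).
#' @return data.frame with `gene_a`, `gene_b`, `combined_score`.
#' @export
load_string_edges <- function(path, score_min = 400) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(parts) && suppressWarnings(is.na(as.numeric(parts[[1]][3]))))
    start <- 2L  # header row
  rows <- parts[seq(start, length(parts))]
  bad <- which(lengths(rows) < 3L |
                 vapply(rows, function(r)
                   suppressWarnings(is.na(as.numeric(r[3]))), logical(1)))
  if (length(bad))
    stop("malformed edge rows at lines: ",
         paste(bad + start - 1L, collapse = ", "))
  df <- data.frame(
    node1 = vapply(rows, `[[`, character(1), 1L),
    node2 = vapply(rows, `[[`, character(1), 2L),
    combined_score = vapply(rows, function(r) as.numeric(r[3]), numeric(1)),
    stringsAsFactors = FALSE)
  canonicalize_edges(df, score_min)
}

#' @keywords internal
canonicalize_edges <- function(df, score_min = 0) {
  df <- df[df$combined_score >= score_min, , drop = FALSE]
  a <- pmin(df$node1, df$node2)
  b <- pmax(df$node1, df$node2)
  keep <- a != b
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    combined_score = df$combined_score[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    key <- paste(out$gene_a, out$gene_b, sep = "\r")
    out <- out[order(key, -out$combined_score), , drop = FALSE]
    out <- out[!duplicated(paste(out$gene_a, out$gene_b, sep = "\r")), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Confirm interaction edges by expression correlation
#'
#' For each edge, computes the Pearson correlation of the two genes'
#' `log2(normalized count + 1)` expression across the selected samples and
#' its two-sided p-value (`t = r sqrt(n-2) / sqrt(1-r^2)`, df `n-2`). An
#' edge is confirmed when `|r| > r_thr` and `p < p_thr`; unconfirmed edges
#' are retained for context. Zero-variance genes leave `r` undefined and
#' the edge unconfirmed (flagged via NA correlation).
#'
#' @param edges data.frame with `gene_a`, `gene_b` (and optionally
#'   `combined_score`); both endpoints must be rows of `counts`.
#' @param counts count matrix.
#' @param metadata optional sample metadata; with `group` selects the
#'   samples of one maternal stratum.
#' @param group "LE", "OB", or NULL for all samples of `counts` (pooled).
#' @param r_thr absolute-correlation threshold (default 0.3).
#' @param p_thr p-value threshold (default .05).
#' @param sf size factors for the selected samples (default recomputed).
#' @return `edges` with `pearson_r`, `pearson_p`, `confirmed` appended.
#' @export
confirm_edges <- function(edges, counts, metadata = NULL, group = NULL,
                          r_thr = 0.3, p_thr = 0.05, sf = NULL) {
  check_thresholds(p_thr = p_thr, r_thr = r_thr)
  if (!is.null(group)) {
    md <- de_design_frame(metadata)
    ids <- md$sample_id[md$maternal_group == group]
    counts <- counts[, colnames(counts) %in% ids, drop = FALSE]
  }
  if (ncol(counts) < 3L) stop("need at least 3 samples for correlation")
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)),
                     rownames(counts))
  if (length(missing))
    stop("edge endpoints absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log2p1(sweep(counts, 2, sf, "/"))
  n <- ncol(x)
  r <- numeric(nrow(edges)); p <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    xa <- x[edges$gene_a[i], ]; xb <- x[edges$gene_b[i], ]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      r[i] <- NA_real_; p[i] <- NA_real_
    } else {
      ct <- stats::cor.test(xa, xb, method = "pearson")
      r[i] <- unname(ct$estimate); p[i] <- ct$p.value
    }
  }
  edges$pearson_r <- r
  edges$pearson_p <- p
  edges$confirmed <- !is.na(r) & abs(r) > r_thr & p < p_thr
  edges
}

#' Node degrees of an edge list
#'
#' @param edges data.frame with `gene_a`, `gene_b`.
#' @param nodes optional node universe; nodes without edges get degree 0.
#' @return named integer vector of degrees.
#' @export
node_degrees <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  stats::setNames(as.integer(deg), nodes)
}

#' Hub genes by degree quantile
#'
#' Hubs are nodes whose degree strictly exceeds the empirical `q`-quantile
#' of the degree distribution (linear interpolation of order statistics).
#'
#' @param degrees named numeric vector of node degrees.
#' @param q quantile (default 0.90).
#' @return character vector of hub node names (possibly empty).
#' @export
hub_genes <- function(degrees, q = 0.90) {
  if (!length(degrees)) stop("empty graph")
  check_thresholds(hub_q = q)
  thr <- stats::quantile(degrees, q, type = 7, names = FALSE)
  names(degrees)[degrees > thr]
}

#' Permutation test of interaction enrichment
#'
#' Tests whether a gene set induces more interactions than same-size
#' random gene sets. The observed statistic is the number of background
#' edges with both endpoints in the set; the null draws `M` uniform
#' same-size gene sets from the universe; the p-value is
#' `(1 + #{null >= observed}) / (M + 1)`.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param background_edges data.frame with `gene_a`, `gene_b`.
#' @param universe character vector of candidate genes.
#' @param M number of permutations (>= 100; default 999).
#' @param seed integer seed.
#' @return list with `observed`, `null_mean`, `p_value`, `M`.
#' @export
ppi_enrichment <- function(gene_set, background_edges, universe, M = 999L,
                           seed = 1L) {
  if (M < 100L) stop("M must be >= 100")
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (length(gene_set) > length(universe))
    stop("gene_set larger than universe")
  count_induced <- function(s) {
    sum(background_edges$gene_a %in% s & background_edges$gene_b %in% s)
  }
  observed <- count_induced(gene_set)
  set.seed(seed)
  null <- vapply(seq_len(M), function(i)
    count_induced(sample(universe, length(gene_set))), numeric(1))
  list(observed = observed,
       null_mean = mean(null),
       p_value = (1 + sum(null >= observed)) / (M + 1),
       M = M)
}

#' Confirmed-edge percentage
#'
#' @param n_confirmed number of correlation-confirmed edges.
#' @param n_edges total number of edges (> 0).
#' @return percentage rounded to one decimal.
#' @export
confirmed_fraction <- function(n_confirmed, n_edges) {
  if (n_edges <= 0) stop("no edges")
  if (n_confirmed > n_edges) stop("n_confirmed exceeds n_edges")
  round(100 * n_confirmed / n_edges, 1)
}

#' Summarize an annotated network
#'
#' @param annotated_edges output of [confirm_edges()].
#' @param hub_q hub degree quantile (default 0.9).
#' @param nodes optional node universe for degree computation.
#' @return list with `degrees`, `hubs`, `n_edges`, `n_confirmed`,
#'   `confirmed_pct`.
#' @export
network_summary <- function(annotated_edges, hub_q = 0.9, nodes = NULL) {
  deg <- node_degrees(annotated_edges, nodes)
  n_edges <- nrow(annotated_edges)
  n_conf <- sum(annotated_edges$confirmed, na.rm = TRUE)
  list(degrees = deg,
       hubs = hub_genes(deg, hub_q),
       n_edges = n_edges,
       n_confirmed = n_conf,
       confirmed_pct = if (n_edges > 0) confirmed_fraction(n_conf, n_edges)
                       else NA_real_)
}
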