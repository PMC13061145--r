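# CNAAG derivation, unique NAAG sets, and gene-set over-representation.

#' Derive common neonatal adiposity-associated genes (CNAAGs)
#'
#' Intersects the NAAG sets of the lean and obese strata by gene id and
#' classifies each shared gene as concordant (same direction in both
#' strata) or discordant (opposite directions).
#'
#' @param naags_le,naags_ob data.frames with `gene_id` and `direction`
#'   ("up"/"down"), e.g. from [select_naags()].
#' @return data.frame sorted by gene id with `gene_id`, `direction_le`,
#'   `direction_ob`, `concordance`.
#' @export
derive_cnaags <- function(naags_le, naags_ob) {
  shared <- sort(intersect(naags_le$gene_id, naags_ob$gene_id))
  dl <- naags_le$direction[match(shared, naags_le$gene_id)]
  dob <- naags_ob$direction[match(shared, naags_ob$gene_id)]
  data.frame(gene_id = shared,
             direction_le = dl,
             direction_ob = dob,
             concordance = ifelse(dl == dob, "concordant", "discordant"),
             stringsAsFactors = FALSE)
}

#' Stratum-unique NAAG sets
#'
#' @inheritParams derive_cnaags
#' @return list with sorted character vectors `le_only` and `ob_only`;
#'   together with the CNAAGs these partition the union of the two NAAG
#'   sets.
#' @export
unique_naags <- function(naags_le, naags_ob) {
  list(le_only = sort(setdiff(naags_le$gene_id, naags_ob$gene_id)),
       ob_only = sort(setdiff(naags_ob$gene_id, naags_le$gene_id)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis (hypergeometric ORA)
#'
#' For each gene set, tests whether the query over-represents the set
#' relative to the universe with the one-sided hypergeometric tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (`N` universe size, `K`
#' set size within the universe, `n` query size, `k` overlap), then
#' applies Benjamini-Hochberg adjustment across tested terms.
#'
#' @param query character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of background genes.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the universe, and sets
#'   with no universe members are dropped.
#' @param fdr_thr significance threshold on the adjusted p (default 0.1).
#' @return data.frame sorted by p with `term_id`, `k`, `K`, `n`, `N`,
#'   `p_hypergeometric`, `fdr_bh`, `significant`.
#' @export
go_enrichment <- function(query, universe, gene_sets, fdr_thr = 0.1) {
  check_thresholds(fdr_thr = fdr_thr)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  members <- lapply(gene_sets, intersect, universe)
  keep <- lengths(members) > 0L
  members <- members[keep]
  if (!length(members))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      p_hypergeometric = numeric(), fdr_bh = numeric(),
                      significant = logical()))
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- bh_adjust(p)
  out <- data.frame(term_id = names(members), k = k, K = K, n = n, N = N,
                    p_hypergeometric = p, fdr_bh = fdr,
                    significant = fdr < fdr_thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_hypergeometric, out$term_id), , drop = FALSE]
}
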