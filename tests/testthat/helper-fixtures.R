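# Shared fixtures and independent oracles for the test suite.

# small, fast simulation configuration for smoke-level checks
small_config <- function(seed = 1L, ...) {
  simulation_config(n_per_group = c(10L, 10L, 10L, 10L),
                    n_genes = 120L,
                    n_shared_concordant = 6L, n_shared_discordant = 6L,
                    n_le_unique = 6L, n_ob_unique = 6L,
                    seed = seed, ...)
}

# balanced two-stratum design frame without anthropometrics
toy_metadata <- function(n_per_class = 6L, strata = c("LE", "OB")) {
  rows <- lapply(strata, function(st) {
    n <- 2L * n_per_class
    data.frame(sample_id = sprintf("%s%02d", st, seq_len(n)),
               maternal_group = st,
               adiposity_class = rep(c("LA", "HA"), each = n_per_class),
               sex = rep(c("F", "M"), length.out = n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# deterministic count matrix with a known mean ratio between classes
toy_counts <- function(md, means_la, means_ha) {
  G <- length(means_la)
  vals <- vapply(seq_len(nrow(md)), function(j) {
    if (md$adiposity_class[j] == "HA") means_ha else means_la
  }, numeric(G))
  count_matrix(matrix(vals, G, nrow(md)),
               sprintf("g%02d", seq_len(G)), md$sample_id)
}

# independent permutation generator (iterative next-permutation), used as
# the enumeration oracle for rank statistics
oracle_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  p <- seq_len(n)
  for (row in seq_len(nrow(out))) {
    out[row, ] <- p
    # next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
  }
  out
}

# brute-force hypergeometric upper tail by enumerating all draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- draws <= K  # genes 1..K form the set
  mean(colSums(in_set) >= k)
}
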