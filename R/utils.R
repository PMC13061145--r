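# Internal helpers shared across modules.

#' @keywords internal
log2p1 <- function(x) log2(x + 1)

# Vectorized solve of G symmetric positive-definite 2x2 / 3x3 systems.
# A is G x p(p+1)/2 (upper-triangle packing), b is G x p.
# Returns list(x = G x p solution, diag_inv = G x p diagonal of A^{-1}).
solve_sym_batch <- function(A, b, p) {
  if (p == 1L) {
    x <- b / A[, 1L]
    return(list(x = cbind(x), diag_inv = cbind(1 / A[, 1L])))
  }
  if (p == 2L) {
    a11 <- A[, 1L]; a12 <- A[, 2L]; a22 <- A[, 3L]
    det <- a11 * a22 - a12 * a12
    x1 <- (a22 * b[, 1L] - a12 * b[, 2L]) / det
    x2 <- (a11 * b[, 2L] - a12 * b[, 1L]) / det
    return(list(x = cbind(x1, x2),
                diag_inv = cbind(a22 / det, a11 / det)))
  }
  if (p == 3L) {
    a11 <- A[, 1L]; a12 <- A[, 2L]; a13 <- A[, 3L]
    a22 <- A[, 4L]; a23 <- A[, 5L]; a33 <- A[, 6L]
    # cofactors of the symmetric matrix
    c11 <- a22 * a33 - a23 * a23
    c12 <- a13 * a23 - a12 * a33
    c13 <- a12 * a23 - a13 * a22
    c22 <- a11 * a33 - a13 * a13
    c23 <- a12 * a13 - a11 * a23
    c33 <- a11 * a22 - a12 * a12
    det <- a11 * c11 + a12 * c12 + a13 * c13
    x1 <- (c11 * b[, 1L] + c12 * b[, 2L] + c13 * b[, 3L]) / det
    x2 <- (c12 * b[, 1L] + c22 * b[, 2L] + c23 * b[, 3L]) / det
    x3 <- (c13 * b[, 1L] + c23 * b[, 2L] + c33 * b[, 3L]) / det
    return(list(x = cbind(x1, x2, x3),
                diag_inv = cbind(c11 / det, c22 / det, c33 / det)))
  }
  # generic fallback: loop with base solve()
  G <- nrow(A)
  x <- matrix(NA_real_, G, p)
  dinv <- matrix(NA_real_, G, p)
  tri <- do.call(rbind, lapply(seq_len(p), function(i) cbind(i, i:p)))
  for (g in seq_len(G)) {
    M <- matrix(0, p, p)
    M[tri] <- A[g, ]
    M <- M + t(M) - diag(diag(M))
    Mi <- try(solve(M), silent = TRUE)
    if (!inherits(Mi, "try-error")) {
      x[g, ] <- Mi %*% b[g, ]
      dinv[g, ] <- diag(Mi)
    }
  }
  list(x = x, diag_inv = dinv)
}

# All permutations of 1..n as an n! x n integer matrix (n small).
#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' @keywords internal
stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}
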