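#' First-order proximity matrix
#'
#' Symmetrizes the weighted adjacency matrix: an entry is nonzero iff an
#' edge exists in either direction. For asymmetric weights the elementwise
#' maximum is used (the logical OR for binary graphs).
#'
#' @param g A `grn` object.
#' @return Symmetric nonnegative n x n matrix.
#' @export
first_order_proximity <- function(g) {
  pmax(g$A, t(g$A))
}

#' Second-order in-degree proximity matrix
#'
#' `A_S_in(i, j) = sum_k A[k,i] A[k,j] / sum_v A[k,v]`: nodes are similar
#' when they share regulators, each shared regulator's contribution being
#' normalized by its total out-weight. Regulator rows with zero out-weight
#' contribute nothing (0/0 taken as 0). Entries are 0 exactly where two
#' nodes share no regulator.
#'
#' @param g A `grn` object.
#' @return Symmetric nonnegative n x n matrix.
#' @export
second_order_in <- function(g) {
  A <- g$A
  r <- rowSums(A)
  B <- A / ifelse(r > 0, r, 1)
  B[r == 0, ] <- 0
  M <- crossprod(A, B)           # t(A) %*% D_out^{-1} %*% A
  (M + t(M)) / 2                 # exact symmetry against rounding
}

#' Second-order out-degree proximity matrix
#'
#' `A_S_out(i, j) = sum_k A[i,k] A[j,k] / sum_v A[v,k]`: nodes are similar
#' when they regulate common targets, normalized by the target's total
#' in-weight. Target columns with zero in-weight contribute nothing.
#'
#' @param g A `grn` object.
#' @return Symmetric nonnegative n x n matrix.
#' @export
second_order_out <- function(g) {
  A <- g$A
  cs <- colSums(A)
  B <- sweep(A, 2, ifelse(cs > 0, cs, 1), "/")
  B[, cs == 0] <- 0
  M <- tcrossprod(B, A)          # A %*% D_in^{-1} %*% t(A)
  (M + t(M)) / 2
}

#' Symmetric normalization with self-loops
#'
#' Computes `D^{-1/2} (M + I) D^{-1/2}` where `D` is the diagonal of row
#' sums of `M + I` — the spectral-convolution propagation matrix. Row sums
#' are at least 1 after the self-loop, so the operation is always defined;
#' the largest eigenvalue of the result is 1.
#'
#' @param M Symmetric nonnegative matrix.
#' @return Symmetric matrix with strictly positive diagonal.
#' @export
normalize_self_loop <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  At <- M + diag(nrow(M))
  s <- 1 / sqrt(rowSums(At))
  out <- At * outer(s, s)
  (out + t(out)) / 2
}

#' All proximity matrices of a directed network
#'
#' Builds the first-order and the two second-order proximity matrices and
#' their normalized-with-self-loop companions used by the directed graph
#' convolution.
#'
#' @param g A `grn` object.
#' @return List of class `proximity_matrices` with elements `A_F`, `A_S_in`,
#'   `A_S_out`, `P_F`, `P_S_in`, `P_S_out` (the `P_*` are normalized).
#' @export
proximity_matrices <- function(g) {
  A_F <- first_order_proximity(g)
  A_S_in <- second_order_in(g)
  A_S_out <- second_order_out(g)
  structure(list(
    A_F = A_F, A_S_in = A_S_in, A_S_out = A_S_out,
    P_F = normalize_self_loop(A_F),
    P_S_in = normalize_self_loop(A_S_in),
    P_S_out = normalize_self_loop(A_S_out)
  ), class = "proximity_matrices")
}
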