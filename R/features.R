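# Node feature assembly. The feature matrix is a column-block concatenation
# [expression | physicochemical | sequence-hidden | augmented]; a block
# descriptor records which columns belong to which source so blocks can be
# swapped per epoch (sequence-hidden) or toggled by ablation flags.

standardize_rows <- function(M) {
  mu <- rowMeans(M)
  s <- apply(M, 1, sd)
  s[s < 1e-12] <- 1
  (M - mu) / s
}

standardize_cols <- function(M) {
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  s[s < 1e-12] <- 1
  sweep(sweep(M, 2, mu), 2, s, "/")
}

#' Assemble a node feature matrix from blocks
#'
#' @param expression Genes x samples matrix (standardized per gene here).
#' @param physchem Optional genes x 25 descriptor matrix (standardized per
#'   column).
#' @param seq_hidden Optional genes x seq_dim Bi-GRU feature matrix (used
#'   as produced; it is trained jointly).
#' @param augmented Optional genes x d_gen generated feature matrix.
#' @return List of class `node_features`: `X` (the matrix) and `blocks`
#'   (named list of column index vectors).
#' @export
assemble_features <- function(expression, physchem = NULL, seq_hidden = NULL,
                              augmented = NULL) {
  parts <- list(expression = standardize_rows(expression))
  if (!is.null(physchem)) parts$physchem <- standardize_cols(physchem)
  if (!is.null(seq_hidden)) parts$seq_hidden <- seq_hidden
  if (!is.null(augmented)) parts$augmented <- augmented
  widths <- vapply(parts, ncol, integer(1))
  ends <- cumsum(widths)
  blocks <- purrr::map2(ends - widths + 1L, ends, seq.int)
  names(blocks) <- names(parts)
  X <- do.call(cbind, parts)
  colnames(X) <- NULL
  if (any(!is.finite(X))) abort("non-finite entries in assembled features")
  structure(list(X = X, blocks = blocks), class = "node_features")
}
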