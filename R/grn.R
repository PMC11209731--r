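#' Construct a directed gene regulatory network
#'
#' A `grn` object stores an ordered node set and a nonnegative weighted
#' adjacency matrix `A`, with `A[i, j]` the weight of the directed edge
#' from node `i` (regulator) to node `j` (target). The diagonal is zero on
#' construction; self-loops enter only during spectral normalization.
#'
#' @param edges Tibble/data frame with columns `source`, `target` and
#'   optionally `weight` (default 1 for every edge, the unweighted case).
#' @param nodes Optional character vector fixing the node set and order;
#'   defaults to the sorted union of edge endpoints. All edge endpoints must
#'   be contained in `nodes`.
#' @return An object of class `grn` with fields `node_ids` and `A`.
#' @export
grn <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target") %in% names(edges)))
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, nrow(edges))
  if (any(!is.finite(w)) || any(w < 0)) abort("edge weights must be finite and nonnegative")
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$source, edges$target)))
  }
  if (anyDuplicated(nodes)) abort("duplicate node ids")
  missing <- setdiff(c(edges$source, edges$target), nodes)
  if (length(missing) > 0L) {
    abort(paste0("edge endpoints not in node set: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  if (any(edges$source == edges$target)) abort("self-loops are not allowed")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- w
  structure(list(node_ids = nodes, A = A), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d nodes, %d directed edges\n",
              length(x$node_ids), sum(x$A > 0)))
  invisible(x)
}

#' Number of nodes of a network
#' @param g A `grn` object.
#' @return Integer node count.
#' @export
n_nodes <- function(g) length(g$node_ids)

#' Edge table of a network
#'
#' @param g A `grn` object.
#' @return Tibble with `source`, `target`, `weight`, one row per directed
#'   edge, in column-major matrix order.
#' @export
grn_edges <- function(g) {
  idx <- which(g$A > 0, arr.ind = TRUE)
  tibble::tibble(source = g$node_ids[idx[, 1]],
                 target = g$node_ids[idx[, 2]],
                 weight = g$A[idx])
}

#' Replace edge weights of a network
#'
#' Keeps the topology fixed and substitutes new weights for the existing
#' edges, as the dynamic update strategy does during training.
#'
#' @param g A `grn` object.
#' @param weights Numeric vector in edge order of `which(g$A > 0)`
#'   (column-major), or a matrix of identical support.
#' @return A `grn` with the same edge set and new weights.
#' @export
set_edge_weights <- function(g, weights) {
  idx <- which(g$A > 0)
  if (is.matrix(weights)) weights <- weights[idx]
  if (length(weights) != length(idx)) abort("one weight per existing edge required")
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights >= 1)) {
    abort("dynamic edge weights must lie strictly in (0, 1)")
  }
  g$A[idx] <- weights
  g
}
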