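# Directed graph convolutional network. Each layer runs one spectral
# convolution per proximity branch (first-order, second-order-in,
# second-order-out), fuses the branches by concatenation with scalar mixing
# weights and a rectifier, and a two-layer feed-forward head scores ordered
# node pairs. Gradients are hand-derived; see the gradient-check tests.

#' Initialize DGCN parameters
#'
#' @param d_in Input feature width.
#' @param hidden1 Per-branch width of the first convolution (default 32).
#' @param hidden2 Per-branch width of the second convolution (default 16).
#' @param head_hidden Hidden width of the edge-scoring head (default 64).
#' @param share_theta Tie the branch weight matrices within each layer.
#' @param alpha,beta Mixing weights of the second-order in/out branches
#'   (default 1; 0 disables a branch, the undirected-GCN ablation).
#' @return Parameter list of class `dgcn_params`.
#' @export
dgcn_init <- function(d_in, hidden1 = 32L, hidden2 = 16L, head_hidden = 64L,
                      share_theta = FALSE, alpha = 1, beta = 1) {
  layer <- function(din, dout) {
    th <- list(F = glorot(din, dout), S_in = glorot(din, dout),
               S_out = glorot(din, dout))
    if (share_theta) th$S_in <- th$S_out <- th$F
    th
  }
  d_emb <- 3L * hidden2
  structure(list(
    layer1 = layer(d_in, hidden1),
    layer2 = layer(3L * hidden1, hidden2),
    head = list(W1 = glorot(2L * d_emb, head_hidden), b1 = rep(0, head_hidden),
                w2 = glorot(head_hidden, 1L), b2 = 0),
    share_theta = share_theta, alpha = alpha, beta = beta,
    dims = list(d_in = d_in, hidden1 = hidden1, hidden2 = hidden2,
                head_hidden = head_hidden)
  ), class = "dgcn_params")
}

#' One directed graph convolution layer
#'
#' `Z_b = P_b X Theta_b` for each branch b, where `P_b` is the normalized
#' self-looped proximity matrix. Linear: no activation inside.
#'
#' @param X n x d_in feature matrix.
#' @param P A `proximity_matrices` object.
#' @param theta List with branch weight matrices `F`, `S_in`, `S_out`.
#' @return List of branch embeddings `Z_F`, `Z_S_in`, `Z_S_out`.
#' @export
dgcn_layer <- function(X, P, theta) {
  if (nrow(theta$F) != ncol(X)) abort("feature width does not match Theta")
  list(Z_F = P$P_F %*% X %*% theta$F,
       Z_S_in = P$P_S_in %*% X %*% theta$S_in,
       Z_S_out = P$P_S_out %*% X %*% theta$S_out)
}

#' Fuse branch embeddings
#'
#' Column-wise concatenation `[Z_F || alpha Z_S_in || beta Z_S_out]`
#' followed by elementwise rectification.
#'
#' @param Z Branch embeddings from [dgcn_layer()].
#' @param alpha,beta Nonnegative mixing scalars.
#' @return n x (3 d_out) matrix.
#' @export
fuse_branches <- function(Z, alpha = 1, beta = 1) {
  relu(cbind(Z$Z_F, alpha * Z$Z_S_in, beta * Z$Z_S_out))
}

#' Score ordered node pairs from embeddings
#'
#' Ordered concatenation of the two embeddings through a two-layer
#' feed-forward map and a logistic squashing; directional, so
#' `score(i, j)` need not equal `score(j, i)`.
#'
#' @param head Head parameter list (`W1`, `b1`, `w2`, `b2`).
#' @param H n x d embedding matrix.
#' @param pairs Two-column integer matrix of (source, target) row indices.
#' @return Numeric vector of scores strictly inside (0, 1).
#' @export
score_edges <- function(head, H, pairs) {
  U <- cbind(H[pairs[, 1], , drop = FALSE], H[pairs[, 2], , drop = FALSE])
  R1 <- relu(addb(U %*% head$W1, head$b1))
  as.vector(sigmoid(R1 %*% head$w2 + head$b2))
}

# Full forward pass. pairs: integer matrix m x 2. dropout_mask: NULL or the
# scaled keep mask for the first fused layer (supplied by the trainer so
# that the RNG stream stays under its control).
dgcn_forward <- function(params, P, X, pairs, dropout_mask = NULL) {
  a <- params$alpha; b <- params$beta
  M1 <- list(F = P$P_F %*% X, S_in = P$P_S_in %*% X, S_out = P$P_S_out %*% X)
  H1pre <- cbind(M1$F %*% params$layer1$F,
                 a * (M1$S_in %*% params$layer1$S_in),
                 b * (M1$S_out %*% params$layer1$S_out))
  H1 <- relu(H1pre)
  H1d <- if (is.null(dropout_mask)) H1 else H1 * dropout_mask
  M2 <- list(F = P$P_F %*% H1d, S_in = P$P_S_in %*% H1d,
             S_out = P$P_S_out %*% H1d)
  H2pre <- cbind(M2$F %*% params$layer2$F,
                 a * (M2$S_in %*% params$layer2$S_in),
                 b * (M2$S_out %*% params$layer2$S_out))
  H2 <- relu(H2pre)
  U <- cbind(H2[pairs[, 1], , drop = FALSE], H2[pairs[, 2], , drop = FALSE])
  A1 <- addb(U %*% params$head$W1, params$head$b1)
  R1 <- relu(A1)
  logits <- as.vector(R1 %*% params$head$w2 + params$head$b2)
  if (any(!is.finite(logits))) abort("non-finite values in forward pass")
  list(scores = sigmoid(logits), logits = logits,
       cache = list(X = X, M1 = M1, H1pre = H1pre, H1 = H1, H1d = H1d,
                    dropout_mask = dropout_mask, M2 = M2, H2pre = H2pre,
                    H2 = H2, U = U, A1 = A1, R1 = R1, pairs = pairs))
}

# Backward pass for mean binary cross-entropy over the scored pairs.
# Returns gradients with the params nesting plus dX for upstream feature
# encoders (the Bi-GRU block).
dgcn_backward <- function(params, P, cache, scores, labels) {
  m <- length(scores)
  a <- params$alpha; b <- params$beta
  h1 <- ncol(params$layer1$F); h2 <- ncol(params$layer2$F)
  n <- nrow(cache$X)
  dlogit <- (scores - labels) / m
  head <- params$head
  gw2 <- crossprod(cache$R1, dlogit)
  gb2 <- sum(dlogit)
  dR1 <- outer(dlogit, as.vector(head$w2))
  dA1 <- dR1 * (cache$A1 > 0)
  gW1 <- crossprod(cache$U, dA1)
  gb1 <- colSums(dA1)
  dU <- dA1 %*% t(head$W1)
  D <- ncol(cache$H2)
  dH2 <- matrix(0, n, D)
  contrib <- rbind(dU[, seq_len(D), drop = FALSE],
                   dU[, D + seq_len(D), drop = FALSE])
  agg <- rowsum(contrib, group = c(cache$pairs[, 1], cache$pairs[, 2]))
  rows <- as.integer(rownames(agg))
  dH2[rows, ] <- agg
  dH2pre <- dH2 * (cache$H2pre > 0)
  dZ2 <- list(F = dH2pre[, seq_len(h2), drop = FALSE],
              S_in = a * dH2pre[, h2 + seq_len(h2), drop = FALSE],
              S_out = b * dH2pre[, 2 * h2 + seq_len(h2), drop = FALSE])
  g2 <- list(F = crossprod(cache$M2$F, dZ2$F),
             S_in = crossprod(cache$M2$S_in, dZ2$S_in),
             S_out = crossprod(cache$M2$S_out, dZ2$S_out))
  dH1d <- P$P_F %*% (dZ2$F %*% t(params$layer2$F)) +
    P$P_S_in %*% (dZ2$S_in %*% t(params$layer2$S_in)) +
    P$P_S_out %*% (dZ2$S_out %*% t(params$layer2$S_out))
  dH1 <- if (is.null(cache$dropout_mask)) dH1d else dH1d * cache$dropout_mask
  dH1pre <- dH1 * (cache$H1pre > 0)
  dZ1 <- list(F = dH1pre[, seq_len(h1), drop = FALSE],
              S_in = a * dH1pre[, h1 + seq_len(h1), drop = FALSE],
              S_out = b * dH1pre[, 2 * h1 + seq_len(h1), drop = FALSE])
  g1 <- list(F = crossprod(cache$M1$F, dZ1$F),
             S_in = crossprod(cache$M1$S_in, dZ1$S_in),
             S_out = crossprod(cache$M1$S_out, dZ1$S_out))
  dX <- P$P_F %*% (dZ1$F %*% t(params$layer1$F)) +
    P$P_S_in %*% (dZ1$S_in %*% t(params$layer1$S_in)) +
    P$P_S_out %*% (dZ1$S_out %*% t(params$layer1$S_out))
  if (params$share_theta) {
    g1 <- tie_grads(g1); g2 <- tie_grads(g2)
  }
  list(layer1 = g1, layer2 = g2,
       head = list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2),
       dX = dX)
}

tie_grads <- function(g) {
  s <- g$F + g$S_in + g$S_out
  list(F = s, S_in = s, S_out = s)
}

# mean binary cross-entropy with clipped probabilities
bce_loss <- function(scores, labels) {
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
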