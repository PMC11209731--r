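tiny_proximity <- function(n) {
  # identity propagation: edgeless graph
  g <- structure(list(node_ids = sprintf("N%d", seq_len(n)),
                      A = matrix(0, n, n)), class = "grn")
  proximity_matrices(g)
}

test_that("a layer with identity weights on an edgeless graph is the identity", {
  P <- tiny_proximity(3)
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  theta <- list(F = diag(2), S_in = diag(2), S_out = diag(2))
  Z <- dgcn_layer(X, P, theta)
  expect_equal(Z$Z_F, X)
  expect_equal(Z$Z_S_in, X)
})

test_that("layer output matches hand evaluation on a two-node complete graph", {
  g <- grn(tibble::tibble(source = c("N1", "N2"), target = c("N2", "N1")),
           nodes = c("N1", "N2"))
  P <- proximity_matrices(g)
  X <- matrix(c(1, 3), 2, 1)
  Z <- dgcn_layer(X, P, list(F = matrix(1), S_in = matrix(1),
                             S_out = matrix(1)))
  expect_equal(unname(Z$Z_F), matrix(c(2, 2), 2, 1))  # [[.5,.5],[.5,.5]] %*% [1,3]
})

test_that("the layer map is linear in the features", {
  set.seed(31)
  g <- random_digraph(6, p = 0.4)
  P <- proximity_matrices(g)
  theta <- list(F = dgcgrn:::glorot(3, 2), S_in = dgcgrn:::glorot(3, 2), S_out = dgcgrn:::glorot(3, 2))
  X1 <- matrix(rnorm(18), 6, 3)
  X2 <- matrix(rnorm(18), 6, 3)
  Zs <- dgcn_layer(X1 + X2, P, theta)
  Za <- dgcn_layer(X1, P, theta)
  Zb <- dgcn_layer(X2, P, theta)
  expect_equal(Zs$Z_F, Za$Z_F + Zb$Z_F)
  expect_equal(Zs$Z_S_in, Za$Z_S_in + Zb$Z_S_in)
})

test_that("fusion concatenates with mixing weights and rectifies", {
  Z <- list(Z_F = matrix(1, 2, 2), Z_S_in = matrix(-1, 2, 2),
            Z_S_out = matrix(2, 2, 2))
  H0 <- fuse_branches(Z, alpha = 0, beta = 0)
  expect_equal(ncol(H0), 6L)
  expect_true(all(H0[, 3:6] == 0))
  Hn <- fuse_branches(list(Z_F = matrix(-1, 2, 2), Z_S_in = matrix(-2, 2, 2),
                           Z_S_out = matrix(-3, 2, 2)), 1, 1)
  expect_true(all(Hn == 0))
})

test_that("edge head is directional, bounded, and 0.5 at zero weights", {
  set.seed(32)
  H <- matrix(rnorm(12), 4, 3)
  zero_head <- list(W1 = matrix(0, 6, 5), b1 = rep(0, 5),
                    w2 = matrix(0, 5, 1), b2 = 0)
  s0 <- score_edges(zero_head, H, cbind(1:2, 3:4))
  expect_equal(s0, c(0.5, 0.5))
  head <- list(W1 = dgcgrn:::glorot(6, 5), b1 = rnorm(5), w2 = dgcgrn:::glorot(5, 1), b2 = 0.3)
  s_ij <- score_edges(head, H, cbind(1, 2))
  s_ji <- score_edges(head, H, cbind(2, 1))
  expect_false(isTRUE(all.equal(s_ij, s_ji)))
  s <- score_edges(head, H * 10, cbind(1:3, c(2, 3, 4)))
  expect_true(all(s > 0 & s < 1))
})

test_that("full forward is deterministic and permutation-equivariant", {
  set.seed(33)
  g <- random_digraph(6, p = 0.4)
  P <- proximity_matrices(g)
  X <- matrix(rnorm(6 * 4), 6, 4)
  params <- dgcn_init(4, hidden1 = 3, hidden2 = 2, head_hidden = 5)
  pairs <- cbind(c(1, 2, 5), c(3, 6, 4))
  f1 <- dgcgrn:::dgcn_forward(params, P, X, pairs)
  f2 <- dgcgrn:::dgcn_forward(params, P, X, pairs)
  expect_identical(f1$scores, f2$scores)

  perm <- sample(6)
  gp <- g; gp$A <- g$A[perm, perm]
  Pp <- proximity_matrices(gp)
  inv <- order(perm)
  fp <- dgcgrn:::dgcn_forward(params, Pp, X[perm, , drop = FALSE],
                     cbind(inv[pairs[, 1]], inv[pairs[, 2]]))
  expect_equal(fp$scores, f1$scores, tolerance = 1e-10)
})

test_that("analytic DGCN gradients match finite differences", {
  set.seed(34)
  g <- random_digraph(5, p = 0.4, weighted = TRUE)
  P <- proximity_matrices(g)
  X <- matrix(rnorm(5 * 3), 5, 3)
  params <- dgcn_init(3, hidden1 = 2, hidden2 = 2, head_hidden = 4,
                      alpha = 0.8, beta = 1.2)
  pairs <- cbind(c(1, 2, 4, 3), c(2, 5, 1, 4))
  labels <- c(1, 0, 1, 0)
  trainable <- params[c("layer1", "layer2", "head")]
  loss_fn <- function(tr) {
    p <- params
    p[c("layer1", "layer2", "head")] <- tr
    fw <- dgcgrn:::dgcn_forward(p, P, X, pairs)
    dgcgrn:::bce_loss(fw$scores, labels)
  }
  fw <- dgcgrn:::dgcn_forward(params, P, X, pairs)
  gr <- dgcgrn:::dgcn_backward(params, P, fw$cache, fw$scores, labels)
  num <- numeric_grad(trainable, loss_fn)
  expect_lt(max_abs_diff(gr[c("layer1", "layer2", "head")], num), 1e-6)

  # feature gradient (the path into the sequence encoder)
  num_dX <- matrix(0, 5, 3)
  eps <- 1e-6
  for (i in 1:5) for (j in 1:3) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + eps
    Xm <- X; Xm[i, j] <- Xm[i, j] - eps
    num_dX[i, j] <- (dgcgrn:::bce_loss(dgcgrn:::dgcn_forward(params, P, Xp, pairs)$scores, labels) -
                     dgcgrn:::bce_loss(dgcgrn:::dgcn_forward(params, P, Xm, pairs)$scores, labels)) / (2 * eps)
  }
  expect_lt(max(abs(gr$dX - num_dX)), 1e-6)
})

test_that("shared-theta keeps branch weights tied through training updates", {
  params <- dgcn_init(3, hidden1 = 2, hidden2 = 2, share_theta = TRUE)
  expect_identical(params$layer1$F, params$layer1$S_in)
  g <- random_digraph(5, p = 0.5)
  P <- proximity_matrices(g)
  X <- matrix(rnorm(15), 5, 3)
  pairs <- cbind(c(1, 2), c(3, 4))
  fw <- dgcgrn:::dgcn_forward(params, P, X, pairs)
  gr <- dgcgrn:::dgcn_backward(params, P, fw$cache, fw$scores, c(1, 0))
  expect_identical(gr$layer1$F, gr$layer1$S_in)
  expect_identical(gr$layer2$F, gr$layer2$S_out)
})
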