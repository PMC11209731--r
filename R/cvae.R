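# Conditional VAE for local feature augmentation. The encoder sees a
# (neighbor, center) feature pair and produces a latent Gaussian; the
# decoder reconstructs the neighbor's (dimension-reduced) features from the
# latent sample and the center's features. At generation time z ~ N(0, I)
# plus the center's features yield one synthetic neighbor-like vector per
# node, appended to the node feature matrix to support low-degree nodes.

#' Collect (neighbor, center) index pairs for CVAE training
#'
#' Neighborhoods ignore edge direction: every adjacency contributes two
#' pairs, each endpoint serving once as the center. Isolated nodes
#' contribute none.
#'
#' @param g A `grn` object.
#' @return Tibble with integer columns `u` (neighbor) and `v` (center).
#' @export
collect_pairs <- function(g) {
  und <- which(pmax(g$A, t(g$A)) > 0 & upper.tri(g$A), arr.ind = TRUE)
  if (nrow(und) == 0L) {
    return(tibble::tibble(u = integer(0), v = integer(0)))
  }
  tibble::tibble(u = c(und[, 1], und[, 2]), v = c(und[, 2], und[, 1]))
}

#' Closed-form KL divergence of a diagonal Gaussian from N(0, I)
#'
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)` per row.
#'
#' @param mu Matrix (or vector) of means.
#' @param logvar Matrix (or vector) of log-variances.
#' @return Numeric vector of per-row KL values (nonnegative).
#' @export
kl_gaussian <- function(mu, logvar) {
  mu <- rbind(mu); logvar <- rbind(logvar)
  unname(0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar))
}

#' CVAE loss for one reconstruction
#'
#' Squared-error reconstruction term plus the closed-form KL term.
#'
#' @param x_target Target feature vector.
#' @param x_recon Decoder output.
#' @param mu,logvar Encoder outputs.
#' @return Nonnegative scalar.
#' @export
cvae_loss <- function(x_target, x_recon, mu, logvar) {
  sum((x_target - x_recon)^2) + sum(kl_gaussian(mu, logvar))
}

cvae_init <- function(d_in, d_cond, d_gen, latent = 16L, hidden = 64L) {
  list(enc = list(W1 = glorot(d_in + d_cond, hidden), b1 = rep(0, hidden),
                  Wmu = glorot(hidden, latent), bmu = rep(0, latent),
                  Wlv = glorot(hidden, latent), blv = rep(0, latent)),
       dec = list(V1 = glorot(latent + d_cond, hidden), c1 = rep(0, hidden),
                  V2 = glorot(hidden, d_gen), c2 = rep(0, d_gen)),
       dims = list(d_in = d_in, d_cond = d_cond, d_gen = d_gen,
                   latent = latent, hidden = hidden))
}

cvae_forward <- function(params, Xu, Xv, target, eps) {
  enc <- params$enc; dec <- params$dec
  inp <- cbind(Xu, Xv)
  a1 <- addb(inp %*% enc$W1, enc$b1)
  h1 <- relu(a1)
  mu <- addb(h1 %*% enc$Wmu, enc$bmu)
  lv <- pmin(pmax(addb(h1 %*% enc$Wlv, enc$blv), -8), 8)
  z <- mu + exp(lv / 2) * eps
  zin <- cbind(z, Xv)
  a2 <- addb(zin %*% dec$V1, dec$c1)
  h2 <- relu(a2)
  out <- addb(h2 %*% dec$V2, dec$c2)
  recon <- rowSums((out - target)^2)
  kl <- kl_gaussian(mu, lv)
  list(loss = mean(recon + kl), out = out,
       cache = list(inp = inp, h1 = h1, mu = mu, lv = lv, z = z, eps = eps,
                    zin = zin, h2 = h2, out = out, target = target))
}

cvae_backward <- function(params, cache) {
  enc <- params$enc; dec <- params$dec
  m <- nrow(cache$inp)
  L <- ncol(cache$mu)
  dout <- 2 * (cache$out - cache$target) / m
  gV2 <- crossprod(cache$h2, dout); gc2 <- colSums(dout)
  da2 <- (dout %*% t(dec$V2)) * (cache$h2 > 0)
  gV1 <- crossprod(cache$zin, da2); gc1 <- colSums(da2)
  dzin <- da2 %*% t(dec$V1)
  dz <- dzin[, seq_len(L), drop = FALSE]
  dmu <- dz + cache$mu / m
  dlv <- dz * cache$eps * 0.5 * exp(cache$lv / 2) +
    0.5 * (exp(cache$lv) - 1) / m
  gWmu <- crossprod(cache$h1, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(cache$h1, dlv); gblv <- colSums(dlv)
  da1 <- (dmu %*% t(enc$Wmu) + dlv %*% t(enc$Wlv)) * (cache$h1 > 0)
  gW1 <- crossprod(cache$inp, da1); gb1 <- colSums(da1)
  list(enc = list(W1 = gW1, b1 = gb1, Wmu = gWmu, bmu = gbmu,
                  Wlv = gWlv, blv = gblv),
       dec = list(V1 = gV1, c1 = gc1, V2 = gV2, c2 = gc2),
       dims = rapply(params$dims, function(x) 0, how = "replace"))
}

#' Train the CVAE on (neighbor, center) feature pairs
#'
#' Full-batch Adam on the evidence bound (squared-error reconstruction +
#' KL). Deterministic given the seed, which drives initialization and the
#' per-epoch reparameterization noise.
#'
#' @param x_neighbor m x d matrix of neighbor features (encoder input).
#' @param x_center m x d_cond matrix of center features (condition).
#' @param target m x d_gen matrix of reconstruction targets.
#' @param latent Latent dimension (default 16).
#' @param hidden Hidden-layer width (default 64).
#' @param epochs Training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed.
#' @return List of class `cvae`: parameters plus a `loss` trace.
#' @export
train_cvae <- function(x_neighbor, x_center, target, latent = 16L,
                       hidden = 64L, epochs = 200L, lr = 1e-3, seed = 1L) {
  if (nrow(x_neighbor) == 0L) abort("CVAE training needs at least one pair")
  stopifnot(nrow(x_neighbor) == nrow(x_center),
            nrow(x_neighbor) == nrow(target))
  set.seed(seed)
  params <- cvae_init(ncol(x_neighbor), ncol(x_center), ncol(target),
                      latent = latent, hidden = hidden)
  opt <- adam_init(params)
  trace <- numeric(epochs)
  m <- nrow(x_neighbor)
  for (e in seq_len(epochs)) {
    eps <- matrix(rnorm(m * latent), m, latent)
    fw <- cvae_forward(params, x_neighbor, x_center, target, eps)
    trace[e] <- fw$loss
    if (!is.finite(fw$loss)) abort("CVAE loss became non-finite")
    gr <- cvae_backward(params, fw$cache)
    st <- adam_step(params, gr, opt, lr = lr)
    params <- st$params
    params$dims <- purrr::map(params$dims, as.integer)
    opt <- st$state
  }
  params$loss <- trace
  class(params) <- "cvae"
  params
}

#' Generate one augmented feature vector per node
#'
#' Draws `z ~ N(0, I)` once per node and decodes it together with the
#' node's own features, yielding the generated block that is appended to
#' the node feature matrix.
#'
#' @param params A trained `cvae`.
#' @param x_center n x d_cond matrix of node features (condition).
#' @param seed Integer seed for the latent draws.
#' @return n x d_gen matrix of generated features.
#' @export
generate_augmented <- function(params, x_center, seed = 1L) {
  set.seed(seed)
  n <- nrow(x_center)
  L <- params$dims$latent
  z <- matrix(rnorm(n * L), n, L)
  dec <- params$dec
  h2 <- relu(addb(cbind(z, x_center) %*% dec$V1, dec$c1))
  out <- addb(h2 %*% dec$V2, dec$c2)
  rownames(out) <- rownames(x_center)
  out
}

# Unit-variance principal-component scores used as CVAE reconstruction
# targets when the generated width differs from the raw feature width.
pca_targets <- function(X, d_gen) {
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  q <- min(d_gen, ncol(p$x))
  sc <- p$x[, seq_len(q), drop = FALSE]
  sds <- apply(sc, 2, sd)
  sds[sds < 1e-12] <- 1
  sc <- sweep(sc, 2, sds, "/")
  if (q < d_gen) sc <- cbind(sc, matrix(0, nrow(sc), d_gen - q))
  sc
}

#' Local augmentation of a node feature matrix
#'
#' Trains the CVAE on the (neighbor, center) pairs of the graph and
#' generates one feature vector per node. Reconstruction targets are the
#' neighbors' features projected on the leading principal components when
#' the generated width differs from the input width.
#'
#' @param g A `grn` object (typically the training graph).
#' @param X n x d base feature matrix, rows aligned with `g$node_ids`.
#' @param d_gen Generated feature width (default 50).
#' @param latent,hidden,epochs,lr Passed to [train_cvae()].
#' @param seed Integer seed.
#' @return List: `augmented` (n x d_gen matrix), `cvae` (trained model),
#'   `pairs` (the index tibble used).
#' @export
augment_features <- function(g, X, d_gen = 50L, latent = 16L, hidden = 64L,
                             epochs = 200L, lr = 1e-3, seed = 1L) {
  pairs <- collect_pairs(g)
  if (nrow(pairs) == 0L) abort("graph has no edges; nothing to augment from")
  targets <- pca_targets(X, d_gen)
  fit <- train_cvae(X[pairs$u, , drop = FALSE], X[pairs$v, , drop = FALSE],
                    targets[pairs$u, , drop = FALSE],
                    latent = latent, hidden = hidden, epochs = epochs,
                    lr = lr, seed = seed)
  aug <- generate_augmented(fit, X, seed = seed + 1L)
  list(augmented = aug, cvae = fit, pairs = pairs)
}
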