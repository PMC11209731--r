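# Independent oracle implementations and shared fixtures. The oracles are
# written as plain loops over definitions, deliberately avoiding the
# vectorized code paths they check.

# ---- sequence descriptor oracles (pure counting, position loops) ---------

oracle_base_counts <- function(seq) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nchar(seq))) {
    ch <- substr(seq, i, i)
    if (ch %in% names(counts)) counts[ch] <- counts[ch] + 1
  }
  counts
}

oracle_z_curve <- function(seq) {
  ct <- oracle_base_counts(seq)
  n <- sum(ct)
  c(((ct["A"] + ct["G"]) - (ct["C"] + ct["T"])) / n,
    ((ct["A"] + ct["C"]) - (ct["T"] + ct["G"])) / n,
    ((ct["A"] + ct["T"]) - (ct["C"] + ct["G"])) / n)
}

oracle_gc <- function(seq) {
  ct <- oracle_base_counts(seq)
  (ct["G"] + ct["C"]) / sum(ct)
}

oracle_atgc <- function(seq) {
  ct <- oracle_base_counts(seq)
  den <- ct["G"] + ct["C"]
  if (den == 0) (ct["A"] + ct["T"]) / (den + 1) else (ct["A"] + ct["T"]) / den
}

oracle_nac <- function(seq) {
  ct <- oracle_base_counts(seq)
  ct / sum(ct)
}

oracle_cksnap0 <- function(seq) {
  pairs <- dinucleotide_order()
  counts <- setNames(rep(0, 16), pairs)
  total <- 0
  for (i in seq_len(nchar(seq) - 1)) {
    p <- substr(seq, i, i + 1)
    if (p %in% pairs) {
      counts[p] <- counts[p] + 1
      total <- total + 1
    }
  }
  counts / total
}

random_seq <- function(len, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# ---- proximity oracles (naive triple loops) ------------------------------

oracle_second_order_in <- function(A) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) {
      rk <- sum(A[k, ])
      if (rk > 0) s <- s + A[k, i] * A[k, j] / rk
    }
    M[i, j] <- s
  }
  M
}

oracle_second_order_out <- function(A) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) {
      ck <- sum(A[, k])
      if (ck > 0) s <- s + A[i, k] * A[j, k] / ck
    }
    M[i, j] <- s
  }
  M
}

random_digraph <- function(n, p = 0.25, weighted = FALSE) {
  A <- matrix((runif(n * n) < p) * 1, n, n)
  diag(A) <- 0
  if (weighted) A <- A * matrix(runif(n * n, 0.2, 2), n, n)
  nodes <- sprintf("N%02d", seq_len(n))
  dimnames(A) <- list(nodes, nodes)
  structure(list(node_ids = nodes, A = A), class = "grn")
}

# ---- metric oracle --------------------------------------------------------

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# ---- numerical gradients --------------------------------------------------

# finite-difference gradient of scalar_fn over every numeric leaf of params
numeric_grad <- function(params, scalar_fn, eps = 1e-6) {
  flat <- unlist(params)
  g <- numeric(length(flat))
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    g[i] <- (scalar_fn(utils::relist(up, params)) -
               scalar_fn(utils::relist(dn, params))) / (2 * eps)
  }
  utils::relist(g, params)
}

max_abs_diff <- function(a, b) max(abs(unlist(a) - unlist(b)))

# ---- small synthetic dataset for fast pipeline tests ---------------------

small_dataset <- function(seed = 42L) {
  synthetic_dataset(synthetic_config(
    n_genes = 30L, n_samples = 40L, edge_density = 45 / (30 * 29),
    seq_length = c(60L, 100L), seed = seed))
}

fast_config <- function(...) {
  dgcgrn_config(epochs = 15L, cvae_epochs = 40L, warmup = 5L,
                repeats = 1L, folds = 3L, ...)
}
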