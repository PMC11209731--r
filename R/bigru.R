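# Bidirectional GRU encoder over k-mer token sequences, with hand-derived
# backpropagation-through-time so it can be trained jointly with the
# link-prediction loss. One-hot k-mer encoding is realized as an embedding
# lookup over the 4^k + 1 vocabulary (identical to one-hot times a matrix).

#' Tokenize sequences into k-mer identifier vectors
#'
#' Maps each overlapping k-mer to an integer in `1..4^k` (base-4 encoding of
#' A/C/G/T); k-mers containing N map to the unknown token `4^k + 1`.
#'
#' @param sequences Named character vector of sequences.
#' @param k K-mer length (default 5).
#' @return List of class `kmer_tokens`: `token_ids` (list of integer
#'   vectors), `k`, `vocab_size` (`4^k + 1`).
#' @export
kmer_tokens <- function(sequences, k = 5L) {
  vocab <- 4L^k + 1L
  ids <- purrr::map(sequences, function(s) {
    km <- kmerize(s, k)
    if (length(km) == 0L) return(integer(0))
    digits <- chartr("ACGT", "0123", km)
    v <- suppressWarnings(strtoi(digits, base = 4L)) + 1L
    v[is.na(v)] <- vocab              # k-mers containing N
    v
  })
  structure(list(token_ids = ids, k = k, vocab_size = vocab),
            class = "kmer_tokens")
}

#' Pad token sequences to a common length
#'
#' Truncates or right-pads (pad id 0) to `max_len`; by default the 95th
#' percentile of observed token counts, so a few very long genes do not
#' inflate every batch.
#'
#' @param tokens A `kmer_tokens` object.
#' @param max_len Target length; `NULL` for the 95th-percentile rule.
#' @return List with `ids` (n x max_len integer matrix), `mask` (n x max_len
#'   0/1 matrix), `lengths`, `vocab_size`.
#' @export
pad_tokens <- function(tokens, max_len = NULL) {
  lens <- lengths(tokens$token_ids)
  if (is.null(max_len)) {
    max_len <- max(1L, ceiling(stats::quantile(lens, 0.95, names = FALSE)))
  }
  n <- length(tokens$token_ids)
  ids <- matrix(0L, n, max_len)
  for (i in seq_len(n)) {
    v <- tokens$token_ids[[i]]
    if (length(v) > 0L) {
      keep <- min(length(v), max_len)
      ids[i, seq_len(keep)] <- v[seq_len(keep)]
    }
  }
  rownames(ids) <- names(tokens$token_ids)
  list(ids = ids, mask = (ids > 0L) * 1, lengths = pmin(lens, max_len),
       vocab_size = tokens$vocab_size)
}

#' Initialize Bi-GRU encoder parameters
#'
#' @param vocab_size Token vocabulary size (4^k + 1).
#' @param embed_dim Embedding width per token (default 16).
#' @param hidden_dim Hidden units per direction (default 32).
#' @param out_dim Projected sequence-feature width (default 60).
#' @return Nested parameter list (embedding, forward/backward GRU cells,
#'   output projection).
#' @export
bigru_init <- function(vocab_size, embed_dim = 16L, hidden_dim = 32L,
                       out_dim = 60L) {
  cell <- function() {
    s <- 1 / sqrt(hidden_dim)
    list(Wr = uniform_init(embed_dim, hidden_dim, s),
         Wz = uniform_init(embed_dim, hidden_dim, s),
         Wn = uniform_init(embed_dim, hidden_dim, s),
         Ur = uniform_init(hidden_dim, hidden_dim, s),
         Uz = uniform_init(hidden_dim, hidden_dim, s),
         Un = uniform_init(hidden_dim, hidden_dim, s),
         br = rep(0, hidden_dim), bz = rep(0, hidden_dim),
         bn = rep(0, hidden_dim))
  }
  list(E = matrix(rnorm(vocab_size * embed_dim, sd = 0.1), vocab_size),
       fwd = cell(), bwd = cell(),
       Wp = glorot(2L * hidden_dim, out_dim), bp = rep(0, out_dim))
}

addb <- function(M, b) M + rep(b, each = nrow(M))

# One direction of the GRU over a padded batch. reverse=TRUE walks each row
# from its own end (tokens are reversed within the valid prefix). The
# embedding lookup and input-side gate pre-activations are batched over all
# timesteps in one matrix product; the recursion itself runs in compiled
# code (src/gru.cpp).
gru_direction <- function(cell, E, ids, mask, reverse = FALSE) {
  if (reverse) {
    for (i in seq_len(nrow(ids))) {
      len <- sum(mask[i, ])
      if (len > 1L) ids[i, seq_len(len)] <- ids[i, rev(seq_len(len))]
    }
  }
  idx_all <- as.vector(ids)                # column-major: step t = rows (t-1)B+1..tB
  EW <- E %*% cbind(cell$Wr, cell$Wz, cell$Wn)   # vocab-sized, gathered per token
  xW <- EW[pmax(idx_all, 1L), , drop = FALSE]
  xW[idx_all == 0L, ] <- 0
  fw <- .gru_fwd_cpp(xW, c(cell$br, cell$bz, cell$bn), mask,
                     cell$Ur, cell$Uz, cell$Un)
  fw$idx_all <- idx_all
  fw$mask <- mask
  fw
}

gru_direction_backward <- function(cell, E, fw, dh) {
  bw <- .gru_bwd_cpp(fw$mask, cell$Ur, cell$Uz, cell$Un,
                     fw$R, fw$Z, fw$N, fw$Hprev, dh)
  H <- ncol(dh)
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  # aggregate gate gradients by token: pad rows are zero by masking
  agg <- rowsum(bw$DA, group = fw$idx_all)
  rows <- as.integer(rownames(agg))
  if (length(rows) > 0L && rows[1] == 0L) {
    agg <- agg[-1L, , drop = FALSE]
    rows <- rows[-1L]
  }
  gW <- crossprod(E[rows, , drop = FALSE], agg)
  gb <- colSums(agg)
  g <- list(Wr = gW[, ir, drop = FALSE], Wz = gW[, iz, drop = FALSE],
            Wn = gW[, inn, drop = FALSE],
            Ur = bw$gUr, Uz = bw$gUz, Un = bw$gUn,
            br = gb[ir], bz = gb[iz], bn = gb[inn])
  dE <- matrix(0, nrow(E), ncol(E))
  dE[rows, ] <- agg %*% t(cbind(cell$Wr, cell$Wz, cell$Wn))
  list(grads = g, dE = dE)
}

#' Encode sequences with the Bi-GRU
#'
#' Runs forward and backward GRU passes over the padded token batch,
#' concatenates the two final hidden states and projects them linearly to
#' the output width. Rows with no tokens (sequence shorter than k) yield a
#' zero vector, with a warning.
#'
#' @param params Parameters from [bigru_init()].
#' @param padded Padded batch from [pad_tokens()].
#' @param keep_cache Keep the intermediate state needed by
#'   [bigru_backward()].
#' @return When `keep_cache = FALSE`, the n x out_dim feature matrix.
#'   Otherwise a list `(S, cache)`.
#' @export
bigru_encode <- function(params, padded, keep_cache = FALSE) {
  fw <- gru_direction(params$fwd, params$E, padded$ids, padded$mask)
  bw <- gru_direction(params$bwd, params$E, padded$ids, padded$mask,
                      reverse = TRUE)
  Hc <- cbind(fw$h, bw$h)
  S <- addb(Hc %*% params$Wp, params$bp)
  empty <- padded$lengths == 0L
  if (any(empty)) {
    warn(sprintf("%d sequence(s) shorter than k yield zero feature vectors",
                 sum(empty)))
    S[empty, ] <- 0
  }
  rownames(S) <- rownames(padded$ids)
  if (!keep_cache) return(S)
  list(S = S, cache = list(fw = fw, bw = bw, Hc = Hc, empty = empty,
                           padded = padded))
}

#' Backpropagate through the Bi-GRU encoder
#'
#' @param params Parameters from [bigru_init()].
#' @param cache Cache returned by `bigru_encode(..., keep_cache = TRUE)`.
#' @param dS Gradient of the loss with respect to the encoder output.
#' @return Parameter-gradient list with the same nesting as `params`.
#' @export
bigru_backward <- function(params, cache, dS) {
  if (any(cache$empty)) dS[cache$empty, ] <- 0
  H <- ncol(cache$fw$h)
  gWp <- crossprod(cache$Hc, dS)
  gbp <- colSums(dS)
  dHc <- dS %*% t(params$Wp)
  bf <- gru_direction_backward(params$fwd, params$E, cache$fw,
                               dHc[, seq_len(H), drop = FALSE])
  bb <- gru_direction_backward(params$bwd, params$E, cache$bw,
                               dHc[, H + seq_len(H), drop = FALSE])
  list(E = bf$dE + bb$dE, fwd = bf$grads, bwd = bb$grads, Wp = gWp, bp = gbp)
}
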