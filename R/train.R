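# Training: negative sampling, the fit loop with the dynamic edge-weight
# update, cross-validation and the ablation harness.

pair_key <- function(i, j, n) (as.numeric(i) - 1) * n + as.numeric(j)

#' Sample negative (non-edge) ordered pairs
#'
#' Uniform over ordered pairs (i, j), i != j, that are not in the excluded
#' positive set. Reversed positives are eligible negatives by default,
#' since regulation is directional.
#'
#' @param n_nodes Number of nodes.
#' @param positives Two-column integer matrix of positive (source, target)
#'   index pairs to exclude.
#' @param n_neg Number of negatives to draw.
#' @param seed Integer seed.
#' @param allow_reverse If `FALSE`, reversed positives are also excluded.
#' @return `n_neg` x 2 integer matrix.
#' @export
sample_negatives <- function(n_nodes, positives, n_neg, seed = 1L,
                             allow_reverse = TRUE) {
  n <- n_nodes
  banned <- pair_key(positives[, 1], positives[, 2], n)
  if (!allow_reverse) {
    banned <- c(banned, pair_key(positives[, 2], positives[, 1], n))
  }
  banned <- c(banned, pair_key(seq_len(n), seq_len(n), n))  # self-pairs
  avail <- n * (n - 1) - length(unique(banned)) + n
  if (avail < n_neg) abort("not enough non-edges to sample negatives from")
  set.seed(seed)
  chosen <- numeric(0)
  while (length(chosen) < n_neg) {
    cand <- pair_key(sample.int(n, 2 * n_neg, replace = TRUE),
                     sample.int(n, 2 * n_neg, replace = TRUE), n)
    cand <- setdiff(cand, c(banned, chosen))
    chosen <- c(chosen, cand[seq_len(min(length(cand), n_neg - length(chosen)))])
  }
  key <- chosen[seq_len(n_neg)]
  cbind(as.integer((key - 1) %/% n + 1), as.integer((key - 1) %% n + 1))
}

#' Dynamic edge-weight update
#'
#' Replaces the weights of the (fixed) training-graph edge set with the
#' model's current edge probabilities and recomputes the proximity
#' matrices, so the next epoch's message passing is guided by the scores.
#'
#' @param g A `grn` object.
#' @param scores Numeric vector of probabilities in (0, 1), one per edge in
#'   the order of `which(g$A > 0)` (the order of [grn_edges()]).
#' @return List: `g` (reweighted graph), `P` (recomputed
#'   [proximity_matrices()]).
#' @export
dynamic_update <- function(g, scores) {
  g2 <- set_edge_weights(g, scores)
  list(g = g2, P = proximity_matrices(g2))
}

# ---- single fit -----------------------------------------------------------

#' Fit the edge-prediction model on a training graph
#'
#' Trains the directed graph convolutional network (optionally with CVAE
#' augmentation, jointly trained Bi-GRU sequence features and the dynamic
#' update strategy) on the given positive/negative training pairs, with
#' binary cross-entropy and Adam.
#'
#' @param g_train `grn` whose edges are the training positives (message
#'   passing never sees test edges).
#' @param expression Genes x samples matrix, rows aligned with
#'   `g_train$node_ids`.
#' @param train_neg Two-column integer matrix of negative training pairs.
#' @param sequences Named character vector of gene sequences (required when
#'   `config$use_seq`).
#' @param config A [dgcgrn_config()].
#' @param seed Integer seed; the run is a deterministic function of it.
#' @return Object of class `dgcgrn_fit`: final parameters, evaluation-mode
#'   node embeddings, the training log, and the feature block layout.
#' @export
dgcgrn_train <- function(g_train, expression, train_neg, sequences = NULL,
                         config = dgcgrn_config(), seed = 1L) {
  n <- n_nodes(g_train)
  stopifnot(nrow(expression) == n)
  genes <- g_train$node_ids
  use_seq <- isTRUE(config$use_seq) && !is.null(sequences)
  if (isTRUE(config$use_seq) && is.null(sequences)) {
    warn("use_seq is TRUE but no sequences supplied; sequence branch disabled")
  }

  if (!config$use_dgcn) {
    # undirected GCN ablation: symmetrized adjacency, first-order only
    config$alpha <- 0; config$beta <- 0
    g_train$A <- pmax(g_train$A, t(g_train$A))
  }

  phys <- NULL; padded <- NULL
  if (use_seq) {
    seqs <- sequences[genes]
    if (anyNA(names(seqs)) || any(!genes %in% names(sequences))) {
      missing <- setdiff(genes, names(sequences))
      warn(sprintf("%d gene(s) lack sequences; their descriptor block is zero",
                   length(missing)))
      seqs <- setNames(ifelse(genes %in% names(sequences),
                              sequences[genes], NA_character_), genes)
    }
    have <- !is.na(seqs)
    phys <- matrix(0, n, 25)
    if (any(have)) {
      phys[have, ] <- t(vapply(seqs[have], physchem_vector, numeric(25)))
    }
    toks <- kmer_tokens(ifelse(have, seqs, ""), k = config$k)
    names(toks$token_ids) <- genes
    padded <- pad_tokens(toks)
  }

  base <- assemble_features(expression, physchem = phys)

  aug <- NULL; cvae_fit <- NULL
  if (config$use_cvae) {
    la <- augment_features(g_train, base$X, d_gen = config$d_gen,
                           latent = config$cvae_latent,
                           hidden = config$cvae_hidden,
                           epochs = config$cvae_epochs, lr = config$lr,
                           seed = derive_seed(seed, 11L))
    aug <- la$augmented
    cvae_fit <- la$cvae
  }

  set.seed(derive_seed(seed, 23L))
  gru <- if (use_seq) {
    suppressWarnings(bigru_init(padded$vocab_size, config$embed_dim,
                                config$gru_hidden, config$seq_dim))
  } else NULL

  seq_hidden0 <- if (use_seq) {
    suppressWarnings(bigru_encode(gru, padded))
  } else NULL
  feats <- assemble_features(expression, physchem = phys,
                             seq_hidden = seq_hidden0, augmented = aug)
  d_in <- ncol(feats$X)

  params <- dgcn_init(d_in, config$hidden1, config$hidden2,
                      config$head_hidden, share_theta = config$share_theta,
                      alpha = config$alpha, beta = config$beta)
  trainable <- params[c("layer1", "layer2", "head")]
  opt <- adam_init(trainable)
  gru_opt <- if (use_seq) adam_init(gru) else NULL

  edge_idx <- which(g_train$A > 0, arr.ind = TRUE)
  train_pos <- cbind(as.integer(edge_idx[, 1]), as.integer(edge_idx[, 2]))
  pairs <- rbind(train_pos, train_neg)
  labels <- rep(c(1, 0), c(nrow(train_pos), nrow(train_neg)))

  g_cur <- g_train
  P <- proximity_matrices(g_cur)
  log <- tibble::tibble(epoch = integer(0), loss = numeric(0))

  enc <- NULL
  for (epoch in seq_len(config$epochs)) {
    # the Bi-GRU forward/backward pass is refreshed every seq_update_every
    # epochs; between refreshes the cached sequence embeddings are reused
    seq_epoch <- use_seq && (epoch - 1L) %% config$seq_update_every == 0L
    if (seq_epoch) {
      enc <- suppressWarnings(bigru_encode(gru, padded, keep_cache = TRUE))
      feats$X[, feats$blocks$seq_hidden] <- enc$S
    }
    mask <- if (config$dropout > 0) {
      keep <- matrix(stats::rbinom(n * 3L * config$hidden1, 1L,
                                   1 - config$dropout),
                     n, 3L * config$hidden1)
      keep / (1 - config$dropout)
    } else NULL
    fw <- dgcn_forward(params, P, feats$X, pairs, dropout_mask = mask)
    loss <- bce_loss(fw$scores, labels)
    if (!is.finite(loss)) abort("training loss became non-finite")
    log <- dplyr::bind_rows(log, tibble::tibble(epoch = epoch, loss = loss))
    gr <- dgcn_backward(params, P, fw$cache, fw$scores, labels)
    st <- adam_step(trainable, gr[c("layer1", "layer2", "head")], opt,
                    lr = config$lr)
    params[c("layer1", "layer2", "head")] <- st$params
    opt <- st$state
    if (seq_epoch) {
      dS <- gr$dX[, feats$blocks$seq_hidden, drop = FALSE]
      ggru <- bigru_backward(gru, enc$cache, dS)
      stg <- adam_step(gru, ggru, gru_opt, lr = config$lr)
      gru <- stg$params
      gru_opt <- stg$state
    }
    if (config$use_dynamic && epoch > config$warmup) {
      fw_eval <- dgcn_forward(params, P, feats$X, train_pos)
      upd <- dynamic_update(g_cur, pmin(pmax(fw_eval$scores, 1e-6), 1 - 1e-6))
      g_cur <- upd$g
      P <- upd$P
    }
  }

  # evaluation-mode embeddings: no dropout, final parameters
  if (use_seq) {
    feats$X[, feats$blocks$seq_hidden] <-
      suppressWarnings(bigru_encode(gru, padded))
  }
  fw <- dgcn_forward(params, P, feats$X, pairs)
  Z1 <- dgcn_layer(feats$X, P, params$layer1)
  H1 <- fuse_branches(Z1, params$alpha, params$beta)
  Z2 <- dgcn_layer(H1, P, params$layer2)
  H2 <- fuse_branches(Z2, params$alpha, params$beta)
  rownames(H2) <- genes

  structure(list(
    params = params, gru = gru, cvae = cvae_fit,
    embeddings = H2, proximity = P, graph = g_cur,
    blocks = feats$blocks, genes = genes, config = config, seed = seed,
    log = log, final_train_loss = bce_loss(fw$scores, labels)
  ), class = "dgcgrn_fit")
}

#' @export
print.dgcgrn_fit <- function(x, ...) {
  cat(sprintf("<dgcgrn_fit> %d genes, %d epochs, final training loss %.4f\n",
              length(x$genes), nrow(x$log), x$final_train_loss))
  invisible(x)
}

#' Score directed gene pairs with a fitted model
#'
#' @param object A `dgcgrn_fit`.
#' @param pairs Tibble with `source`/`target` gene ids, or a two-column
#'   integer index matrix.
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `score`.
#' @export
predict.dgcgrn_fit <- function(object, pairs, ...) {
  if (is.matrix(pairs)) {
    idx <- pairs
  } else {
    idx <- cbind(match(pairs$source, object$genes),
                 match(pairs$target, object$genes))
    if (anyNA(idx)) abort("pair contains a gene absent from the model")
  }
  s <- score_edges(object$params$head, object$embeddings, idx)
  tibble::tibble(source = object$genes[idx[, 1]],
                 target = object$genes[idx[, 2]], score = s)
}

# ---- cross-validation -----------------------------------------------------

edge_indices <- function(edges, genes) {
  keep <- edges$source %in% genes & edges$target %in% genes
  e <- edges[keep, , drop = FALSE]
  cbind(match(e$source, genes), match(e$target, genes))
}

#' Repeated k-fold cross-validated evaluation
#'
#' Positives are split into `folds` folds per repeat; each fold in turn is
#' held out, the model is trained on a graph containing only the remaining
#' positives, and held-out positives are scored against sampled negatives.
#' Negatives are resampled each repeat (never overlapping any known
#' positive) and split into folds alongside the positives.
#'
#' @param expression Expression tibble ([read_expression_matrix()] layout).
#' @param edges Edge tibble (`source`, `target`, `label`); label-1 rows are
#'   positives. Label-0 rows are used as known test/train negatives when
#'   `config$use_known_negatives` is set, otherwise ignored.
#' @param sequences Optional named character vector of gene sequences.
#' @param config A [dgcgrn_config()].
#' @param seed Integer seed.
#' @return Object of class `dgcgrn_cv`: tibble of per-fold [evaluate_scores()]
#'   rows with `repeat_id`/`fold` columns, plus the config.
#' @export
cross_validate <- function(expression, edges, sequences = NULL,
                           config = dgcgrn_config(), seed = 1L) {
  genes <- expression$gene_id
  values <- expression_values(expression)
  pos <- edge_indices(edges[edges$label == 1L, ], genes)
  if (nrow(pos) < config$folds) abort("too few positive edges for the fold count")
  known_neg <- edge_indices(edges[edges$label == 0L, ], genes)
  n <- length(genes)

  res <- purrr::map_dfr(seq_len(config$repeats), function(rep_id) {
    rs <- derive_seed(seed, 101L, rep_id)
    set.seed(rs)
    fold_of <- sample(rep(seq_len(config$folds), length.out = nrow(pos)))
    n_neg <- ceiling(config$neg_ratio * nrow(pos))
    if (config$use_known_negatives && nrow(known_neg) > 0) {
      extra <- max(0L, n_neg - nrow(known_neg))
      neg <- known_neg
      if (extra > 0) {
        neg <- rbind(neg, sample_negatives(n, rbind(pos, known_neg), extra,
                                           seed = rs + 1L,
                                           allow_reverse = config$allow_reverse))
      }
    } else {
      neg <- sample_negatives(n, pos, n_neg, seed = rs + 1L,
                              allow_reverse = config$allow_reverse)
    }
    set.seed(rs + 2L)
    neg_fold <- sample(rep(seq_len(config$folds), length.out = nrow(neg)))
    purrr::map_dfr(seq_len(config$folds), function(f) {
      train_pos <- pos[fold_of != f, , drop = FALSE]
      test_pos <- pos[fold_of == f, , drop = FALSE]
      train_neg <- neg[neg_fold != f, , drop = FALSE]
      test_neg <- neg[neg_fold == f, , drop = FALSE]
      # structural no-leakage guarantees: disjoint splits, and the training
      # graph below is built from train_pos only
      stopifnot(
        !any(pair_key(test_pos[, 1], test_pos[, 2], n) %in%
               pair_key(train_pos[, 1], train_pos[, 2], n)),
        !any(pair_key(neg[, 1], neg[, 2], n) %in%
               pair_key(pos[, 1], pos[, 2], n)))
      g_train <- grn(tibble::tibble(source = genes[train_pos[, 1]],
                                    target = genes[train_pos[, 2]]),
                     nodes = genes)
      fit <- dgcgrn_train(g_train, values, train_neg, sequences = sequences,
                          config = config, seed = derive_seed(rs, 7L, f))
      if (config$test_negatives == "all") {
        all_pairs <- which(upper.tri(matrix(0, n, n)) |
                             lower.tri(matrix(0, n, n)), arr.ind = TRUE)
        banned <- pair_key(rbind(pos, train_neg)[, 1],
                           rbind(pos, train_neg)[, 2], n)
        keep <- !(pair_key(all_pairs[, 1], all_pairs[, 2], n) %in% banned)
        test_neg <- all_pairs[keep, , drop = FALSE]
      }
      ps <- predict(fit, test_pos)$score
      ns <- predict(fit, test_neg)$score
      dplyr::bind_cols(tibble::tibble(repeat_id = rep_id, fold = f),
                       evaluate_scores(ps, ns, config$threshold))
    })
  })
  structure(list(results = res, config = config, seed = seed),
            class = "dgcgrn_cv")
}

#' @export
print.dgcgrn_cv <- function(x, ...) {
  cat(sprintf("<dgcgrn_cv> %d folds: mean AUROC %.3f (sd %.3f), mean AUPR %.3f\n",
              nrow(x$results), mean(x$results$AUROC), sd(x$results$AUROC),
              mean(x$results$AUPR)))
  invisible(x)
}

# ---- ablation harness -----------------------------------------------------

#' The six standard ablation variants
#'
#' @return Tibble with `variant` and the four `use_*` flags each variant
#'   sets.
#' @export
ablation_variants <- function() {
  tibble::tribble(
    ~variant, ~use_dgcn, ~use_cvae, ~use_seq, ~use_dynamic,
    "E.1",    FALSE,     FALSE,     FALSE,    FALSE,
    "E.2",    TRUE,      FALSE,     FALSE,    FALSE,
    "E.3",    TRUE,      TRUE,      FALSE,    FALSE,
    "E.4",    TRUE,      TRUE,      TRUE,     FALSE,
    "E.5",    TRUE,      TRUE,      FALSE,    TRUE,
    "E.6",    TRUE,      TRUE,      TRUE,     TRUE)
}

#' Ablation harness over model variants
#'
#' Runs cross-validation for the six standard variants — E.1 undirected
#' GCN, E.2 directed convolution, E.3 +CVAE augmentation, E.4 +sequence
#' features, E.5 E.3 + dynamic update, E.6 everything — and reports mean
#' AUROC per variant and seed.
#'
#' @inheritParams cross_validate
#' @param seeds Integer vector of seeds (one cross-validation per seed).
#' @param variants Subset of `c("E.1", ..., "E.6")` to run.
#' @return Object of class `dgcgrn_ablation`: tibble with `variant`,
#'   `seed`, `mean_auroc`, `mean_aupr`.
#' @export
run_ablation <- function(expression, edges, sequences = NULL,
                         config = dgcgrn_config(), seeds = 1:5,
                         variants = ablation_variants()$variant) {
  plan <- ablation_variants()
  plan <- plan[plan$variant %in% variants, ]
  res <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    v <- plan[i, ]
    cfg <- config
    cfg$use_dgcn <- v$use_dgcn; cfg$use_cvae <- v$use_cvae
    cfg$use_seq <- v$use_seq && !is.null(sequences)
    cfg$use_dynamic <- v$use_dynamic
    purrr::map_dfr(seeds, function(s) {
      cv <- cross_validate(expression, edges,
                           sequences = if (cfg$use_seq) sequences else NULL,
                           config = cfg, seed = s)
      tibble::tibble(variant = v$variant, seed = s,
                     mean_auroc = mean(cv$results$AUROC),
                     mean_aupr = mean(cv$results$AUPR))
    })
  })
  structure(list(results = res, config = config), class = "dgcgrn_ablation")
}

#' @export
print.dgcgrn_ablation <- function(x, ...) {
  agg <- dplyr::summarise(dplyr::group_by(x$results, .data$variant),
                          mean_auroc = mean(.data$mean_auroc), .groups = "drop")
  cat("<dgcgrn_ablation>\n")
  print.data.frame(as.data.frame(agg), row.names = FALSE)
  invisible(x)
}
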