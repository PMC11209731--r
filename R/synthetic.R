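# Synthetic benchmark generator: a directed scale-free regulatory graph
# with a planted low-degree fraction, a sigmoidal expression model with
# additive Gaussian noise, and nucleotide sequences whose GC composition
# carries a weak regulator-class signal. Sized after the 100-gene /
# 210-sample / 176-edge benchmark scale.

#' Synthetic benchmark configuration
#'
#' @param ... Named overrides. Fields and defaults: `n_genes = 100`,
#'   `n_samples = 210`, `edge_density = 176/9900` (about 176 edges at 100
#'   genes), `tf_fraction = 0.2`, `lowdegree_fraction = 0.3` (fraction of
#'   genes forced to total degree 1), `noise_sd = 0.3`,
#'   `activation_prob = 0.7` (share of activating edges),
#'   `seq_length = c(150, 300)` (promoter-scale region lengths),
#'   `base_gc = 0.5`, `tf_gc_shift = 0.05` (weak compositional class
#'   signal), `seed = 1`.
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(n_genes = 100L, n_samples = 210L, edge_density = 176 / 9900,
              tf_fraction = 0.2, lowdegree_fraction = 0.3, noise_sd = 0.3,
              activation_prob = 0.7, seq_length = c(150L, 300L),
              base_gc = 0.5, tf_gc_shift = 0.05, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown synthetic_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$n_genes >= 3, cfg$n_samples >= 2, cfg$edge_density > 0,
            cfg$tf_fraction > 0, cfg$tf_fraction < 1,
            cfg$lowdegree_fraction >= 0, cfg$lowdegree_fraction <= 1,
            cfg$noise_sd >= 0, length(cfg$seq_length) == 2,
            cfg$seq_length[1] >= 10, cfg$seq_length[2] >= cfg$seq_length[1],
            cfg$base_gc > 0, cfg$base_gc < 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate a directed scale-free regulatory graph
#'
#' Genes are ordered so that edges always point from a lower to a higher
#' index (a DAG); the first `tf_fraction` of genes are transcription
#' factors and the only allowed sources. Edges attach preferentially to
#' high-out-degree sources and high-in-degree targets. A
#' `lowdegree_fraction` of non-TF genes is forced to total degree 1
#' (exactly one incoming edge).
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_grn`: `g` (a [grn()]), `W` (signed
#'   regulation weight matrix), `tf` (logical vector), `cfg`.
#' @export
generate_digraph <- function(cfg = synthetic_config()) {
  set.seed(derive_seed(cfg$seed, 1L))
  n <- as.integer(cfg$n_genes)
  genes <- sprintf("G%03d", seq_len(n))
  n_tf <- max(1L, round(cfg$tf_fraction * n))
  tf <- seq_len(n) <= n_tf
  m <- round(cfg$edge_density * n * (n - 1))
  n_low <- floor(cfg$lowdegree_fraction * n)
  if (n_low > n - n_tf) abort("lowdegree_fraction exceeds the non-TF pool")
  if (m < n_low || m > n_tf * (n - 1) - n_tf * (n_tf - 1) / 2) {
    abort("infeasible edge density for this gene/TF configuration")
  }
  low <- sort(sample((n_tf + 1L):n, n_low))
  A <- matrix(0, n, n)
  outdeg <- rep(0, n); indeg <- rep(0, n)
  # each low-degree gene: exactly one incoming edge from a TF
  for (v in low) {
    src <- sample(n_tf, 1L, prob = outdeg[seq_len(n_tf)] + 1)
    A[src, v] <- 1
    outdeg[src] <- outdeg[src] + 1
  }
  # remaining edges among TFs and non-low targets, source index < target
  targets_ok <- setdiff(seq_len(n), c(low, 1L))
  remaining <- m - n_low
  guard <- 0L
  while (remaining > 0L) {
    src <- sample(n_tf, 1L, prob = outdeg[seq_len(n_tf)] + 1)
    cand <- targets_ok[targets_ok > src]
    if (length(cand) == 0L) next
    tgt <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = indeg[cand] + 1)
    if (A[src, tgt] == 0) {
      A[src, tgt] <- 1
      outdeg[src] <- outdeg[src] + 1
      indeg[tgt] <- indeg[tgt] + 1
      remaining <- remaining - 1L
    } else {
      guard <- guard + 1L
      if (guard > 100000L) abort("edge sampling failed to place all edges")
    }
  }
  idx <- which(A > 0, arr.ind = TRUE)
  sign <- ifelse(runif(nrow(idx)) < cfg$activation_prob, 1, -1)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  W[idx] <- sign * runif(nrow(idx), 0.8, 1.2)
  g <- grn(tibble::tibble(source = genes[idx[, 1]], target = genes[idx[, 2]]),
           nodes = genes)
  structure(list(g = g, W = W, tf = setNames(tf, genes), cfg = cfg),
            class = "synthetic_grn")
}

#' Simulate expression from a regulatory graph
#'
#' Regulator-free genes draw from a standard normal per sample; every other
#' gene is a saturating (logistic, centered) function of the signed
#' weighted sum of its regulators plus Gaussian noise of sd `noise_sd`.
#' Genes are evaluated in topological order, so one sweep suffices.
#'
#' @param net A `synthetic_grn` from [generate_digraph()].
#' @param cfg Optional config override (defaults to `net$cfg`).
#' @return Expression tibble: `gene_id` plus `S1..Sk` numeric columns.
#' @export
simulate_expression <- function(net, cfg = net$cfg) {
  set.seed(derive_seed(cfg$seed, 2L))
  n <- nrow(net$W); S <- as.integer(cfg$n_samples)
  genes <- rownames(net$W)
  X <- matrix(0, n, S)
  has_reg <- colSums(abs(net$W)) > 0
  for (i in seq_len(n)) {
    if (!has_reg[i]) {
      X[i, ] <- rnorm(S)
    } else {
      z <- as.vector(crossprod(net$W[, i, drop = FALSE], X))
      X[i, ] <- (2 / (1 + exp(-z)) - 1) + rnorm(S, sd = cfg$noise_sd)
    }
  }
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   tibble::as_tibble(matrix(X, n, S,
                                            dimnames = list(NULL, paste0("S", seq_len(S))))))
}

sample_sequence <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate gene sequences with a regulator-class composition signal
#'
#' Random sequences with lengths uniform in `seq_length`; transcription
#' factors draw bases from a GC fraction shifted up by `tf_gc_shift`, so
#' composition descriptors carry weak class information.
#'
#' @param net A `synthetic_grn`.
#' @param cfg Optional config override.
#' @return Named character vector of sequences.
#' @export
generate_sequences <- function(net, cfg = net$cfg) {
  set.seed(derive_seed(cfg$seed, 3L))
  genes <- rownames(net$W)
  lens <- sample(seq.int(cfg$seq_length[1], cfg$seq_length[2]),
                 length(genes), replace = TRUE)
  gc <- ifelse(net$tf, cfg$base_gc + cfg$tf_gc_shift, cfg$base_gc)
  setNames(purrr::map2_chr(lens, gc, sample_sequence), genes)
}

#' Point-mutate sequences at a fixed per-site rate
#'
#' Every position is independently substituted with probability `rate`; a
#' substituted base becomes one of the three other bases uniformly.
#'
#' @param sequences Named character vector.
#' @param rate Per-site substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Mutated named character vector.
#' @export
mutate_sequences <- function(sequences, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  purrr::map_chr(sequences, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < rate)
    if (length(hit) > 0L) {
      for (i in hit) {
        chars[i] <- sample(setdiff(bases, chars[i]), 1L)
      }
    }
    paste(chars, collapse = "")
  })
}

#' Generate a complete synthetic benchmark instance
#'
#' @param cfg A [synthetic_config()].
#' @return List: `expression` (tibble), `edges` (tibble with label 1),
#'   `sequences` (named character vector), `net` (the `synthetic_grn`).
#' @export
synthetic_dataset <- function(cfg = synthetic_config()) {
  net <- generate_digraph(cfg)
  expr <- simulate_expression(net)
  seqs <- generate_sequences(net)
  edges <- dplyr::mutate(grn_edges(net$g), label = 1L, weight = NULL)
  list(expression = expr, edges = edges, sequences = seqs, net = net)
}

#' Write a synthetic fixture to disk
#'
#' Writes `expression.tsv`, `goldstandard.tsv`, `sequences.fasta` and
#' `config.yaml` in the dialects the readers of this package expect.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [synthetic_config()].
#' @return Character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(dir, cfg = synthetic_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- synthetic_dataset(cfg)
  paths <- file.path(dir, c("expression.tsv", "goldstandard.tsv",
                            "sequences.fasta", "config.yaml"))
  readr::write_tsv(ds$expression, paths[1], progress = FALSE)
  writeLines(sprintf("%s\t%s\t%d", ds$edges$source, ds$edges$target,
                     ds$edges$label), paths[2])
  write_fasta(ds$sequences, paths[3])
  yaml::write_yaml(unclass(cfg), paths[4])
  invisible(paths)
}
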