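#' Model and training configuration
#'
#' Builds the full configuration with field validation; unknown names are
#' rejected. The ablation harness toggles the `use_*` flags.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `dgcgrn_config`.
#'
#' @details Defaults: `use_dgcn = TRUE` (second-order branches on; `FALSE`
#' gives the undirected first-order GCN), `use_cvae = TRUE`,
#' `use_seq = TRUE` (needs sequences), `use_dynamic = TRUE`,
#' `share_theta = FALSE`, `alpha = 1`, `beta = 1`, `hidden1 = 32`,
#' `hidden2 = 16`, `head_hidden = 64`, `dropout = 0.5`, `d_gen = 50`,
#' `seq_dim = 60`, `k = 5`, `embed_dim = 16`, `gru_hidden = 32`,
#' `cvae_latent = 16`, `cvae_hidden = 64`, `cvae_epochs = 200`,
#' `epochs = 200`, `lr = 1e-3`, `warmup = 10`, `neg_ratio = 1`,
#' `allow_reverse = TRUE`, `use_known_negatives = FALSE`, `folds = 5`,
#' `repeats = 10`, `threshold = 0.5`, `test_negatives = "sampled"`
#' (`"all"` ranks every non-edge at test time).
#' @export
dgcgrn_config <- function(...) {
  cfg <- list(
    use_dgcn = TRUE, use_cvae = TRUE, use_seq = TRUE, use_dynamic = TRUE,
    share_theta = FALSE, alpha = 1, beta = 1,
    hidden1 = 32L, hidden2 = 16L, head_hidden = 64L, dropout = 0.5,
    d_gen = 50L, seq_dim = 60L, k = 5L, embed_dim = 16L, gru_hidden = 32L,
    cvae_latent = 16L, cvae_hidden = 64L, cvae_epochs = 200L,
    epochs = 200L, lr = 1e-3, warmup = 10L, seq_update_every = 1L,
    neg_ratio = 1, allow_reverse = TRUE, use_known_negatives = FALSE,
    folds = 5L, repeats = 10L, threshold = 0.5, test_negatives = "sampled")
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  for (f in c("hidden1", "hidden2", "head_hidden", "d_gen", "seq_dim", "k",
              "embed_dim", "gru_hidden", "cvae_latent", "cvae_hidden",
              "cvae_epochs", "epochs", "warmup", "folds", "repeats",
              "seq_update_every")) {
    cfg[[f]] <- as.integer(cfg[[f]])
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) abort(paste0("invalid value for ", f))
  }
  stopifnot(cfg$seq_update_every >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$lr > 0,
            cfg$neg_ratio > 0, cfg$folds >= 2L, cfg$repeats >= 1L,
            cfg$threshold > 0, cfg$threshold < 1,
            cfg$test_negatives %in% c("sampled", "all"))
  structure(cfg, class = "dgcgrn_config")
}

derive_seed <- function(seed, ...) {
  off <- c(...)
  as.integer((as.numeric(seed) %% 1000003) + sum(off * seq_along(off) * 97) %% 1000003)
}
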