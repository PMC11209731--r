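# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @describeIn dgcgrn_train Tidy method: scored training-graph edges.
#' @param x A `dgcgrn_fit`.
#' @export
tidy.dgcgrn_fit <- function(x, ...) {
  idx <- which(x$graph$A > 0, arr.ind = TRUE)
  pairs <- cbind(as.integer(idx[, 1]), as.integer(idx[, 2]))
  predict(x, pairs)
}

#' @describeIn dgcgrn_train Glance method: one-row fit summary.
#' @export
glance.dgcgrn_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 n_train_edges = sum(x$graph$A > 0),
                 epochs = nrow(x$log),
                 final_loss = x$final_train_loss,
                 use_dgcn = x$config$use_dgcn,
                 use_cvae = x$config$use_cvae,
                 use_seq = x$config$use_seq && !is.null(x$gru),
                 use_dynamic = x$config$use_dynamic)
}

#' @describeIn dgcgrn_train Autoplot method: training-loss trace.
#' @param object A `dgcgrn_fit`.
#' @export
autoplot.dgcgrn_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training BCE loss") +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validate Tidy method: the per-fold metric tibble.
#' @param x A `dgcgrn_cv`.
#' @export
tidy.dgcgrn_cv <- function(x, ...) x$results

#' @describeIn cross_validate Glance method: aggregate mean and sd.
#' @export
glance.dgcgrn_cv <- function(x, ...) {
  tibble::tibble(n_folds = nrow(x$results),
                 mean_auroc = mean(x$results$AUROC),
                 sd_auroc = sd(x$results$AUROC),
                 mean_aupr = mean(x$results$AUPR),
                 sd_aupr = sd(x$results$AUPR),
                 mean_acc = mean(x$results$ACC))
}

#' @describeIn cross_validate Autoplot method: per-repeat AUROC/AUPR boxplots.
#' @param object A `dgcgrn_cv`.
#' @export
autoplot.dgcgrn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results, c("AUROC", "AUPR"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$repeat_id),
                                     y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "repeat", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_ablation Tidy method: per-variant, per-seed results.
#' @param x A `dgcgrn_ablation`.
#' @export
tidy.dgcgrn_ablation <- function(x, ...) x$results

#' @describeIn run_ablation Glance method: variant means across seeds.
#' @export
glance.dgcgrn_ablation <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$results, .data$variant),
                   mean_auroc = mean(.data$mean_auroc),
                   sd_auroc = sd(.data$mean_auroc),
                   mean_aupr = mean(.data$mean_aupr),
                   .groups = "drop")
}

#' @describeIn run_ablation Autoplot method: AUROC by variant.
#' @param object A `dgcgrn_ablation`.
#' @export
autoplot.dgcgrn_ablation <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$variant, y = .data$mean_auroc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = "model variant", y = "mean AUROC per seed") +
    ggplot2::theme_minimal()
}
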