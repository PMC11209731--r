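test_that("negative sampling respects counts, exclusions and seeds", {
  set.seed(71)
  pos <- cbind(sample(1:20, 30, replace = TRUE),
               sample(1:20, 30, replace = TRUE))
  pos <- pos[pos[, 1] != pos[, 2], , drop = FALSE]
  pos <- unique(pos)
  neg <- sample_negatives(20, pos, nrow(pos), seed = 3)
  expect_equal(nrow(neg), nrow(pos))
  expect_true(all(neg[, 1] != neg[, 2]))
  keys <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(keys(neg), keys(pos)), 0L)
  neg2 <- sample_negatives(20, pos, nrow(pos), seed = 3)
  expect_identical(neg, neg2)
  # reversed positives excluded when requested
  neg3 <- sample_negatives(20, pos, 50, seed = 4, allow_reverse = FALSE)
  expect_length(intersect(keys(neg3), keys(pos[, 2:1, drop = FALSE])), 0L)
  expect_error(sample_negatives(3, cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2)),
                                5, seed = 1), "not enough")
})

test_that("dynamic update keeps topology, swaps weights, rejects bad scores", {
  g <- grn(tibble::tibble(source = c("N1", "N2", "N1"),
                          target = c("N2", "N3", "N3")),
           nodes = c("N1", "N2", "N3"))
  upd <- dynamic_update(g, c(0.5, 0.5, 0.5))
  expect_identical(upd$g$A > 0, g$A > 0)
  expect_equal(sort(unique(upd$g$A[upd$g$A > 0])), 0.5)
  # uniform weights preserve the support of the normalized proximity matrices
  P_old <- proximity_matrices(g)
  P_new <- proximity_matrices(upd$g)
  expect_identical(P_new$P_F > 0, P_old$P_F > 0)
  expect_identical(P_new$P_S_in > 0, P_old$P_S_in > 0)
  # raising one edge's score raises its weight monotonically
  upd2 <- dynamic_update(g, c(0.9, 0.5, 0.5))
  e <- which(g$A > 0)
  expect_gt(upd2$g$A[e[1]], upd$g$A[e[1]])
  expect_error(dynamic_update(g, c(1.2, 0.5, 0.5)), "\\(0, 1\\)")
  expect_error(dynamic_update(g, c(0, 0.5, 0.5)), "\\(0, 1\\)")
})

test_that("training reduces loss on a toy graph and is seed-deterministic", {
  ds <- small_dataset(seed = 3L)
  genes <- ds$expression$gene_id
  vals <- expression_values(ds$expression)
  pos <- cbind(match(ds$edges$source, genes), match(ds$edges$target, genes))
  g <- grn(ds$edges[, c("source", "target")], nodes = genes)
  neg <- sample_negatives(length(genes), pos, nrow(pos), seed = 8)
  cfg <- dgcgrn_config(use_cvae = FALSE, use_seq = FALSE, use_dynamic = FALSE,
                       epochs = 50, dropout = 0.2)
  fit <- dgcgrn_train(g, vals, neg, config = cfg, seed = 4)
  expect_s3_class(fit, "dgcgrn_fit")
  early <- mean(head(fit$log$loss, 10))
  late <- mean(tail(fit$log$loss, 10))
  expect_lt(late, early)
  fit2 <- dgcgrn_train(g, vals, neg, config = cfg, seed = 4)
  expect_identical(fit$params$layer1, fit2$params$layer1)
  expect_identical(fit$embeddings, fit2$embeddings)
  # prediction interface
  pr <- predict(fit, tibble::tibble(source = genes[1:3], target = genes[4:6]))
  expect_true(all(pr$score > 0 & pr$score < 1))
  expect_error(predict(fit, tibble::tibble(source = "nope", target = genes[1])),
               "absent")
})

test_that("dynamic update during training only changes post-warm-up behavior", {
  ds <- small_dataset(seed = 5L)
  genes <- ds$expression$gene_id
  vals <- expression_values(ds$expression)
  pos <- cbind(match(ds$edges$source, genes), match(ds$edges$target, genes))
  g <- grn(ds$edges[, c("source", "target")], nodes = genes)
  neg <- sample_negatives(length(genes), pos, nrow(pos), seed = 8)
  base <- dgcgrn_config(use_cvae = FALSE, use_seq = FALSE, epochs = 12,
                        warmup = 8, dropout = 0, use_dynamic = FALSE)
  dyn <- base; dyn$use_dynamic <- TRUE
  f_off <- dgcgrn_train(g, vals, neg, config = base, seed = 6)
  f_on <- dgcgrn_train(g, vals, neg, config = dyn, seed = 6)
  # identical up to and including warmup+1 epochs, divergent afterwards
  expect_equal(head(f_off$log$loss, 9), head(f_on$log$loss, 9))
  expect_false(isTRUE(all.equal(f_off$log$loss[11:12], f_on$log$loss[11:12])))
  # dynamic weights stay in (0,1) and topology is preserved
  expect_identical(f_on$graph$A > 0, g$A > 0)
  w <- f_on$graph$A[f_on$graph$A > 0]
  expect_true(all(w > 0 & w < 1))
})

test_that("cross-validation partitions positives and never leaks test edges", {
  ds <- small_dataset(seed = 7L)
  cfg <- fast_config(use_cvae = FALSE, use_seq = FALSE, use_dynamic = FALSE,
                     folds = 4L)
  cv <- cross_validate(ds$expression, ds$edges, config = cfg, seed = 2)
  expect_equal(nrow(tidy(cv)), 4L)
  expect_true(all(tidy(cv)$AUROC >= 0 & tidy(cv)$AUROC <= 1))
  gl <- glance(cv)
  expect_equal(gl$n_folds, 4L)
  # folds partition the positives: held-out positives sum to the edge count
  expect_equal(sum(tidy(cv)$TP + tidy(cv)$FN), nrow(ds$edges))

  # two repeats get different fold assignments
  cfg2 <- fast_config(use_cvae = FALSE, use_seq = FALSE, use_dynamic = FALSE,
                      repeats = 2L, folds = 3L, epochs = 2L)
  cv2 <- cross_validate(ds$expression, ds$edges, config = cfg2, seed = 5)
  expect_equal(nrow(tidy(cv2)), 6L)
  expect_false(isTRUE(all.equal(tidy(cv2)$AUROC[1:3], tidy(cv2)$AUROC[4:6])))
})

test_that("ablation harness toggles flags and reports one row per variant and seed", {
  ds <- small_dataset(seed = 9L)
  cfg <- fast_config(epochs = 5L, cvae_epochs = 15L)
  ab <- run_ablation(ds$expression, ds$edges, sequences = ds$sequences,
                     config = cfg, seeds = 1:2,
                     variants = c("E.1", "E.2", "E.6"))
  out <- tidy(ab)
  expect_equal(nrow(out), 6L)
  expect_setequal(unique(out$variant), c("E.1", "E.2", "E.6"))
  agg <- glance(ab)
  expect_equal(nrow(agg), 3L)
  full <- ablation_variants()
  expect_equal(full$variant, paste0("E.", 1:6))
  expect_false(full$use_dgcn[1])
  expect_true(all(full[full$variant == "E.6", c("use_dgcn", "use_cvae",
                                                "use_seq", "use_dynamic")] == TRUE))
})
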