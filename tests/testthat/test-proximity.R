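test_that("first-order proximity symmetrizes single and doubly-connected edges", {
  g <- grn(tibble::tibble(source = "N1", target = "N2"),
           nodes = c("N1", "N2", "N3"))
  AF <- first_order_proximity(g)
  expect_equal(AF[1, 2], 1)
  expect_equal(AF[2, 1], 1)
  expect_equal(AF[3, ], c(N1 = 0, N2 = 0, N3 = 0))

  g2 <- grn(tibble::tibble(source = c("N1", "N2"), target = c("N2", "N1"),
                           weight = c(0.3, 0.7)), nodes = c("N1", "N2"))
  AF2 <- first_order_proximity(g2)
  expect_equal(AF2[1, 2], 0.7)  # elementwise max of the two directions
  expect_equal(AF2[2, 1], 0.7)
})

test_that("second-order in-proximity matches hand evaluation on a shared parent", {
  g <- grn(tibble::tibble(source = c("N3", "N3"), target = c("N1", "N2")),
           nodes = c("N1", "N2", "N3"))
  Ain <- second_order_in(g)
  expect_equal(Ain[1, 2], 0.5)   # 1*1 / (1+1)
  expect_equal(Ain[1, 1], 0.5)   # diagonal via the same sum
  # no common parent: single edge only
  g2 <- grn(tibble::tibble(source = "N1", target = "N2"),
            nodes = c("N1", "N2"))
  expect_equal(second_order_in(g2)[1, 2], 0)
})

test_that("second-order out-proximity matches hand evaluation and the zero rule", {
  g <- grn(tibble::tibble(source = c("N1", "N2"), target = c("N3", "N3")),
           nodes = c("N1", "N2", "N3"))
  expect_equal(second_order_out(g)[1, 2], 0.5)
  chain <- grn(tibble::tibble(source = c("N1", "N2"), target = c("N2", "N3")),
               nodes = c("N1", "N2", "N3"))
  expect_equal(second_order_out(chain)[1, 3], 0)  # no common child
})

test_that("vectorized proximities agree with loop oracles on random weighted digraphs", {
  set.seed(11)
  for (trial in 1:30) {
    g <- random_digraph(sample(4:15, 1), p = runif(1, 0.1, 0.5),
                        weighted = TRUE)
    expect_lt(max(abs(second_order_in(g) - oracle_second_order_in(g$A))), 1e-12)
    expect_lt(max(abs(second_order_out(g) - oracle_second_order_out(g$A))), 1e-12)
    expect_identical(second_order_in(g), t(second_order_in(g)))
    expect_identical(second_order_out(g), t(second_order_out(g)))
    expect_identical(first_order_proximity(g), t(first_order_proximity(g)))
  }
})

test_that("transpose duality and scale behavior hold", {
  set.seed(12)
  for (trial in 1:20) {
    g <- random_digraph(sample(4:15, 1), p = 0.3, weighted = TRUE)
    gt <- g; gt$A <- t(g$A)
    expect_lt(max(abs(second_order_out(g) - second_order_in(gt))), 1e-12)
    c_scale <- runif(1, 0.5, 3)
    gs <- g; gs$A <- c_scale * g$A
    expect_equal(second_order_in(gs), c_scale * second_order_in(g),
                 tolerance = 1e-12)
    expect_equal(second_order_out(gs), c_scale * second_order_out(g),
                 tolerance = 1e-12)
  }
})

test_that("zero entries appear exactly where no common parent/child exists", {
  set.seed(13)
  for (trial in 1:10) {
    g <- random_digraph(8, p = 0.25)
    A <- g$A
    common_parent <- (t(A) %*% A) > 0   # binary A: k with A[k,i],A[k,j] > 0
    expect_identical(second_order_in(g) > 0, common_parent)
    common_child <- (A %*% t(A)) > 0
    expect_identical(second_order_out(g) > 0, common_child)
  }
})

test_that("self-loop normalization matches hand values and spectral bounds", {
  expect_equal(normalize_self_loop(matrix(0, 3, 3)), diag(3))
  expect_equal(normalize_self_loop(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  set.seed(14)
  for (trial in 1:20) {
    g <- random_digraph(sample(3:12, 1), p = 0.3, weighted = TRUE)
    M <- first_order_proximity(g)
    P <- normalize_self_loop(M)
    expect_identical(P, t(P))
    expect_true(all(diag(P) > 0))
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(max(ev), 1, tolerance = 1e-9)
    expect_gte(min(ev), -1 - 1e-9)
  }
})
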