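test_that("pair collection uses undirected neighborhoods", {
  # star: center N1 with leaves N2..N4 (mixed directions)
  g <- grn(tibble::tibble(source = c("N1", "N3", "N1"),
                          target = c("N2", "N1", "N4")),
           nodes = c("N1", "N2", "N3", "N4", "N5"))
  pr <- collect_pairs(g)
  expect_equal(nrow(pr), 6L)          # 3 adjacencies x 2 orientations
  expect_equal(sum(pr$v == 1), 3L)    # center serves as condition 3x
  expect_equal(sum(pr$u == 1), 3L)    # and as neighbor 3x
  expect_false(5 %in% c(pr$u, pr$v))  # isolated node contributes nothing

  single <- grn(tibble::tibble(source = "N1", target = "N2"),
                nodes = c("N1", "N2"))
  expect_equal(nrow(collect_pairs(single)), 2L)
})

test_that("KL closed form matches hand values and is nonnegative", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  expect_equal(cvae_loss(c(1, 2), c(1, 2), 0, 0), 0)
  set.seed(51)
  for (trial in 1:50) {
    mu <- rnorm(4); lv <- rnorm(4)
    expect_gte(kl_gaussian(mu, lv), 0)
  }
})

test_that("reparameterized latents have the encoder's mean and variance", {
  m <- 10000L
  mu0 <- 0.7; lv0 <- 0.4
  params <- dgcgrn:::cvae_init(d_in = 1, d_cond = 1, d_gen = 1, latent = 1, hidden = 2)
  # rig the encoder to output constant (mu0, lv0)
  params$enc$W1[] <- 0; params$enc$Wmu[] <- 0; params$enc$Wlv[] <- 0
  params$enc$bmu[] <- mu0; params$enc$blv[] <- lv0
  set.seed(52)
  eps <- matrix(rnorm(m), m, 1)
  fw <- dgcgrn:::cvae_forward(params, matrix(0, m, 1), matrix(0, m, 1),
                     matrix(0, m, 1), eps)
  z <- fw$cache$z
  se_mean <- sqrt(exp(lv0) / m)
  expect_lt(abs(mean(z) - mu0), 3 * se_mean)
  se_var <- exp(lv0) * sqrt(2 / (m - 1))
  expect_lt(abs(stats::var(as.vector(z)) - exp(lv0)), 3 * se_var)
})

test_that("analytic CVAE gradients match finite differences", {
  set.seed(53)
  m <- 6L
  Xu <- matrix(rnorm(m * 2), m, 2)
  Xv <- matrix(rnorm(m * 2), m, 2)
  Tg <- matrix(rnorm(m * 2), m, 2)
  eps <- matrix(rnorm(m * 3), m, 3)
  params <- dgcgrn:::cvae_init(2, 2, 2, latent = 3, hidden = 4)
  dims <- params$dims
  params$dims <- NULL
  loss_fn <- function(p) {
    p$dims <- dims
    dgcgrn:::cvae_forward(p, Xu, Xv, Tg, eps)$loss
  }
  pfull <- params; pfull$dims <- dims
  fw <- dgcgrn:::cvae_forward(pfull, Xu, Xv, Tg, eps)
  gr <- dgcgrn:::cvae_backward(pfull, fw$cache)
  num <- numeric_grad(params, loss_fn, eps = 1e-5)
  expect_lt(max_abs_diff(gr[c("enc", "dec")], num[c("enc", "dec")]), 1e-6)
})

test_that("training is deterministic and drives loss down on constant data", {
  m <- 40L
  Xu <- matrix(1, m, 2); Xv <- matrix(0.5, m, 2); Tg <- matrix(1, m, 2)
  f1 <- train_cvae(Xu, Xv, Tg, latent = 2, hidden = 8, epochs = 400,
                   lr = 5e-3, seed = 9)
  f2 <- train_cvae(Xu, Xv, Tg, latent = 2, hidden = 8, epochs = 400,
                   lr = 5e-3, seed = 9)
  expect_identical(f1$enc, f2$enc)
  expect_identical(f1$dec, f2$dec)
  # reconstruction of constant data approaches the trivial optimum
  n10 <- mean(head(f1$loss, 10))
  expect_lt(mean(tail(f1$loss, 10)), n10)
  recon <- generate_augmented(f1, Xv, seed = 3)
  expect_lt(mean((recon - 1)^2), 0.1)
  expect_error(train_cvae(Xu[0, , drop = FALSE], Xv[0, , drop = FALSE],
                          Tg[0, , drop = FALSE]), "at least one pair")
})

test_that("generated features track the conditioning feature on toy data", {
  set.seed(55)
  m <- 400L
  xv <- matrix(rnorm(m), m, 1)
  xu <- xv + matrix(rnorm(m, sd = 0.1), m, 1)
  fit <- train_cvae(xu, xv, xu, latent = 4, hidden = 16, epochs = 400,
                    lr = 3e-3, seed = 5)
  cond <- matrix(seq(-2, 2, length.out = 200), 200, 1)
  gen <- generate_augmented(fit, cond, seed = 6)
  expect_gt(cor(gen[, 1], cond[, 1]), 0.5)
})

test_that("seeded generation is reproducible and covers isolated nodes", {
  set.seed(56)
  g <- grn(tibble::tibble(source = c("N1", "N2"), target = c("N2", "N3")),
           nodes = c("N1", "N2", "N3", "N4"))
  X <- matrix(rnorm(4 * 6), 4, 6)
  la <- augment_features(g, X, d_gen = 5, latent = 3, hidden = 8,
                         epochs = 30, seed = 2)
  expect_equal(dim(la$augmented), c(4L, 5L))
  expect_true(all(is.finite(la$augmented[4, ])))  # isolated node N4 covered
  la2 <- augment_features(g, X, d_gen = 5, latent = 3, hidden = 8,
                          epochs = 30, seed = 2)
  expect_identical(la$augmented, la2$augmented)
})
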