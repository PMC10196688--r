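test_that("per-cluster feature lengths follow the conv/pool shape arithmetic", {
  # p = 8, same padding, pool 2 with ceil: 8 filters x ceil(ceil(8/2)/2) = 16
  fx <- small_fixture(n = 8, phyla = 1)
  cfg <- generator_config(dropout_rate = 0)
  F <- extract_features(fx$clr$clr_values[1, , ], fx$cm, cfg, seed = 2)
  expect_equal(ncol(F), 16)
  expect_equal(nrow(F), 5)
  # undersized clusters bypass the CNN and contribute raw clr values
  fx2 <- small_fixture(n = 7, phyla = 4) # cluster sizes 2,2,2,1
  F2 <- extract_features(fx2$clr$clr_values[1, , ], fx2$cm, cfg, seed = 2)
  expect_equal(ncol(F2), 7)
  perm <- unlist(fx2$cm$clusters)
  expect_equal(F2, fx2$clr$clr_values[1, , perm], ignore_attr = TRUE)
})

test_that("features are deterministic and local to each subject", {
  fx <- small_fixture()
  cfg <- generator_config(dropout_rate = 0)
  th <- init_gan_params(fx$cm, 5, 12, cfg, seed = 3)$theta_g
  x <- fx$clr$clr_values
  F1 <- extract_features(x[2, , ], fx$cm, cfg, theta = th)
  F1b <- extract_features(x[2, , ], fx$cm, cfg, theta = th)
  expect_identical(F1, F1b)
  # all-zero timepoints give identical bias-only responses
  z <- matrix(0, 4, 12)
  Fz <- extract_features(z, fx$cm, cfg, theta = th)
  expect_equal(Fz[1, ], Fz[3, ])
})

test_that("decay factor is exp(-ReLU(W delta + b)) with its limit cases", {
  expect_equal(decay_factor(c(0, 2, 100), 0, 0), rep(1, 3))
  expect_equal(round(decay_factor(3, 0.1, 0), 4), 0.7408)
  lam <- decay_factor(seq(0, 20, by = 0.5), 0.3, 0.1)
  expect_true(all(lam > 0 & lam <= 1))
  expect_true(all(diff(lam) <= 0))
  # negative pre-activation is clipped by the ReLU: lambda stays 1
  expect_equal(decay_factor(c(1, 2), -3, 0), c(1, 1))
})

test_that("observed-entry passthrough holds for any weights; shapes match", {
  fx <- small_fixture()
  x <- fx$clr$clr_values
  for (seed in 1:5) {
    pars <- init_gan_params(fx$cm, 5, 12, seed = seed)
    th <- pars$theta_g + rnorm(length(pars$theta_g), sd = 0.3)
    out <- generate(x, fx$amp$mask, fx$gaps$delta_f, fx$gaps$delta_b,
                    fx$cm, generator_config(), theta = th)
    expect_equal(dim(out$x_bar), dim(x))
    sel <- array(rep(fx$amp$mask, dim(x)[3]), dim = dim(x)) == 1
    expect_identical(out$x_bar[sel], x[sel])
    expect_true(all(is.finite(out$x_bar)))
    expect_true(all(out$lambda_f > 0 & out$lambda_f <= 1))
    expect_true(all(out$lambda_b > 0 & out$lambda_b <= 1))
  }
  # fully observed input: x_bar == x regardless of weights
  full <- small_fixture(rate = 0.01)
  full$amp$mask[] <- 1
  xf <- full$clr$clr_values
  outf <- generate(xf, full$amp$mask, full$gaps$delta_f * 0,
                   full$gaps$delta_b * 0, full$cm, theta = NULL, seed = 9)
  expect_identical(outf$x_bar, xf)
})

test_that("combined output is the decay-weighted sum of the two directions", {
  fx <- small_fixture()
  x <- fx$clr$clr_values
  out <- generate(x, fx$amp$mask, fx$gaps$delta_f, fx$gaps$delta_b, fx$cm,
                  generator_config(dropout_rate = 0), seed = 4)
  want <- out$x_tilde_f * array(rep(out$lambda_f, dim(x)[3]), dim(x)) +
          out$x_tilde_b * array(rep(out$lambda_b, dim(x)[3]), dim(x))
  expect_equal(out$x_tilde, want, tolerance = 1e-12)
})

test_that("discriminator heads are a proper sigmoid and softmax", {
  fx <- small_fixture()
  out <- generate(fx$clr$clr_values, fx$amp$mask, fx$gaps$delta_f,
                  fx$gaps$delta_b, fx$cm, seed = 5)
  masked <- out$x_bar * array(rep(fx$amp$mask, 12), dim = dim(out$x_bar))
  d1 <- discriminate(masked, seed = 6)
  expect_true(all(d1$p_real > 0 & d1$p_real < 1))
  sums <- apply(d1$timepoint_probs, c(1, 2), sum)
  expect_equal(sums, matrix(1, 8, 5), tolerance = 1e-6, ignore_attr = TRUE)
  d2 <- discriminate(masked, seed = 6)
  expect_identical(d1, d2)
})

test_that("analytic gradients match finite differences away from kinks", {
  fx <- small_fixture(S = 3, k = 4, n = 8, phyla = 2, seed = 13)
  cfg <- generator_config(rnn_hidden = 5, dropout_rate = 0)
  clusters <- lapply(fx$cm$clusters, as.integer)
  X <- aperm(fx$clr$clr_values, c(2, 3, 1))
  pars <- init_gan_params(fx$cm, 4, 8, cfg, discriminator_config(3),
                          seed = 17)
  set.seed(21)
  thG <- pars$theta_g + rnorm(length(pars$theta_g), sd = 0.05)
  thD <- pars$theta_d + rnorm(length(pars$theta_d), sd = 0.05)
  gen_f <- function(th) microgen:::cpp_gen_loss_grad(
    th, thD, X, fx$amp$mask, fx$gaps$delta_f, fx$gaps$delta_b, clusters,
    unclass(cfg), 3L, TRUE, FALSE, 1L)
  gl <- gen_f(thG)
  idx <- sort(sample(length(thG), 80))
  num <- vapply(idx, function(i) {
    e <- 1e-6; tp <- thG; tm <- thG
    tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
    (gen_f(tp)$total - gen_f(tm)$total) / (2 * e)
  }, numeric(1))
  expect_equal(num, gl$grad[idx], tolerance = 1e-5)

  Yr <- X; Yf <- X * 0.5
  disc_f <- function(th) microgen:::cpp_disc_loss_grad(th, Yr, Yf, 3L)
  dl <- disc_f(thD)
  idx2 <- sort(sample(length(thD), 60))
  num2 <- vapply(idx2, function(i) {
    e <- 1e-6; tp <- thD; tm <- thD
    tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
    (disc_f(tp)$total - disc_f(tm)$total) / (2 * e)
  }, numeric(1))
  expect_equal(num2, dl$grad[idx2], tolerance = 1e-5)
})
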