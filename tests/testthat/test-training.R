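test_that("generator loss matches hand-computed toy values", {
  # one subject, k = 2, n = 2, both samples observed
  x <- array(0, c(1, 2, 2)); x[1, , ] <- rbind(c(1, 2), c(3, 4))
  xt <- array(0, c(1, 2, 2)); xt[1, , ] <- rbind(c(1.5, 2), c(3, 4.5))
  e <- matrix(1, 1, 2)
  out <- list(x_tilde = xt, x_tilde_f = xt, x_tilde_b = xt)
  gl <- generator_loss(x, e, out, d_fake_prob = 1)
  expect_equal(gl$lossR, 0.5)            # (0.5 + 0.5) / ||e||_1
  expect_equal(gl$lossC, 0)              # identical directions
  expect_equal(gl$total, gl$lossG + gl$lossR + gl$lossC)
  # perfect reconstruction -> lossR = 0
  gl2 <- generator_loss(x, e, list(x_tilde = x, x_tilde_f = x,
                                   x_tilde_b = xt), 0.5)
  expect_equal(gl2$lossR, 0)
  expect_equal(gl2$lossG, -log(0.5))
  expect_error(generator_loss(x, matrix(0, 1, 2), out, 0.5), "observed")
})

test_that("lossR ignores the values generated at missing samples", {
  x <- array(rnorm(12), c(1, 3, 4))
  e <- matrix(c(1, 0, 1), 1, 3)
  xt <- x + 0.3
  out1 <- list(x_tilde = xt, x_tilde_f = xt, x_tilde_b = xt)
  xt2 <- xt; xt2[1, 2, ] <- 99
  out2 <- list(x_tilde = xt2, x_tilde_f = xt, x_tilde_b = xt)
  expect_equal(generator_loss(x, e, out1, 0.5)$lossR,
               generator_loss(x, e, out2, 0.5)$lossR)
})

test_that("discriminator loss matches the binary and timepoint cross-entropies", {
  k <- 3
  unif <- array(1 / k, c(1, k, k))
  dl <- discriminator_loss(0.5, 0.5, unif)
  expect_equal(dl$lossD, 2 * log(2), tolerance = 1e-12)
  expect_equal(round(dl$lossD, 4), 1.3863)
  expect_equal(dl$lossT, k * log(k), tolerance = 1e-12)
  # near-perfect timepoint prediction -> lossT near 0
  sharp <- array(1e-7 / (k - 1), c(1, k, k))
  for (i in 1:k) sharp[1, i, i] <- 1 - 1e-7
  expect_lt(discriminator_loss(0.9, 0.1, sharp)$lossT, 1e-5)
  expect_equal(dl$total, dl$lossD + dl$lossT)
})

test_that("training is seed-reproducible and early stopping honors patience", {
  fx <- small_fixture(S = 6, k = 4, n = 9, phyla = 3, seed = 23)
  tcfg <- training_config(patience_epochs = 30, max_epochs = 120, seed = 41)
  m1 <- train_microgen(fx$clr, fx$gaps, fx$cm, tcfg = tcfg)
  m2 <- train_microgen(fx$clr, fx$gaps, fx$cm, tcfg = tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$theta_g, m2$theta_g)
  # patience 0 stops after exactly one epoch
  m0 <- train_microgen(fx$clr, fx$gaps, fx$cm,
                       tcfg = training_config(patience_epochs = 0,
                                              max_epochs = 100, seed = 1))
  expect_equal(m0$epochs_run, 1)
  # the trace carries all loss components and the total is their sum
  expect_equal(m1$history$gen_total,
               m1$history$lossG + m1$history$lossR + m1$history$lossC,
               tolerance = 1e-12)
})

test_that("reconstruction-only training improves the observed-entry fit", {
  # with no discriminator the objective reduces to lossR + lossC; on a
  # smooth interpolable cohort the fit must improve over training
  fx <- small_fixture(S = 10, k = 6, n = 12, phyla = 3, seed = 29)
  m <- train_microgen(fx$clr, fx$gaps, fx$cm,
                      gcfg = generator_config(dropout_rate = 0),
                      tcfg = training_config(patience_epochs = 400,
                                             max_epochs = 800, seed = 3),
                      variant = "rnn")
  expect_equal(m$history$gen_total, m$history$lossR + m$history$lossC,
               tolerance = 1e-12)
  h <- m$history$lossR
  expect_lt(h[length(h)], h[1])
  # monotone trend over 200-epoch windows
  w <- split(h, ceiling(seq_along(h) / 200))
  means <- vapply(w, mean, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("imputation preserves observed entries and is deterministic", {
  fx <- small_fixture(S = 6, k = 4, n = 9, phyla = 3, seed = 31)
  m <- train_microgen(fx$clr, fx$gaps, fx$cm,
                      tcfg = training_config(patience_epochs = 20,
                                             max_epochs = 60, seed = 2))
  imp1 <- impute_microgen(m, fx$clr)
  imp2 <- impute_microgen(m, fx$clr)
  expect_identical(imp1$clr, imp2$clr)
  sel <- array(rep(fx$amp$mask, 9), dim = dim(imp1$clr)) == 1
  expect_identical(imp1$clr[sel], fx$clr$clr_values[sel])
  expect_true(all(is.finite(imp1$clr)))
  # taxon mismatch with the checkpoint errors
  other <- small_fixture(S = 6, k = 4, n = 10, phyla = 3, seed = 32)
  expect_error(impute_microgen(m, other$clr), "taxon")
})

test_that("checkpoints reproduce imputations exactly", {
  fx <- small_fixture(S = 5, k = 4, n = 8, phyla = 2, seed = 37)
  m <- train_microgen(fx$clr, fx$gaps, fx$cm,
                      tcfg = training_config(patience_epochs = 10,
                                             max_epochs = 30, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_equal(impute_microgen(m2, fx$clr)$clr,
               impute_microgen(m, fx$clr)$clr, tolerance = 1e-12)
})
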