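test_that("clr-scale MAE is the plain mean over missing-sample entries", {
  x <- array(0, c(1, 2, 2))
  y <- x
  x[1, 2, ] <- c(1, 2); y[1, 2, ] <- c(1.5, 3.5)
  mask <- matrix(c(1, 0), 1, 2)
  expect_equal(mae_clr(x, y, mask), 1.0)   # errors 0.5 and 1.5
  expect_equal(mae_clr(x, x, mask), 0)
  # invariant to a joint taxon permutation
  xp <- x[, , 2:1, drop = FALSE]; yp <- y[, , 2:1, drop = FALSE]
  expect_equal(mae_clr(xp, yp, mask), mae_clr(x, y, mask))
  expect_error(mae_clr(x, y, matrix(1, 1, 2)), "no missing")
})

test_that("postprocessing yields compositions, zeroes sub-threshold taxa", {
  # clr of zeros -> uniform composition
  expect_equal(postprocess_to_ra(rep(0, 4), 0.01), rep(0.25, 4))
  # softmax (0.6, 0.399, 0.001) with pseudo-count 0.01: 0.001 zeroed and
  # redistributed equally over the 2 surviving taxa
  v <- log(c(0.6, 0.399, 0.001))
  got <- postprocess_to_ra(v, 0.01)
  expect_equal(got, c(0.6005, 0.3995, 0), tolerance = 1e-9)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  # round trip of a clr-transformed sample with no sub-threshold entries
  ra <- c(0.4, 0.3, 0.2, 0.1)
  clr <- log(ra) - mean(log(ra))
  expect_equal(postprocess_to_ra(clr, 0.01), ra, tolerance = 1e-9)
  expect_error(postprocess_to_ra(rep(0, 4), 0.5), "below")
  # random tensors always give valid compositions
  set.seed(8)
  arr <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
  out <- postprocess_to_ra(arr, 1e-4)
  expect_true(all(out >= 0))
  expect_equal(apply(out, c(1, 2), sum), matrix(1, 2, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Shannon and Bray-Curtis match closed forms and vegan", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(round(shannon_index(rep(0.25, 4)), 4), 1.3863)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(12)
  comps <- random_compositions(100, 15)
  for (i in seq_len(50)) {
    a <- comps[2 * i - 1, ]; b <- comps[2 * i, ]
    expect_lte(shannon_index(a), log(15))
    expect_equal(shannon_index(a),
                 vegan::diversity(a, index = "shannon"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(bray_curtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b),
                                           method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("diversity comparison matches a textbook paired-t oracle", {
  set.seed(19)
  S <- 4; k <- 6; n <- 10
  truth <- array(0, c(S, k, n)); imp <- truth
  for (s in 1:S) for (t in 1:k) {
    truth[s, t, ] <- random_compositions(1, n)
    imp[s, t, ] <- random_compositions(1, n)
  }
  mask <- matrix(1, S, k); mask[, 2:4] <- 0
  dc <- diversity_comparison(truth, imp, mask, nmds = FALSE)
  a <- dc$shannon_true; b <- dc$shannon_imputed
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(dc$t_statistic, t_oracle, tolerance = 1e-10)
  expect_equal(dc$alpha_pearson, cor(a, b), tolerance = 1e-12)
  expect_gte(dc$bray_curtis_corr, -1); expect_lte(dc$bray_curtis_corr, 1)
  # identical tensors: degenerate comparison flagged, correlation 1
  dci <- diversity_comparison(truth, truth, mask, nmds = FALSE)
  expect_true(dci$degenerate)
  expect_equal(dci$t_statistic, 0)
  expect_equal(dci$alpha_pearson, 1)
  expect_error(diversity_comparison(truth, imp, matrix(1, S, k)),
               "3 missing")
})

test_that("NMDS coordinates are returned with a stress value", {
  set.seed(23)
  S <- 3; k <- 4; n <- 8
  truth <- array(0, c(S, k, n)); imp <- truth
  for (s in 1:S) for (t in 1:k) {
    truth[s, t, ] <- random_compositions(1, n)
    imp[s, t, ] <- random_compositions(1, n)
  }
  mask <- matrix(1, S, k); mask[, 2:3] <- 0
  dc <- diversity_comparison(truth, imp, mask, nmds = TRUE, seed = 3)
  m <- sum(mask == 0)
  expect_equal(dim(dc$nmds$points), c(2 * m, 2))
  expect_true(is.finite(dc$nmds$stress))
  expect_equal(table(dc$nmds$group)[["true"]], m)
})

test_that("zero metrics follow the set arithmetic", {
  truth <- array(0, c(1, 2, 4)); imp <- truth
  truth[1, 1, ] <- c(0.5, 0.5, 0, 0); imp[1, 1, ] <- c(0.5, 0, 0.5, 0)
  # entries: true zeros {3,4}, predicted zeros {2,4}
  mask <- matrix(c(0, 1), 1, 2)
  zm <- zero_metrics(truth, imp, mask)
  expect_equal(zm$symdiff, 2L)
  expect_equal(zm$recall, 0.5)
  zp <- zero_metrics(truth, truth, mask)
  expect_equal(zp$symdiff, 0L); expect_equal(zp$recall, 1)
  # predictor with no zeros
  imp2 <- truth; imp2[1, 1, ] <- c(0.25, 0.25, 0.25, 0.25)
  z2 <- zero_metrics(truth, imp2, mask)
  expect_equal(z2$symdiff, 2L); expect_equal(z2$recall, 0)
  # no true zeros -> recall absent
  t3 <- truth; t3[1, 1, ] <- rep(0.25, 4)
  expect_true(is.na(zero_metrics(t3, imp2, mask)$recall))
})

test_that("cross-validated benchmark partitions subjects and scores an oracle at 0", {
  fx <- small_fixture(S = 8, k = 5, n = 10, phyla = 2, seed = 107)
  res <- benchmark(fx$truth, methods = c("oracle", "locf", "mean"),
                   folds = 4, seed = 5, base_mask = fx$amp$mask)
  scored <- unique(res$per_fold$fold)
  expect_true(all(scored %in% 1:4))
  # one row per method per scored fold
  expect_equal(nrow(res$per_fold), 3 * length(scored))
  expect_equal(unname(res$mean_mae[["oracle"]]), 0, tolerance = 1e-9)
  expect_true(all(res$per_fold$mae[res$per_fold$method != "oracle"] > 0))
  # without a base mask, interior timepoints of test subjects are masked
  res2 <- benchmark(fx$truth, methods = "locf", folds = 4, seed = 5)
  expect_equal(nrow(res2$per_fold), 4)
  expect_error(benchmark(fx$truth, folds = 20), "folds")
})
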