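test_that("base cohorts are valid compositions with structural zeros", {
  spec <- simulation_spec(n_taxa = 20, n_phyla = 3, n_timepoints = 5,
                          n_template_subjects = 6, sparsity = 0.3,
                          seed = 61)
  ds <- generate_base_cohort(spec)
  expect_s3_class(ds, "microgen_dataset") # constructor enforces invariants
  # structural zeros persist across all timepoints within a subject
  for (s in 1:6) {
    z1 <- ds$abundances[s, 1, ] == 0
    for (t in 2:5) expect_equal(ds$abundances[s, t, ] == 0, z1)
  }
  # same seed -> identical cohort
  expect_identical(generate_base_cohort(spec)$abundances, ds$abundances)
})

test_that("ar coefficient 1 with zero innovations gives constant trajectories", {
  spec <- simulation_spec(n_taxa = 10, n_phyla = 2, n_timepoints = 4,
                          n_template_subjects = 3, sparsity = 0,
                          ar_coefficient = 1, innovation_sd = 0,
                          phylum_sd = 0, seed = 67)
  ds <- generate_base_cohort(spec)
  for (s in 1:3) for (t in 2:4)
    expect_equal(ds$abundances[s, t, ], ds$abundances[s, 1, ],
                 tolerance = 1e-12)
})

test_that("phylum drift induces stronger within- than between-phylum correlation", {
  within <- numeric(5); between <- numeric(5)
  for (i in 1:5) {
    spec <- simulation_spec(seed = 70 + i) # 60 taxa, 4 phyla defaults
    ds <- generate_base_cohort(spec)
    clr <- clr_transform(add_pseudocount(ds))
    X <- apply(clr$clr_values, 3, c)   # samples x taxa
    R <- suppressWarnings(cor(X, method = "spearman"))
    R[!is.finite(R)] <- 0
    same <- outer(ds$phylum, ds$phylum, "==")
    diag(R) <- NA; diag(same) <- NA
    within[i] <- mean(R[same & !is.na(same)], na.rm = TRUE)
    between[i] <- mean(R[!same & !is.na(same)], na.rm = TRUE)
  }
  expect_true(all(within > between))
})

test_that("perturbed subjects preserve zeros, sums and the noise scale", {
  spec <- simulation_spec(n_taxa = 100, n_phyla = 4, n_timepoints = 4,
                          n_template_subjects = 5, sparsity = 0.3,
                          seed = 83)
  tmpl <- generate_base_cohort(spec)
  per <- perturb_subjects(tmpl, 8, spec)
  expect_equal(dim(per$abundances)[1], 8)
  # trace each perturbed subject back to its template by support match
  for (s in 1:8) {
    sums <- apply(per$abundances[s, , ], 1, sum)
    expect_equal(sums, rep(1, 4), tolerance = 1e-9)
  }
  # zeros preserved: every zero support pattern must exist in the template
  tmpl_supports <- apply(tmpl$abundances[, 1, ] == 0, 1, paste,
                         collapse = "")
  for (s in 1:8)
    expect_true(paste(per$abundances[s, 1, ] == 0, collapse = "") %in%
                tmpl_supports)
  # max per-taxon change vs its template is within the stated noise bound
  for (s in 1:8) {
    src <- which.min(vapply(1:5, function(ts)
      sum(abs(tmpl$abundances[ts, 1, ] - per$abundances[s, 1, ])),
      numeric(1)))
    d <- abs(tmpl$abundances[src, , ] - per$abundances[s, , ])
    expect_lt(max(d), 1e-5)
  }
  expect_error(perturb_subjects(tmpl, 0, spec), "positive")
})

test_that("MCAR amputation hits the requested rate and zeroes masked samples", {
  spec <- simulation_spec(n_taxa = 15, n_phyla = 3, n_timepoints = 8,
                          n_template_subjects = 25, seed = 89)
  ds <- generate_base_cohort(spec)
  for (rate in c(0.2, 0.5)) {
    got <- vapply(1:3, function(s) {
      amp <- ampute(ds, missingness_spec("MCAR", rate, seed = s))
      mean(amp$mask == 0)
    }, numeric(1))
    expect_lt(abs(mean(got) - rate), 0.05)
  }
  amp <- ampute(ds, missingness_spec("MCAR", 0.3, seed = 5))
  mis <- which(amp$mask == 0, arr.ind = TRUE)
  for (r in seq_len(nrow(mis)))
    expect_true(all(amp$abundances[mis[r, 1], mis[r, 2], ] == 0))
  # the input dataset is untouched (ground truth retained by the caller)
  expect_true(all(ds$mask == 1))
  expect_identical(ds$abundances[1, 1, ], generate_base_cohort(spec)$abundances[1, 1, ])
  # same seed -> identical mask
  expect_identical(ampute(ds, missingness_spec("MCAR", 0.3, seed = 5))$mask,
                   amp$mask)
})

test_that("MAR missingness tracks the observed-score, not the amputed values", {
  spec <- simulation_spec(n_taxa = 20, n_phyla = 4, n_timepoints = 6,
                          n_template_subjects = 120, phylum_sd = 0.6,
                          seed = 97)
  ds <- generate_base_cohort(spec)
  amp <- ampute(ds, missingness_spec("MAR", 0.3, seed = 7))
  clr <- clr_transform(add_pseudocount(ds))
  summ <- apply(clr$clr_values, c(1, 2), mean)
  k <- 6
  cand <- 2:(k - 1)
  missing <- as.numeric(amp$mask[, cand] == 0)
  # score = standardized summary of the always-observed first and last
  score <- rowSums(scale(summ)[, c(1, k)])
  score_mat <- matrix(score, nrow(summ), length(cand))
  r_score <- cor(as.vector(score_mat), as.vector(missing))
  expect_gt(r_score, 0)
  expect_lt(cor.test(as.vector(score_mat),
                     as.vector(missing))$p.value, 0.01)
  # own values should not predict missingness under MAR
  own <- scale(summ)[, cand]
  r_own <- cor.test(as.vector(own), as.vector(missing))
  expect_gt(r_own$p.value, 0.01)
})

test_that("MNAR missingness tracks the amputed samples' own values", {
  spec <- simulation_spec(n_taxa = 20, n_phyla = 4, n_timepoints = 6,
                          n_template_subjects = 120, phylum_sd = 0.6,
                          seed = 101)
  ds <- generate_base_cohort(spec)
  amp <- ampute(ds, missingness_spec("MNAR", 0.3, seed = 9))
  clr <- clr_transform(add_pseudocount(ds))
  summ <- scale(apply(clr$clr_values, c(1, 2), mean))
  cand <- 2:5
  missing <- as.numeric(amp$mask[, cand] == 0)
  own_score <- rowSums(summ[, cand])
  r <- cor.test(rep(own_score, length(cand)), as.vector(missing))
  expect_gt(r$estimate, 0)
  expect_lt(r$p.value, 0.01)
})
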