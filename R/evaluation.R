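#' Mean absolute error on the clr scale over missing samples
#'
#' Mean of `|true - imputed|` over all (missing sample, taxon) entries —
#' the imputation score used throughout benchmarking.
#'
#' @param true_clr,imputed_clr numeric arrays `[S, k, n]`.
#' @param mask binary `S x k` matrix; entries with 0 are scored.
#' @return scalar MAE.
#' @export
mae_clr <- function(true_clr, imputed_clr, mask) {
  stopifnot(all(dim(true_clr) == dim(imputed_clr)))
  mis <- which(mask == 0, arr.ind = TRUE)
  if (!nrow(mis)) stop("no missing samples to score")
  err <- 0; cnt <- 0
  for (r in seq_len(nrow(mis))) {
    d <- abs(true_clr[mis[r, 1], mis[r, 2], ] -
             imputed_clr[mis[r, 1], mis[r, 2], ])
    err <- err + sum(d); cnt <- cnt + length(d)
  }
  err / cnt
}

#' Post-process clr-scale imputations to relative abundances
#'
#' Per sample: `RA = exp(clr)` normalized to 1; values below the
#' pseudo-count are set to zero and the resulting deficit is split equally
#' over the remaining nonzero taxa so the sample still sums to 1.
#'
#' @param imputed_clr numeric array `[S, k, n]` (or a single `k x n` /
#'   length-n sample).
#' @param pseudo_count the pseudo-count recorded during preprocessing.
#' @return array of the same shape on the RA scale.
#' @export
postprocess_to_ra <- function(imputed_clr, pseudo_count) {
  stopifnot(is.finite(pseudo_count), pseudo_count > 0)
  if (is.null(dim(imputed_clr)))
    return(postprocess_sample(imputed_clr, pseudo_count))
  out <- imputed_clr
  if (length(dim(imputed_clr)) == 2) {
    for (i in seq_len(nrow(imputed_clr)))
      out[i, ] <- postprocess_sample(imputed_clr[i, ], pseudo_count)
    return(out)
  }
  for (s in seq_len(dim(imputed_clr)[1]))
    for (i in seq_len(dim(imputed_clr)[2]))
      out[s, i, ] <- postprocess_sample(imputed_clr[s, i, ], pseudo_count)
  out
}

postprocess_sample <- function(v, pc) {
  ra <- exp(v - max(v))
  ra <- ra / sum(ra)
  low <- ra < pc
  if (all(low)) stop("all entries fall below the pseudo-count")
  deficit <- sum(ra[low])
  ra[low] <- 0
  ra[!low] <- ra[!low] + deficit / sum(!low)
  ra
}

#' Shannon alpha-diversity of one composition
#'
#' `-sum_{x_j > 0} x_j ln x_j`.
#'
#' @param ra_sample nonnegative vector summing to 1.
#' @return scalar in `[0, ln n]`.
#' @export
shannon_index <- function(ra_sample) {
  p <- ra_sample[ra_sample > 0]
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' `sum |a - b| / sum (a + b)`, which is `0.5 * sum |a - b|` for
#' compositions.
#'
#' @param ra_a,ra_b nonnegative vectors summing to 1.
#' @return scalar in `[0, 1]`.
#' @export
bray_curtis <- function(ra_a, ra_b) {
  sum(abs(ra_a - ra_b)) / sum(ra_a + ra_b)
}

#' Compare diversities of true and imputed missing samples
#'
#' Over the missing samples: paired t-test on Shannon indices, Pearson
#' correlation of the paired Shannon values, Pearson correlation of the
#' matched upper-triangle entries of the true vs imputed Bray-Curtis
#' matrices, and a seeded 2-D NMDS embedding (coordinates only) of the
#' pooled true + imputed distance matrix.
#'
#' @param true_ra,imputed_ra RA arrays `[S, k, n]`.
#' @param mask binary `S x k` matrix; entries with 0 are compared.
#' @param nmds compute the NMDS embedding (default TRUE).
#' @param seed RNG seed for the NMDS starts.
#' @return list with `shannon_true`, `shannon_imputed`, `t_statistic`,
#'   `t_p_value`, `alpha_pearson`, `bray_curtis_corr`, and `nmds`
#'   (coordinates + stress) when requested.
#' @export
diversity_comparison <- function(true_ra, imputed_ra, mask, nmds = TRUE,
                                 seed = 1L) {
  mis <- which(mask == 0, arr.ind = TRUE)
  if (nrow(mis) < 3) stop("need at least 3 missing samples")
  m <- nrow(mis)
  a_true <- numeric(m); a_imp <- numeric(m)
  Rt <- matrix(0, m, dim(true_ra)[3]); Ri <- Rt
  for (r in seq_len(m)) {
    vt <- true_ra[mis[r, 1], mis[r, 2], ]
    vi <- imputed_ra[mis[r, 1], mis[r, 2], ]
    a_true[r] <- shannon_index(vt); a_imp[r] <- shannon_index(vi)
    Rt[r, ] <- vt; Ri[r, ] <- vi
  }
  diffs <- a_true - a_imp
  if (stats::sd(diffs) == 0) {
    tt <- list(statistic = 0, p.value = 1)
    degenerate <- TRUE
  } else {
    ht <- stats::t.test(a_true, a_imp, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    degenerate <- FALSE
  }
  alpha_r <- if (stats::sd(a_true) == 0 || stats::sd(a_imp) == 0) NA_real_
             else stats::cor(a_true, a_imp)
  Dt <- as.matrix(stats::dist(Rt, method = "manhattan")) / 2
  Di <- as.matrix(stats::dist(Ri, method = "manhattan")) / 2
  ut <- Dt[upper.tri(Dt)]; ui <- Di[upper.tri(Di)]
  bc_r <- if (stats::sd(ut) == 0 || stats::sd(ui) == 0) NA_real_
          else stats::cor(ut, ui)
  out <- list(shannon_true = a_true, shannon_imputed = a_imp,
              t_statistic = tt$statistic, t_p_value = tt$p.value,
              alpha_pearson = alpha_r, bray_curtis_corr = bc_r,
              degenerate = degenerate)
  if (nmds) {
    pooled <- rbind(Rt, Ri)
    Dp <- stats::dist(pooled, method = "manhattan") / 2
    set.seed(seed)
    fit <- vegan::monoMDS(Dp, k = 2)
    out$nmds <- list(points = fit$points,
                     stress = fit$stress,
                     group = rep(c("true", "imputed"), each = m))
  }
  out
}

#' Zero-preservation metrics over missing samples
#'
#' Over the (missing sample, taxon) entries of post-processed RA tensors:
#' the size of the symmetric difference between the true-zero and
#' predicted-zero sets, and the fraction of true zeros correctly predicted.
#'
#' @param true_ra,imputed_ra RA arrays `[S, k, n]`.
#' @param mask binary `S x k` matrix.
#' @return list `symdiff` (integer) and `recall` (in `[0,1]`, `NA` when
#'   there are no true zeros).
#' @export
zero_metrics <- function(true_ra, imputed_ra, mask) {
  mis <- which(mask == 0, arr.ind = TRUE)
  tz <- logical(0); pz <- logical(0)
  for (r in seq_len(nrow(mis))) {
    tz <- c(tz, true_ra[mis[r, 1], mis[r, 2], ] == 0)
    pz <- c(pz, imputed_ra[mis[r, 1], mis[r, 2], ] == 0)
  }
  symdiff <- sum(xor(tz, pz))
  recall <- if (!any(tz)) NA_real_ else sum(tz & pz) / sum(tz)
  list(symdiff = as.integer(symdiff), recall = recall)
}

#' Cross-validated imputation benchmark
#'
#' Subjects are split into folds and each fold's test subjects are
#' considered missing: when `base_mask` (a missingness pattern from
#' [ampute()]) is supplied, the test subjects receive their `base_mask`
#' pattern while all other subjects stay fully observed; otherwise the test
#' subjects' samples at `eval_timepoints` (default: all interior
#' timepoints) are masked. Every method imputes the fold-masked dataset and
#' the clr-scale MAE against the ground truth is recorded over the
#' fold-masked samples.
#'
#' @param dataset a fully observed ground-truth [microgen_dataset()].
#' @param methods character vector from `mean`, `median`, `linear`,
#'   `cubic`, `moving_window`, `mice`, `locf`, `full`, `bigan`, `rnn`
#'   (the last three train the adversarial model), or `oracle` (returns the
#'   truth; harness sanity check).
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold split and training.
#' @param base_mask optional `S x k` missingness pattern applied to the
#'   test subjects of each fold.
#' @param eval_timepoints timepoints masked for test subjects when no
#'   `base_mask` is given (default interior).
#' @param tcfg [training_config()] used for the model variants.
#' @param gcfg,dcfg model configurations.
#' @return list with `per_fold` (data.frame method x fold MAE) and
#'   `mean_mae` (named vector).
#' @export
benchmark <- function(dataset, methods = c("locf", "mean"), folds = 10L,
                      seed = 1L, base_mask = NULL, eval_timepoints = NULL,
                      tcfg = training_config(),
                      gcfg = generator_config(),
                      dcfg = discriminator_config()) {
  stopifnot(inherits(dataset, "microgen_dataset"))
  S <- dim(dataset$abundances)[1]; k <- dim(dataset$abundances)[2]
  if (folds > S) stop("more folds than subjects")
  if (is.null(eval_timepoints)) eval_timepoints <- setdiff(seq_len(k), c(1, k))

  # ground-truth clr built once with the global pseudo-count
  truth_pc <- add_pseudocount(dataset)
  truth_clr <- clr_transform(truth_pc)

  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), S))
  rows <- list()
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    mask <- matrix(1, S, k)
    if (is.null(base_mask)) {
      mask[test, eval_timepoints] <- 0
    } else {
      mask[test, ] <- base_mask[test, ]
    }
    # keep every subject imputable
    for (s in test) if (all(mask[s, ] == 0)) mask[s, k] <- 1
    eval_mask <- matrix(1, S, k)
    eval_mask[mask == 0] <- 0
    if (all(eval_mask == 1)) next # no missing samples to score in this fold

    masked <- dataset
    masked$mask <- mask
    for (s in seq_len(S)) for (t in seq_len(k))
      if (mask[s, t] == 0) masked$abundances[s, t, ] <- 0
    m_pc <- add_pseudocount(masked)
    m_clr <- clr_transform(m_pc)

    for (meth in methods) {
      imp <- switch(meth,
        full = , bigan = , rnn = {
          tc <- tcfg; tc$seed <- as.integer(seed + 1000L * f)
          model <- train_microgen(m_clr, gcfg = gcfg, dcfg = dcfg,
                                  tcfg = tc, variant = meth)
          impute_microgen(model, m_clr)
        },
        oracle = new_imputation(truth_clr$clr_values, mask,
                                truth_clr$pseudo_count, "oracle"),
        impute_baseline(m_clr, mask, baseline_spec(meth)))
      rows[[length(rows) + 1]] <- data.frame(
        fold = f, method = meth,
        mae = mae_clr(truth_clr$clr_values, imp$clr, eval_mask))
    }
  }
  per_fold <- do.call(rbind, rows)
  mean_mae <- tapply(per_fold$mae, per_fold$method, mean)
  list(per_fold = per_fold, mean_mae = mean_mae[unique(per_fold$method)])
}
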