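# Small cohorts and hand-built datasets used across the test files.

# deterministic hand-built dataset from a list of per-subject k x n matrices
manual_dataset <- function(mats, mask, timepoints = NULL, phylum = NULL) {
  S <- length(mats); k <- nrow(mats[[1]]); n <- ncol(mats[[1]])
  ab <- array(0, dim = c(S, k, n))
  for (s in seq_len(S)) ab[s, , ] <- mats[[s]]
  if (is.null(timepoints)) timepoints <- seq_len(k)
  if (is.null(phylum)) phylum <- rep("P1", n)
  microgen_dataset(ab, timepoints, mask,
                   sprintf("OTU%02d", seq_len(n)), phylum,
                   sprintf("S%02d", seq_len(S)))
}

# random composition rows that sum to 1
random_compositions <- function(m, n) {
  x <- matrix(stats::rgamma(m * n, shape = 1), m, n)
  x / rowSums(x)
}

# small simulated cohort with missingness, clr and cluster map prepared
small_fixture <- function(S = 8, k = 5, n = 12, phyla = 3, rate = 0.25,
                          seed = 7) {
  spec <- simulation_spec(n_taxa = n, n_phyla = phyla, n_timepoints = k,
                          n_template_subjects = S, sparsity = 0.2,
                          seed = seed)
  truth <- generate_base_cohort(spec)
  amp <- ampute(truth, missingness_spec("MCAR", rate, seed = seed))
  clr <- clr_transform(add_pseudocount(amp))
  list(truth = truth, amp = amp, clr = clr,
       cm = build_cluster_map(clr), gaps = time_gap_matrices(amp))
}

# brute-force time gaps: scan for the nearest observed neighbour
oracle_time_gaps <- function(tt, e) {
  k <- length(tt)
  df <- numeric(k); db <- numeric(k)
  for (i in seq_len(k)) {
    prev <- if (i > 1) max(which(e[seq_len(i - 1)] == 1), -Inf) else -Inf
    df[i] <- if (i == 1) 0
             else if (is.finite(prev)) tt[i] - tt[prev]
             else tt[i] - tt[1] + 0 # no observed before: accumulate from t1
    # the printed recurrence accumulates from the start regardless
    if (i > 1 && !is.finite(prev)) df[i] <- tt[i] - tt[1]
    nxt <- if (i < k) {
      w <- which(e[(i + 1):k] == 1)
      if (length(w)) i + min(w) else Inf
    } else Inf
    db[i] <- if (i == k) 0
             else if (is.finite(nxt)) tt[nxt] - tt[i]
             else tt[k] - tt[i]
  }
  list(delta_f = df, delta_b = db)
}

# textbook Spearman: average ranks then Pearson
oracle_spearman <- function(X) {
  R <- apply(X, 2, rank)
  stats::cor(R)
}
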