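#' Simulation specification for synthetic longitudinal cohorts
#'
#' Defines a download-free stand-in for a real longitudinal template cohort:
#' compositional, sparse, with within-phylum correlation and smooth
#' log-scale AR(1) trajectories. New subjects are derived from templates by
#' the small-additive-noise recipe (normal noise with mean drawn once per
#' run from `noise_mean_range`, sd `noise_sd`, zeros preserved, samples
#' re-balanced to sum to 1).
#'
#' @param n_taxa,n_phyla,n_timepoints cohort dimensions.
#' @param n_template_subjects subjects generated de novo.
#' @param n_simulated_subjects subjects derived from templates by
#'   perturbation (0 = use templates only).
#' @param sparsity fraction of structurally-zero taxa per subject.
#' @param ar_coefficient AR(1) coefficient of the log-scale trajectories.
#' @param noise_mean_range,noise_sd perturbation noise parameters.
#' @param innovation_sd sd of the AR(1) innovations on the log scale.
#' @param phylum_sd sd of the shared per-phylum drift (induces within-phylum
#'   correlation).
#' @param timepoints optional explicit timepoint vector (months); defaults
#'   to `4, 7, 10, ...`.
#' @param seed integer RNG seed.
#' @return list of class `microgen_sim_spec`.
#' @export
simulation_spec <- function(n_taxa = 60L, n_phyla = 4L, n_timepoints = 8L,
                            n_template_subjects = 30L,
                            n_simulated_subjects = 0L,
                            sparsity = 0.25, ar_coefficient = 0.7,
                            noise_mean_range = c(1e-6, 2e-6),
                            noise_sd = 1e-6, innovation_sd = 1.5,
                            phylum_sd = 0.4, timepoints = NULL,
                            seed = 1L) {
  stopifnot(n_taxa >= 2, n_phyla >= 1, n_timepoints >= 1,
            n_template_subjects >= 1, n_simulated_subjects >= 0,
            sparsity >= 0, sparsity < 1,
            ar_coefficient > 0, ar_coefficient <= 1,
            noise_mean_range[1] <= noise_mean_range[2], noise_sd >= 0,
            innovation_sd >= 0, phylum_sd >= 0)
  if (is.null(timepoints)) timepoints <- 4 + 3 * (seq_len(n_timepoints) - 1)
  structure(list(n_taxa = as.integer(n_taxa), n_phyla = as.integer(n_phyla),
                 n_timepoints = as.integer(n_timepoints),
                 n_template_subjects = as.integer(n_template_subjects),
                 n_simulated_subjects = as.integer(n_simulated_subjects),
                 sparsity = sparsity, ar_coefficient = ar_coefficient,
                 noise_mean_range = noise_mean_range, noise_sd = noise_sd,
                 innovation_sd = innovation_sd, phylum_sd = phylum_sd,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "microgen_sim_spec")
}

#' Generate a fully observed template cohort
#'
#' Per subject: structural zeros are drawn at rate `sparsity` (at least two
#' taxa stay nonzero); the baseline composition of the nonzero taxa comes
#' from a symmetric Dirichlet(1); log-abundances then evolve by an AR(1)
#' process plus a shared per-phylum drift, and each timepoint is
#' renormalized. Structural zeros stay zero at all timepoints.
#'
#' @param spec a [simulation_spec()].
#' @return a fully observed [microgen_dataset()].
#' @export
generate_base_cohort <- function(spec) {
  stopifnot(inherits(spec, "microgen_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_taxa; k <- spec$n_timepoints; S <- spec$n_template_subjects
  phyla <- paste0("P", rep_len(seq_len(spec$n_phyla), n))
  phyla <- sort(phyla) # contiguous blocks, labels P1..P
  taxa <- sprintf("OTU%03d", seq_len(n))
  ab <- array(0, dim = c(S, k, n))
  # persistent per-phylum trend: a random walk shared by all subjects and
  # by the phylum's taxa, emulating the strong cohort-level developmental
  # dynamics of longitudinal (e.g. infant gut) studies; it yields smooth
  # trajectories and within-phylum correlation
  drift <- matrix(stats::rnorm(spec$n_phyla * k, sd = spec$phylum_sd),
                  spec$n_phyla, k)
  drift <- t(apply(drift, 1, cumsum))
  if (spec$n_phyla == 1) drift <- matrix(drift, 1, k)
  for (s in seq_len(S)) {
    nz <- which(stats::runif(n) >= spec$sparsity)
    if (length(nz) < 2)
      stop("sparsity leaves fewer than 2 nonzero taxa for a subject")
    base <- stats::rgamma(length(nz), shape = 1)
    logab <- log(base / sum(base))
    phy_idx <- as.integer(factor(phyla[nz], levels = unique(phyla)))
    lt <- logab
    for (t in seq_len(k)) {
      if (t > 1) {
        eps <- stats::rnorm(length(nz), sd = spec$innovation_sd)
        lt <- spec$ar_coefficient * lt +
          (1 - spec$ar_coefficient) * logab + eps
      }
      v <- exp(lt + drift[phy_idx, t])
      ab[s, t, nz] <- v / sum(v)
    }
  }
  microgen_dataset(ab, spec$timepoints, matrix(1, S, k), taxa, phyla,
                   sprintf("T%03d", seq_len(S)))
}

#' Derive new subjects from a template cohort by small additive noise
#'
#' Each new subject copies a randomly chosen template subject; every nonzero
#' entry receives additive noise `N(mu, noise_sd)` with `mu` drawn once per
#' run uniformly from `noise_mean_range`. Zeros are preserved and the net
#' perturbation is re-balanced in equal shares across the nonzero taxa so
#' each sample still sums to 1; entries pushed negative are clipped to a
#' tiny floor and the deficit re-balanced again.
#'
#' @param template a fully observed [microgen_dataset()].
#' @param n_new number of derived subjects.
#' @param spec a [simulation_spec()] (noise parameters and seed).
#' @return a fully observed [microgen_dataset()] of the derived subjects.
#' @export
perturb_subjects <- function(template, n_new, spec) {
  stopifnot(inherits(template, "microgen_dataset"))
  if (n_new <= 0) stop("n_new must be positive")
  if (any(template$mask == 0)) stop("template must be fully observed")
  set.seed(spec$seed + 1L)
  S0 <- dim(template$abundances)[1]
  k <- dim(template$abundances)[2]; n <- dim(template$abundances)[3]
  mu <- stats::runif(1, spec$noise_mean_range[1], spec$noise_mean_range[2])
  ab <- array(0, dim = c(n_new, k, n))
  src <- sample.int(S0, n_new, replace = TRUE)
  floor_val <- 1e-12
  for (s in seq_len(n_new)) {
    for (t in seq_len(k)) {
      v <- template$abundances[src[s], t, ]
      nz <- which(v > 0)
      w <- v
      w[nz] <- w[nz] + stats::rnorm(length(nz), mean = mu,
                                    sd = spec$noise_sd)
      # re-balance the net change in equal shares over the nonzero taxa
      w[nz] <- w[nz] - (sum(w[nz]) - 1) / length(nz)
      for (rep in 1:10) {
        neg <- nz[w[nz] < floor_val]
        if (!length(neg)) break
        deficit <- sum(floor_val - w[neg])
        w[neg] <- floor_val
        pos <- setdiff(nz, neg)
        w[pos] <- w[pos] - deficit / length(pos)
      }
      ab[s, t, ] <- w
    }
  }
  microgen_dataset(ab, template$timepoints, matrix(1, n_new, k),
                   template$taxon_ids, template$phylum,
                   sprintf("S%03d", seq_len(n_new)))
}

#' Simulate a cohort (templates plus perturbation-derived subjects)
#'
#' @param spec a [simulation_spec()].
#' @return a fully observed [microgen_dataset()] with
#'   `n_template_subjects + n_simulated_subjects` subjects.
#' @export
simulate_cohort <- function(spec) {
  tmpl <- generate_base_cohort(spec)
  if (spec$n_simulated_subjects == 0) return(tmpl)
  per <- perturb_subjects(tmpl, spec$n_simulated_subjects, spec)
  ab <- array(0, dim = c(dim(tmpl$abundances)[1] + dim(per$abundances)[1],
                         dim(tmpl$abundances)[2], dim(tmpl$abundances)[3]))
  ab[seq_len(dim(tmpl$abundances)[1]), , ] <- tmpl$abundances
  ab[-seq_len(dim(tmpl$abundances)[1]), , ] <- per$abundances
  microgen_dataset(ab, tmpl$timepoints,
                   matrix(1, dim(ab)[1], dim(ab)[2]), tmpl$taxon_ids,
                   tmpl$phylum,
                   c(tmpl$subject_ids, per$subject_ids))
}

#' Missingness specification
#'
#' @param mechanism `MCAR`, `MAR` or `MNAR`.
#' @param rate target fraction of samples made missing, in (0, 1).
#' @param patterns list of integer timepoint subsets eligible for
#'   amputation; defaults to all timepoints for MCAR and the interior
#'   timepoints for MAR/MNAR (so scoring variables remain).
#' @param weights per-timepoint weights of the weighted-sum score (before
#'   the mechanism's zero-weight convention); default all 1.
#' @param seed integer RNG seed.
#' @return list of class `microgen_missing_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             rate = 0.2, patterns = NULL, weights = NULL,
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate > 0, rate < 1)
  structure(list(mechanism = mechanism, rate = rate, patterns = patterns,
                 weights = weights, seed = as.integer(seed)),
            class = "microgen_missing_spec")
}

#' Apply MCAR/MAR/MNAR missingness to a fully observed cohort
#'
#' Subjects are split uniformly among the amputation patterns; the samples
#' of a subject's pattern are the amputation candidates. Under MCAR every
#' candidate is amputed independently with equal probability, tuned so the
#' expected missing fraction over all samples equals `rate`. Under MAR/MNAR
#' a weighted-sum score of standardized per-sample summaries (mean clr per
#' sample) is computed per subject — over the timepoints that remain
#' observed for MAR (amputed variables weighted 0) and over the candidate
#' timepoints for MNAR (observed variables weighted 0) — and converted to an
#' amputation probability through a logistic curve whose offset is tuned by
#' bisection to hit the target rate. Amputed samples are zeroed and their
#' mask set to 0; a subject that would lose every sample keeps its last
#' observed one.
#'
#' @param ds a fully observed [microgen_dataset()] (the caller retains it as
#'   ground truth).
#' @param mspec a [missingness_spec()].
#' @return a [microgen_dataset()] with the amputed mask.
#' @export
ampute <- function(ds, mspec) {
  stopifnot(inherits(ds, "microgen_dataset"),
            inherits(mspec, "microgen_missing_spec"))
  if (any(ds$mask == 0)) stop("ampute expects a fully observed dataset")
  set.seed(mspec$seed)
  S <- dim(ds$abundances)[1]; k <- dim(ds$abundances)[2]
  patterns <- mspec$patterns
  if (is.null(patterns)) {
    patterns <- if (mspec$mechanism == "MCAR") list(seq_len(k))
                else list(setdiff(seq_len(k), c(1L, k)))
  }
  if (!length(patterns)) stop("need at least one pattern")
  weights <- mspec$weights
  if (is.null(weights)) weights <- rep(1, k)

  # per-sample summary variable: mean clr value of the sample
  summ <- matrix(0, S, k)
  pcds <- add_pseudocount(ds)
  cl <- clr_transform(pcds)
  for (s in seq_len(S)) for (t in seq_len(k))
    summ[s, t] <- mean(cl$clr_values[s, t, ])
  summ <- scale(summ)

  assign <- sample(rep_len(seq_along(patterns), S))
  cand <- matrix(FALSE, S, k)
  score <- matrix(0, S, k)
  for (s in seq_len(S)) {
    pat <- patterns[[assign[s]]]
    cand[s, pat] <- TRUE
    w <- weights
    if (mspec$mechanism == "MAR") w[pat] <- 0
    if (mspec$mechanism == "MNAR") w[setdiff(seq_len(k), pat)] <- 0
    score[s, pat] <- sum(w * summ[s, ])
  }
  n_cand <- sum(cand)
  target <- mspec$rate * S * k
  if (target > n_cand + 1e-9)
    stop("requested rate unreachable with the given patterns")

  if (mspec$mechanism == "MCAR") {
    q <- target / n_cand
    if (length(patterns) == 1 && length(patterns[[1]]) == k && q < 1) {
      # a subject drawing all k amputations keeps its last sample; solve
      # q - q^k / k = rate so the expected realized fraction still matches
      q <- stats::uniroot(function(x) x - x^k / k - target / n_cand,
                          c(q, min(1, q + 0.2)), extendInt = "upX")$root
    }
    prob <- matrix(0, S, k)
    prob[cand] <- q
  } else {
    sc <- score[cand]
    f <- function(a) mean(stats::plogis(a + sc)) - target / n_cand
    lo <- -50; hi <- 50
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    prob <- matrix(0, S, k)
    prob[cand] <- stats::plogis((lo + hi) / 2 + sc)
  }
  mask <- matrix(1, S, k)
  u <- matrix(stats::runif(S * k), S, k)
  mask[cand & (u < prob)] <- 0
  # never strip a subject entirely
  for (s in seq_len(S)) if (all(mask[s, ] == 0)) {
    mask[s, k] <- 1
    message("subject ", s, " would lose all samples; keeping its last one")
  }
  ab <- ds$abundances
  for (s in seq_len(S)) for (t in seq_len(k))
    if (mask[s, t] == 0) ab[s, t, ] <- 0
  microgen_dataset(ab, ds$timepoints, mask, ds$taxon_ids, ds$phylum,
                   ds$subject_ids)
}
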