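#' Training configuration
#'
#' Defaults follow the published schedule: Adam with learning rate 1e-3 for
#' both networks, five discriminator iterations per generator update, early
#' stopping when the generator total loss has not reached a new minimum for
#' 1000 consecutive epochs, full-batch updates.
#'
#' @param learning_rate Adam learning rate for both networks.
#' @param d_steps_per_g_step discriminator iterations per generator update.
#' @param patience_epochs epochs without a new generator-loss minimum before
#'   stopping (0 = stop after one epoch).
#' @param max_epochs hard cap on epochs.
#' @param seed integer RNG seed for initialization and dropout.
#' @return list of class `microgen_train_config`.
#' @export
training_config <- function(learning_rate = 1e-3, d_steps_per_g_step = 5L,
                            patience_epochs = 1000L, max_epochs = 20000L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, d_steps_per_g_step >= 1, patience_epochs >= 0,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "microgen_train_config")
}

#' Generator loss
#'
#' `lossG = -log D(x_bar (*) (1-e))` (adversarial), `lossR = sum_i ||(x_.i -
#' x_tilde_.i) e_i||_1 / ||e||_1` (L1 reconstruction on observed samples,
#' normalized by the observed count), `lossC = (1/k) sum_i ||x_tilde_f -
#' x_tilde_b||_1` (forward/backward consistency); the total is their
#' unweighted sum, averaged over subjects.
#'
#' @param x clr array `[S, k, n]`; @param e `S x k` mask.
#' @param outputs a [generate()] result.
#' @param d_fake_prob length-S discriminator probabilities on the fake
#'   branch.
#' @return list `total`, `lossG`, `lossR`, `lossC`.
#' @export
generator_loss <- function(x, e, outputs, d_fake_prob) {
  S <- dim(x)[1]; k <- dim(x)[2]
  if (all(e == 0)) stop("no observed samples (||e||_1 = 0)")
  p <- pmin(pmax(d_fake_prob, 1e-7), 1 - 1e-7)
  lossG <- mean(-log(p))
  lr <- 0; lc <- 0
  for (s in seq_len(S)) {
    ne <- sum(e[s, ])
    if (ne > 0) {
      r <- 0
      for (i in seq_len(k)) if (e[s, i] == 1)
        r <- r + sum(abs(x[s, i, ] - outputs$x_tilde[s, i, ]))
      lr <- lr + r / ne
    }
    lc <- lc + sum(abs(outputs$x_tilde_f[s, , ] -
                       outputs$x_tilde_b[s, , ])) / k
  }
  lossR <- lr / S; lossC <- lc / S
  list(total = lossG + lossR + lossC, lossG = lossG, lossR = lossR,
       lossC = lossC)
}

#' Discriminator loss
#'
#' `lossD = -log D(real) - log(1 - D(fake))` (binary cross-entropy) plus the
#' timepoint cross-entropy `lossT = -sum_i y(i) log yhat(i)` with one-hot
#' targets equal to the timestep indices, both averaged over subjects.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param d_real_prob,d_fake_prob length-S probability vectors.
#' @param timepoint_probs `[S, k, k]` softmax output.
#' @param true_timepoints integer vector of target classes per timestep
#'   (default `1:k`).
#' @return list `total`, `lossD`, `lossT`.
#' @export
discriminator_loss <- function(d_real_prob, d_fake_prob, timepoint_probs,
                               true_timepoints = NULL) {
  pr <- pmin(pmax(d_real_prob, 1e-7), 1 - 1e-7)
  pf <- pmin(pmax(d_fake_prob, 1e-7), 1 - 1e-7)
  lossD <- mean(-log(pr) - log(1 - pf))
  k <- dim(timepoint_probs)[2]
  if (is.null(true_timepoints)) true_timepoints <- seq_len(k)
  lt <- 0
  for (s in seq_len(dim(timepoint_probs)[1]))
    for (i in seq_len(k))
      lt <- lt - log(max(timepoint_probs[s, i, true_timepoints[i]], 1e-7))
  lossT <- lt / dim(timepoint_probs)[1]
  list(total = lossD + lossT, lossD = lossD, lossT = lossT)
}

#' Train the adversarial imputation model
#'
#' Full-batch adversarial training: per epoch the discriminator takes
#' `d_steps_per_g_step` Adam steps (binary cross-entropy on real/fake plus
#' timepoint cross-entropy on the real branch) and the generator one Adam
#' step on `lossG + lossR + lossC`. Training stops when the generator total
#' loss has not reached a new minimum for `patience_epochs` epochs; the
#' best-loss weights are restored. Fully reproducible given the seed.
#'
#' @param clr a `microgen_clr` object.
#' @param gaps result of [time_gap_matrices()]; computed from the source
#'   dataset when `NULL`.
#' @param cluster_map a `microgen_cluster_map` (built from `clr` when
#'   `NULL`).
#' @param gcfg,dcfg,tcfg configurations.
#' @param variant `"full"` (CNN + discriminator), `"bigan"` (no CNN), or
#'   `"rnn"` (no CNN, no discriminator; reconstruction-only training).
#' @return A `microgen_model`: parameter vectors, configs, cluster map,
#'   pseudo-count, per-epoch loss history (data.frame), and stopping info.
#' @export
train_microgen <- function(clr, gaps = NULL, cluster_map = NULL,
                           gcfg = generator_config(),
                           dcfg = discriminator_config(),
                           tcfg = training_config(),
                           variant = c("full", "bigan", "rnn")) {
  stopifnot(inherits(clr, "microgen_clr"))
  variant <- match.arg(variant)
  ds <- clr$source
  if (is.null(gaps)) gaps <- time_gap_matrices(ds)
  if (is.null(cluster_map)) cluster_map <- build_cluster_map(clr)
  if (nrow(ds$mask) < 2 || any(rowSums(ds$mask) < 1))
    stop("need >= 2 subjects, each with >= 1 observed sample")
  if (variant != "full") gcfg$use_cnn <- FALSE
  use_disc <- variant != "rnn"

  fit <- cpp_train(clr_to_cube(clr$clr_values), ds$mask, gaps$delta_f,
                   gaps$delta_b, cluster_list(cluster_map), unclass(gcfg),
                   dcfg$lstm_units, use_disc, tcfg$learning_rate,
                   tcfg$d_steps_per_g_step, tcfg$patience_epochs,
                   tcfg$max_epochs, tcfg$seed, numeric(0))
  hist <- as.data.frame(fit$history)
  names(hist) <- c("lossD", "lossT", "disc_total", "lossG", "lossR",
                   "lossC", "gen_total")
  hist$epoch <- seq_len(nrow(hist))
  if (isTRUE(fit$max_epochs_hit))
    message("training hit the max_epochs cap (", tcfg$max_epochs, ")")
  structure(list(theta_g = as.numeric(fit$theta_g),
                 theta_d = as.numeric(fit$theta_d),
                 gcfg = gcfg, dcfg = dcfg, tcfg = tcfg, variant = variant,
                 use_disc = use_disc,
                 cluster_map = cluster_map,
                 taxon_ids = ds$taxon_ids,
                 timepoints = ds$timepoints,
                 pseudo_count = clr$pseudo_count,
                 history = hist,
                 best_epoch = fit$best_epoch,
                 best_loss = fit$best_loss,
                 epochs_run = fit$epochs_run),
            class = "microgen_model")
}

#' @export
print.microgen_model <- function(x, ...) {
  cat(sprintf("microgen_model (variant '%s'): %d generator + %d discriminator parameters\n",
              x$variant, length(x$theta_g), length(x$theta_d)))
  cat(sprintf("  trained %d epochs, best generator loss %.4f at epoch %d\n",
              x$epochs_run, x$best_loss, x$best_epoch))
  invisible(x)
}

#' Impute missing samples with a trained model
#'
#' Runs the generator in inference mode (dropout disabled) and returns the
#' observed-value-preserving imputation on the clr scale.
#'
#' @param model a `microgen_model`.
#' @param clr a `microgen_clr` with the same taxa as the training data.
#' @param gaps time-gap matrices (computed when `NULL`).
#' @return A `microgen_imputation`: `clr` array `[S, k, n]`, the mask, the
#'   pseudo-count and the method label.
#' @export
impute_microgen <- function(model, clr, gaps = NULL) {
  stopifnot(inherits(model, "microgen_model"), inherits(clr, "microgen_clr"))
  ds <- clr$source
  if (!identical(model$taxon_ids, ds$taxon_ids))
    stop("taxon set differs from the model checkpoint")
  if (is.null(gaps)) gaps <- time_gap_matrices(ds)
  out <- generate(clr$clr_values, ds$mask, gaps$delta_f, gaps$delta_b,
                  model$cluster_map, model$gcfg, theta = model$theta_g,
                  training = FALSE, seed = model$tcfg$seed)
  new_imputation(out$x_bar, ds$mask, clr$pseudo_count, model$variant)
}

new_imputation <- function(clr_arr, mask, pseudo_count, method) {
  structure(list(clr = clr_arr, mask = mask, pseudo_count = pseudo_count,
                 method = method),
            class = "microgen_imputation")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a JSON file holding all weights, both configs, the
#' cluster map, taxon ids, timepoints and the pseudo-count, so imputation is
#' reproducible from the checkpoint alone.
#'
#' @param model a `microgen_model`; @param path file path.
#' @export
write_checkpoint <- function(model, path) {
  obj <- model
  obj$history <- NULL
  obj$cluster_map <- list(clusters = lapply(model$cluster_map$clusters,
                                            as.integer),
                          rho_bar = model$cluster_map$rho_bar,
                          taxon_ids = model$cluster_map$taxon_ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$gcfg <- structure(as.list(obj$gcfg), class = "microgen_gen_config")
  obj$gcfg$conv_filters <- as.integer(obj$gcfg$conv_filters)
  obj$dcfg <- structure(as.list(obj$dcfg), class = "microgen_disc_config")
  obj$tcfg <- structure(as.list(obj$tcfg), class = "microgen_train_config")
  obj$cluster_map <- structure(list(
      clusters = lapply(obj$cluster_map$clusters, as.integer),
      rho_bar = obj$cluster_map$rho_bar,
      taxon_ids = obj$cluster_map$taxon_ids),
    class = "microgen_cluster_map")
  structure(obj, class = "microgen_model")
}
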