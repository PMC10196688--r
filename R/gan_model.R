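#' Generator configuration
#'
#' Architecture of the imputation generator: per-phylum-cluster 1D
#' convolutions (kernel 3, 16 then 8 filters, each followed by LeakyReLU and
#' max-pooling), a one-layer bidirectional tanh RNN, and per-direction linear
#' output layers. Clusters smaller than the kernel bypass the convolution and
#' contribute their clr values directly as features.
#'
#' @param kernel_size convolution kernel width along the ordered-taxon axis.
#' @param conv_filters integer pair: filters of the first and second layer.
#' @param dropout_rate fraction of CNN feature units dropped during
#'   training (inverted dropout; inference is deterministic). The published
#'   setting of this model family ("0.7" under TensorFlow 1.x, whose dropout
#'   argument is the keep probability) corresponds to a drop fraction of
#'   0.3, the default here.
#' @param rnn_hidden hidden-state size of each RNN direction.
#' @param leaky_relu_slope negative-side slope of the LeakyReLU.
#' @param pool_size max-pooling width (ceil semantics at the edge).
#' @param use_cnn if `FALSE`, skip feature extraction and feed raw clr values
#'   to the RNN (the "bigan"/"rnn" ablation variants).
#' @return list of class `microgen_gen_config`.
#' @export
generator_config <- function(kernel_size = 3L, conv_filters = c(16L, 8L),
                             dropout_rate = 0.3, rnn_hidden = 32L,
                             leaky_relu_slope = 0.2, pool_size = 2L,
                             use_cnn = TRUE) {
  stopifnot(kernel_size >= 1, dropout_rate >= 0, dropout_rate < 1,
            length(conv_filters) == 2, pool_size >= 1, rnn_hidden >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 conv_filters = as.integer(conv_filters),
                 dropout_rate = dropout_rate,
                 rnn_hidden = as.integer(rnn_hidden),
                 leaky_relu_slope = leaky_relu_slope,
                 pool_size = as.integer(pool_size),
                 use_cnn = isTRUE(use_cnn)),
            class = "microgen_gen_config")
}

#' Discriminator configuration
#'
#' @param lstm_units number of LSTM units.
#' @return list of class `microgen_disc_config`.
#' @export
discriminator_config <- function(lstm_units = 10L) {
  stopifnot(lstm_units >= 1)
  structure(list(lstm_units = as.integer(lstm_units)),
            class = "microgen_disc_config")
}

# clr array [S,k,n] -> cube (k,n,S) expected by the C++ core
clr_to_cube <- function(arr) aperm(arr, c(2, 3, 1))
cube_to_arr <- function(cb) aperm(cb, c(3, 1, 2))

cluster_list <- function(cluster_map) {
  unname(lapply(cluster_map$clusters, as.integer))
}

#' Initialize generator and discriminator weights
#'
#' Glorot-uniform weight matrices, zero biases (LSTM forget bias 1), and
#' decay-factor parameters starting at zero so both combination factors begin
#' at 1.
#'
#' @param cluster_map a `microgen_cluster_map`.
#' @param k number of timepoints; @param n number of taxa.
#' @param gcfg,dcfg configurations; @param seed integer RNG seed.
#' @return list with numeric parameter vectors `theta_g`, `theta_d` and the
#'   feature dimension `d`.
#' @export
init_gan_params <- function(cluster_map, k, n, gcfg = generator_config(),
                            dcfg = discriminator_config(), seed = 1L) {
  g <- cpp_gen_init(cluster_list(cluster_map), k, n, unclass(gcfg),
                    as.integer(seed), numeric(0))
  d <- cpp_disc_init(as.integer(k), as.integer(n), dcfg$lstm_units,
                     as.integer(seed) + 1L)
  list(theta_g = as.numeric(g$theta), theta_d = as.numeric(d$theta),
       d = g$d)
}

#' Extract per-timepoint CNN features from one clr sample sequence
#'
#' Applies the per-cluster convolutional module to a `k x n` clr matrix
#' (rows = timepoints, columns = taxa) and returns the concatenated
#' per-timepoint feature matrix. Clusters smaller than the kernel contribute
#' their raw clr values.
#'
#' @param clr_seq numeric `k x n` matrix.
#' @param cluster_map a `microgen_cluster_map`.
#' @param cfg a [generator_config()].
#' @param theta generator parameter vector; fresh Glorot weights drawn from
#'   `seed` when `NULL`.
#' @param training apply dropout (default `FALSE`).
#' @param seed RNG seed for weight draw / dropout.
#' @return `k x d` feature matrix.
#' @export
extract_features <- function(clr_seq, cluster_map, cfg = generator_config(),
                             theta = NULL, training = FALSE, seed = 1L) {
  clr_seq <- as.matrix(clr_seq)
  k <- nrow(clr_seq); n <- ncol(clr_seq)
  if (length(unlist(cluster_map$clusters)) != n)
    stop("cluster map inconsistent with the number of taxa")
  if (is.null(theta))
    theta <- cpp_gen_init(cluster_list(cluster_map), k, n, unclass(cfg),
                          as.integer(seed), numeric(0))$theta
  X <- array(clr_seq, dim = c(k, n, 1))
  z <- matrix(0, 1, k)
  out <- cpp_gen_forward(theta, X, matrix(1, 1, k), z, z,
                         cluster_list(cluster_map), unclass(cfg),
                         training, as.integer(seed))
  out$features[, , 1, drop = TRUE]
}

#' Temporal decay factor
#'
#' `lambda = exp(-ReLU(W * delta + b))`, elementwise over a gap vector; lies
#' in (0, 1], equals 1 when `W = b = 0`, and decays with the gap when
#' `W >= 0`.
#'
#' @param delta nonnegative numeric vector of time gaps.
#' @param W,b scalar weight and bias.
#' @return numeric vector in (0, 1].
#' @export
decay_factor <- function(delta, W, b) {
  stopifnot(all(delta >= 0))
  exp(-pmax(W * delta + b, 0))
}

#' Run the generator on a masked clr tensor
#'
#' Produces the forward/backward generated tensors, their decay-weighted
#' combination `x_tilde`, and the final imputation `x_bar = x (*) e +
#' x_tilde (*) (1 - e)` which reproduces the input exactly at observed
#' samples for any weight setting.
#'
#' @param x numeric array `[S, k, n]` of clr values (missing samples zero).
#' @param e binary `S x k` observation mask.
#' @param delta_f,delta_b `S x k` time-gap matrices.
#' @param cluster_map a `microgen_cluster_map`.
#' @param cfg a [generator_config()].
#' @param theta generator parameters (random from `seed` when `NULL`).
#' @param training apply dropout.
#' @param seed RNG seed.
#' @return list with arrays `x_tilde_f`, `x_tilde_b`, `x_tilde`, `x_bar`
#'   (`[S, k, n]`) and matrices `lambda_f`, `lambda_b` (`S x k`).
#' @export
generate <- function(x, e, delta_f, delta_b, cluster_map,
                     cfg = generator_config(), theta = NULL,
                     training = FALSE, seed = 1L) {
  stopifnot(length(dim(x)) == 3)
  k <- dim(x)[2]; n <- dim(x)[3]
  if (length(unlist(cluster_map$clusters)) != n)
    stop("cluster map inconsistent with the number of taxa")
  if (is.null(theta))
    theta <- cpp_gen_init(cluster_list(cluster_map), k, n, unclass(cfg),
                          as.integer(seed), numeric(0))$theta
  out <- cpp_gen_forward(theta, clr_to_cube(x), e, delta_f, delta_b,
                         cluster_list(cluster_map), unclass(cfg),
                         training, as.integer(seed))
  list(x_tilde_f = cube_to_arr(out$x_tilde_f),
       x_tilde_b = cube_to_arr(out$x_tilde_b),
       x_tilde = cube_to_arr(out$x_tilde),
       x_bar = cube_to_arr(out$x_bar),
       lambda_f = out$lambda_f, lambda_b = out$lambda_b)
}

#' Run the discriminator
#'
#' A 10-unit (by default) LSTM over the timepoint axis; the final hidden
#' state feeds a sigmoid real/fake head and every hidden state feeds a
#' softmax head predicting its own timepoint index.
#'
#' @param x_masked numeric array `[S, k, n]`: `x_bar (*) e` for the real
#'   branch or `x_bar (*) (1 - e)` for the fake branch.
#' @param cfg a [discriminator_config()].
#' @param theta discriminator parameters (random from `seed` when `NULL`).
#' @param seed RNG seed for the weight draw.
#' @return list with `p_real` (length-S vector in (0,1)) and
#'   `timepoint_probs` (`[S, k, k]`, rows summing to 1).
#' @export
discriminate <- function(x_masked, cfg = discriminator_config(),
                         theta = NULL, seed = 1L) {
  stopifnot(length(dim(x_masked)) == 3)
  k <- dim(x_masked)[2]; n <- dim(x_masked)[3]
  if (is.null(theta))
    theta <- cpp_disc_init(k, n, cfg$lstm_units, as.integer(seed))$theta
  out <- cpp_disc_forward(theta, clr_to_cube(x_masked), cfg$lstm_units)
  list(p_real = as.numeric(out$p_real),
       timepoint_probs = cube_to_arr(out$timepoint_probs))
}
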