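#' Baseline imputer specification
#'
#' @param method one of `mean`, `median`, `linear`, `cubic`,
#'   `moving_window`, `mice`, `locf`.
#' @param window odd window width for `moving_window`.
#' @param mice_iterations chained-equation sweeps for `mice`.
#' @return list of class `microgen_baseline_spec`.
#' @export
baseline_spec <- function(method = c("mean", "median", "linear", "cubic",
                                     "moving_window", "mice", "locf"),
                          window = 3L, mice_iterations = 10L) {
  method <- match.arg(method)
  stopifnot(window >= 1, window %% 2 == 1, mice_iterations >= 1)
  structure(list(method = method, window = as.integer(window),
                 mice_iterations = as.integer(mice_iterations)),
            class = "microgen_baseline_spec")
}

#' Impute missing samples with a classical baseline
#'
#' All baselines operate per subject per taxon on the clr scale, pass
#' observed entries through unchanged, and share the missingness mask of the
#' input. Subjects with a single observed timepoint fall back to the cohort
#' mean profile at that timepoint where a within-subject statistic is
#' degenerate (linear/cubic/moving-window/locf all reduce to the one observed
#' value there).
#'
#' @param clr a `microgen_clr` object.
#' @param mask optional `S x k` mask (defaults to the source dataset's).
#' @param spec a [baseline_spec()].
#' @return A `microgen_imputation` on the clr scale.
#' @export
impute_baseline <- function(clr, mask = NULL, spec = baseline_spec()) {
  stopifnot(inherits(clr, "microgen_clr"),
            inherits(spec, "microgen_baseline_spec"))
  if (is.null(mask)) mask <- clr$source$mask
  x <- clr$clr_values
  S <- dim(x)[1]; k <- dim(x)[2]; n <- dim(x)[3]
  tt <- clr$source$timepoints
  out <- x
  if (any(rowSums(mask) < 1))
    stop("every subject needs at least one observed timepoint")

  if (spec$method == "mice") {
    out <- impute_mice(x, mask, spec$mice_iterations)
  } else {
    for (s in seq_len(S)) {
      obs <- which(mask[s, ] == 1)
      mis <- which(mask[s, ] == 0)
      if (!length(mis)) next
      for (j in seq_len(n)) {
        v <- x[s, , j]
        out[s, mis, j] <- impute_series(v, tt, obs, mis, spec)
      }
    }
  }
  # observed-entry passthrough, whatever the method did
  for (s in seq_len(S)) for (i in seq_len(k))
    if (mask[s, i] == 1) out[s, i, ] <- x[s, i, ]
  new_imputation(out, mask, clr$pseudo_count, spec$method)
}

impute_series <- function(v, tt, obs, mis, spec) {
  vo <- v[obs]; to <- tt[obs]; tm <- tt[mis]
  switch(spec$method,
    mean = rep(mean(vo), length(mis)),
    median = rep(stats::median(vo), length(mis)),
    locf = vapply(tm, function(t) {
      prev <- to[to < t]
      if (length(prev)) vo[which.max(prev)] else vo[which.min(to)]
    }, numeric(1)),
    moving_window = vapply(mis, function(i) {
      half <- (spec$window - 1) / 2
      w <- obs[abs(obs - i) <= half]
      if (!length(w)) w <- obs[which.min(abs(obs - i))]
      mean(v[w])
    }, numeric(1)),
    linear = poly_impute(vo, to, tm, order = 1),
    cubic = poly_impute(vo, to, tm, order = 3),
    stop("unknown method: ", spec$method))
}

# polynomial interpolation with order reduction and nearest-value
# extrapolation at the edges
poly_impute <- function(vo, to, tm, order) {
  ord <- min(order, length(to) - 1)
  out <- numeric(length(tm))
  inside <- tm >= min(to) & tm <= max(to)
  out[tm < min(to)] <- vo[which.min(to)]
  out[tm > max(to)] <- vo[which.max(to)]
  if (any(inside)) {
    if (ord == 0) {
      out[inside] <- vo[1]
    } else if (ord == 1) {
      out[inside] <- stats::approx(to, vo, xout = tm[inside])$y
    } else {
      # with exactly ord+1 observed points this is the unique interpolating
      # polynomial; with more, the least-squares fit of that order
      fit <- stats::lm.fit(cbind(1, outer(to, seq_len(ord), `^`)), vo)
      X <- cbind(1, outer(tm[inside], seq_len(ord), `^`))
      out[inside] <- drop(X %*% fit$coefficients)
    }
  }
  out
}

# deterministic chained-equation regression imputation: per taxon, subjects
# as rows, timepoints as columns; mean-initialized, `iter` sweeps, single
# imputation, no posterior draws
impute_mice <- function(x, mask, iter) {
  S <- dim(x)[1]; k <- dim(x)[2]; n <- dim(x)[3]
  out <- x
  for (j in seq_len(n)) {
    M <- x[, , j, drop = TRUE]
    if (S == 1) M <- matrix(M, 1, k)
    miss <- mask == 0
    for (t in seq_len(k)) {
      mt <- miss[, t]
      if (any(mt)) {
        mu <- mean(M[!mt, t])
        if (!is.finite(mu)) mu <- 0
        M[mt, t] <- mu
      }
    }
    if (k >= 2) {
      for (sweep in seq_len(iter)) {
        for (t in seq_len(k)) {
          mt <- miss[, t]
          if (!any(mt) || sum(!mt) < 2) next
          X <- cbind(1, M[, -t, drop = FALSE])
          fit <- stats::lm.fit(X[!mt, , drop = FALSE], M[!mt, t])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          M[mt, t] <- drop(X[mt, , drop = FALSE] %*% beta)
        }
      }
    }
    out[, , j] <- M
  }
  out
}

#' Run every baseline imputer
#'
#' @param clr a `microgen_clr`; @param mask optional mask override.
#' @return named list of `microgen_imputation`, one per method; a method
#'   that errors is dropped with a warning.
#' @export
run_all_baselines <- function(clr, mask = NULL) {
  methods <- c("mean", "median", "linear", "cubic", "moving_window",
               "mice", "locf")
  out <- list()
  for (m in methods) {
    res <- tryCatch(impute_baseline(clr, mask, baseline_spec(m)),
                    error = function(e) {
                      warning("baseline '", m, "' failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) out[[m]] <- res
  }
  out
}
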