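#' Partition taxa into phylum clusters
#'
#' One cluster per distinct phylum label; singleton phyla are allowed.
#' Clusters are returned in order of first appearance of the phylum.
#'
#' @param ds a [microgen_dataset()].
#' @return named list mapping phylum to an integer vector of taxon indices.
#' @export
cluster_by_phylum <- function(ds) {
  phy <- ds$phylum
  bad <- which(is.na(phy) | phy == "")
  if (length(bad))
    stop("taxa without a phylum label: ",
         paste(ds$taxon_ids[bad], collapse = ", "))
  idx <- split(seq_along(phy), factor(phy, levels = unique(phy)))
  lapply(idx, as.integer)
}

#' Spearman correlation matrix for a taxon cluster
#'
#' Rank correlations are computed on clr values over all observed samples
#' pooled across subjects and timepoints. A taxon constant across all
#' observed samples has undefined rank correlation; its off-diagonal entries
#' are set to 0 with a warning.
#'
#' @param clr a `microgen_clr` object.
#' @param cluster integer vector of taxon indices.
#' @return symmetric `p x p` correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(clr, cluster) {
  X <- pooled_observed_clr(clr)[, cluster, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 observed samples")
  const <- apply(X, 2, function(v) max(v) == min(v))
  R <- suppressWarnings(stats::cor(X, method = "spearman"))
  if (any(const)) {
    warning("constant taxa in cluster; their correlations set to 0")
    R[const, ] <- 0; R[, const] <- 0
  }
  diag(R) <- 1
  R
}

# observed samples as rows of an (#observed) x n matrix
pooled_observed_clr <- function(clr) {
  obs <- which(clr$source$mask == 1, arr.ind = TRUE)
  t(vapply(seq_len(nrow(obs)),
           function(r) clr$clr_values[obs[r, 1], obs[r, 2], ],
           numeric(dim(clr$clr_values)[3])))
}

#' Geometric mean of absolute Spearman correlations for one taxon
#'
#' `(|rho_j1 * ... * rho_jp|)^(1/p)` over all p entries of the taxon's row of
#' the cluster correlation matrix, self-correlation included.
#'
#' @param rho_row numeric vector of correlations.
#' @return scalar in `[0, 1]`.
#' @export
geometric_mean_rho <- function(rho_row) {
  p <- length(rho_row)
  stopifnot(p >= 1)
  abs(prod(rho_row))^(1 / p)
}

#' Order taxa of one cluster by decreasing geometric-mean correlation
#'
#' Ties are broken by taxon-id lexicographic order so the ordering is
#' deterministic.
#'
#' @param cluster integer vector of taxon indices.
#' @param rho_bar numeric vector of geometric-mean correlations, parallel to
#'   `cluster`.
#' @param taxon_ids character vector of all taxon ids (for the tie-break).
#' @return the cluster indices reordered.
#' @export
order_otus <- function(cluster, rho_bar, taxon_ids) {
  stopifnot(length(cluster) == length(rho_bar))
  cluster[order(-rho_bar, taxon_ids[cluster], method = "radix")]
}

#' Build the phylum cluster map with within-cluster correlation ordering
#'
#' Combines [cluster_by_phylum()], [spearman_matrix()],
#' [geometric_mean_rho()] and [order_otus()]: taxa are partitioned by phylum
#' and each cluster is sorted by decreasing geometric mean of absolute
#' Spearman correlation so that correlated taxa are adjacent for the
#' convolutional feature extractor.
#'
#' @param clr a `microgen_clr` object.
#' @return A `microgen_cluster_map`: list with `clusters` (named list of
#'   ordered index vectors), `rho_bar` (per-taxon), and `taxon_ids`.
#' @export
build_cluster_map <- function(clr) {
  ds <- clr$source
  clusters <- cluster_by_phylum(ds)
  rho_bar <- rep(NA_real_, length(ds$taxon_ids))
  ordered <- lapply(clusters, function(idx) {
    if (length(idx) == 1) {
      rho_bar[idx] <<- 1
      return(idx)
    }
    R <- spearman_matrix(clr, idx)
    rb <- apply(R, 1, geometric_mean_rho)
    rho_bar[idx] <<- rb
    order_otus(idx, rb, ds$taxon_ids)
  })
  structure(list(clusters = ordered, rho_bar = rho_bar,
                 taxon_ids = ds$taxon_ids),
            class = "microgen_cluster_map")
}

#' Serialize a cluster map to JSON (phylum -> ordered taxon ids)
#'
#' @param cm a `microgen_cluster_map`.
#' @param path output file path.
#' @export
write_cluster_map <- function(cm, path) {
  obj <- lapply(cm$clusters, function(idx) cm$taxon_ids[idx])
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
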