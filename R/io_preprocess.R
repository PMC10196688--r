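#' @useDynLib microgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a longitudinal microbiome dataset
#'
#' Bundles a subject x timepoint x taxon relative-abundance tensor with its
#' observation mask, timepoints and taxonomy into a validated
#' `microgen_dataset`. Missing samples (mask 0) are stored as all-zero taxon
#' vectors; observed samples must be compositions (nonnegative, summing to 1).
#'
#' @param abundances numeric array `[S, k, n]` of relative abundances.
#' @param timepoints strictly increasing numeric vector of length `k`, in
#'   study-time units (e.g. months).
#' @param mask binary `S x k` matrix; 1 = sample observed.
#' @param taxon_ids character vector of `n` taxon identifiers.
#' @param phylum character vector of `n` phylum labels, parallel to
#'   `taxon_ids`.
#' @param subject_ids character vector of `S` subject identifiers.
#' @return A `microgen_dataset` list with the fields above.
#' @export
microgen_dataset <- function(abundances, timepoints, mask, taxon_ids,
                             phylum, subject_ids) {
  stopifnot(is.array(abundances), length(dim(abundances)) == 3)
  S <- dim(abundances)[1]; k <- dim(abundances)[2]; n <- dim(abundances)[3]
  if (length(timepoints) != k) stop("timepoints length must equal dim 2")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(S, k))) stop("mask must be S x k")
  if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
  if (length(taxon_ids) != n || length(phylum) != n)
    stop("taxon_ids and phylum must have length n")
  if (length(subject_ids) != S) stop("subject_ids must have length S")
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  for (s in seq_len(S)) for (t in seq_len(k)) {
    v <- abundances[s, t, ]
    if (mask[s, t] == 1) {
      if (abs(sum(v) - 1) > 1e-6)
        stop(sprintf("observed sample (subject %d, timepoint %d) does not sum to 1", s, t))
    } else if (any(v != 0)) {
      stop("missing samples must be stored as zero vectors")
    }
  }
  structure(list(abundances = abundances, timepoints = as.numeric(timepoints),
                 mask = mask, taxon_ids = as.character(taxon_ids),
                 phylum = as.character(phylum),
                 subject_ids = as.character(subject_ids)),
            class = "microgen_dataset")
}

#' @export
print.microgen_dataset <- function(x, ...) {
  d <- dim(x$abundances)
  cat(sprintf("microgen_dataset: %d subjects x %d timepoints x %d taxa\n",
              d[1], d[2], d[3]))
  cat(sprintf("  observed samples: %d / %d (%.1f%% missing)\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask == 0)))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  phyla: %s\n", paste(unique(x$phylum), collapse = ", ")))
  invisible(x)
}

#' Read an OTU table, metadata and taxonomy into a longitudinal dataset
#'
#' The OTU table is a TSV with taxa as rows (first column taxon ids) and
#' samples as columns; metadata maps each sample column to a subject and a
#' timepoint; taxonomy maps each taxon to a phylum, either through a
#' Greengenes-style lineage string (`k__...; p__Firmicutes; ...`) or a bare
#' phylum column. Columns holding counts are total-sum scaled to relative
#' abundances. The result is aligned on all subjects x the sorted unique
#' timepoints; (subject, timepoint) pairs with no sample get mask 0.
#'
#' @param table_path path to the taxa x samples TSV.
#' @param metadata_path path to a TSV with columns `sample_id`, `subject_id`,
#'   `timepoint`.
#' @param taxonomy_path path to a TSV with columns `taxon_id` and `lineage`
#'   (or `phylum`).
#' @return A [microgen_dataset()].
#' @export
load_dataset <- function(table_path, metadata_path, taxonomy_path) {
  tab <- utils::read.delim(table_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  taxon_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- taxon_ids

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "timepoint")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns sample_id, subject_id, timepoint")
  key <- paste(meta$subject_id, meta$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pairs in metadata: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  taxo <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  if ("phylum" %in% names(taxo)) {
    phy_map <- stats::setNames(taxo$phylum, taxo$taxon_id)
  } else if ("lineage" %in% names(taxo)) {
    phy_map <- stats::setNames(parse_phylum(taxo$lineage), taxo$taxon_id)
  } else stop("taxonomy must have a 'phylum' or 'lineage' column")
  missing_tax <- setdiff(taxon_ids, names(phy_map))
  if (length(missing_tax))
    stop("taxa missing from taxonomy: ", paste(missing_tax, collapse = ", "))

  subjects <- unique(meta$subject_id)
  timepoints <- sort(unique(meta$timepoint))
  S <- length(subjects); k <- length(timepoints); n <- length(taxon_ids)
  ab <- array(0, dim = c(S, k, n))
  mask <- matrix(0, S, k)
  for (r in seq_len(nrow(meta))) {
    sid <- meta$sample_id[r]
    if (!sid %in% colnames(mat)) next
    s <- match(meta$subject_id[r], subjects)
    t <- match(meta$timepoint[r], timepoints)
    v <- mat[, sid]
    tot <- sum(v)
    if (!is.finite(tot) || tot <= 0)
      stop("sample column not sum-normalizable: ", sid)
    ab[s, t, ] <- v / tot
    mask[s, t] <- 1
  }
  microgen_dataset(ab, timepoints, mask, taxon_ids,
                   unname(phy_map[taxon_ids]), subjects)
}

parse_phylum <- function(lineage) {
  out <- vapply(strsplit(lineage, ";"), function(parts) {
    parts <- trimws(parts)
    p <- grep("^p__", parts, value = TRUE)
    if (length(p)) sub("^p__", "", p[1]) else NA_character_
  }, character(1))
  if (anyNA(out) || any(out == ""))
    stop("lineage strings without a phylum (p__) token")
  out
}

#' Replace zeros with a pseudo-count and renormalize
#'
#' Every zero entry of every observed sample is replaced by half the global
#' minimum nonzero relative abundance over all observed entries; each observed
#' sample is then renormalized to sum to 1. The pseudo-count is recorded in
#' the returned dataset (attribute `pseudo_count`) because post-processing of
#' imputed output uses it as the zeroing threshold.
#'
#' @param ds a [microgen_dataset()].
#' @return The dataset with positive observed entries and a `pseudo_count`
#'   field.
#' @export
add_pseudocount <- function(ds) {
  stopifnot(inherits(ds, "microgen_dataset"))
  obs <- which(ds$mask == 1, arr.ind = TRUE)
  vals <- ds$abundances
  nz <- numeric(0)
  for (r in seq_len(nrow(obs))) {
    v <- vals[obs[r, 1], obs[r, 2], ]
    nz <- c(nz, min(v[v > 0], Inf))
  }
  nz <- nz[is.finite(nz)]
  if (!length(nz)) stop("dataset has no nonzero observed entries")
  pc <- min(nz) / 2
  for (r in seq_len(nrow(obs))) {
    v <- vals[obs[r, 1], obs[r, 2], ]
    v[v == 0] <- pc
    vals[obs[r, 1], obs[r, 2], ] <- v / sum(v)
  }
  ds$abundances <- vals
  ds$pseudo_count <- pc
  ds
}

#' Centered log-ratio transform of an observed longitudinal dataset
#'
#' Per observed sample, `clr_j = ln x_j - mean(ln x)`; missing samples stay
#' zero vectors. Requires strictly positive observed entries, i.e. a
#' pseudo-counted dataset.
#'
#' @param ds a [microgen_dataset()] with positive observed entries (see
#'   [add_pseudocount()]).
#' @return A `microgen_clr` list: `clr_values` array `[S, k, n]`,
#'   `pseudo_count`, and `source` (the input dataset).
#' @export
clr_transform <- function(ds) {
  stopifnot(inherits(ds, "microgen_dataset"))
  vals <- ds$abundances
  out <- array(0, dim = dim(vals))
  obs <- which(ds$mask == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(obs))) {
    v <- vals[obs[r, 1], obs[r, 2], ]
    if (any(v <= 0))
      stop("nonpositive entry in an observed sample; apply add_pseudocount first")
    lv <- log(v)
    out[obs[r, 1], obs[r, 2], ] <- lv - mean(lv)
  }
  structure(list(clr_values = out,
                 pseudo_count = if (is.null(ds$pseudo_count)) NA_real_ else ds$pseudo_count,
                 source = ds),
            class = "microgen_clr")
}

#' Forward and backward time gaps for one mask row
#'
#' The forward gap at timepoint i is the elapsed time since the most recent
#' observed sample before i (0 at the first timepoint, accumulating across
#' runs of missing samples); the backward gap mirrors it from the last
#' timepoint.
#'
#' @param timepoints strictly increasing numeric vector.
#' @param mask_row binary vector of the same length.
#' @return list with numeric vectors `delta_f` and `delta_b`.
#' @export
compute_time_gaps <- function(timepoints, mask_row) {
  k <- length(timepoints)
  if (k == 0) stop("empty timepoint sequence")
  if (length(mask_row) != k) stop("mask_row length mismatch")
  if (k > 1 && is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  df <- numeric(k); db <- numeric(k)
  for (i in seq_len(k)) {
    if (i == 1) df[i] <- 0
    else if (mask_row[i - 1] == 1) df[i] <- timepoints[i] - timepoints[i - 1]
    else df[i] <- df[i - 1] + timepoints[i] - timepoints[i - 1]
  }
  for (i in rev(seq_len(k))) {
    if (i == k) db[i] <- 0
    else if (mask_row[i + 1] == 1) db[i] <- timepoints[i + 1] - timepoints[i]
    else db[i] <- db[i + 1] + timepoints[i + 1] - timepoints[i]
  }
  list(delta_f = df, delta_b = db)
}

#' Time-gap matrices for every subject
#'
#' @param ds a [microgen_dataset()].
#' @return list with `S x k` matrices `delta_f`, `delta_b`.
#' @export
time_gap_matrices <- function(ds) {
  S <- nrow(ds$mask); k <- ncol(ds$mask)
  df <- matrix(0, S, k); db <- matrix(0, S, k)
  for (s in seq_len(S)) {
    g <- compute_time_gaps(ds$timepoints, ds$mask[s, ])
    df[s, ] <- g$delta_f; db[s, ] <- g$delta_b
  }
  list(delta_f = df, delta_b = db)
}
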