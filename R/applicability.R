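# Applicability domain via the Local Outlier Factor (LOF) in novelty mode:
# the neighbourhood statistics (k-distances and local reachability
# densities) are fitted on the training features of one encoder, and query
# molecules are scored against that fitted state only. A query whose local
# density is substantially lower than its neighbours' (LOF above the
# threshold) is out of domain for that encoder; per-encoder flags are then
# combined by an all/any consensus.

pairwise_dist <- function(A, B, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    # Jaccard distance for binary matrices: 1 - |intersection| / |union|
    inter <- tcrossprod(A, B)
    asum <- rowSums(A); bsum <- rowSums(B)
    uni <- outer(asum, bsum, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0
    d
  }
}

#' Fit an applicability-domain model
#'
#' Computes the k-nearest-neighbour structure of the training features for
#' one encoder: per-point k-distances and local reachability densities
#' (lrd), enabling novelty LOF scores for unseen molecules.
#'
#' @param train_features numeric matrix of training-set features.
#' @param n_neighbors neighbourhood size k (default 20).
#' @param threshold LOF score above which a query is out of domain
#'   (default 1.5; scores near 1 indicate density comparable to the
#'   training neighbourhood).
#' @param metric `"euclidean"` (default) or `"jaccard"` (binary
#'   fingerprints).
#' @param encoder optional encoder name carried into reports.
#' @return An object of class `ad_model`.
#' @export
fit_ad <- function(train_features, n_neighbors = 20, threshold = 1.5,
                   metric = c("euclidean", "jaccard"), encoder = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(train_features)
  n <- nrow(X)
  if (n_neighbors >= n) {
    abort(sprintf("n_neighbors (%d) must be smaller than the number of training rows (%d)",
                  n_neighbors, n))
  }
  D <- pairwise_dist(X, X, metric)
  diag(D) <- Inf
  k <- n_neighbors
  nn_idx <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])[seq_len(k)]
    nn_idx[i, ] <- o
    nn_dist[i, ] <- D[i, o]
  }
  kdist <- nn_dist[, k]
  # local reachability density of each training point
  reach <- pmax(nn_dist, matrix(kdist[nn_idx], n, k))
  lrd <- 1 / pmax(rowMeans(reach), .Machine$double.eps)
  structure(
    list(X = X, k = k, threshold = threshold, metric = metric,
         kdist = kdist, lrd = lrd, encoder = encoder %||% "encoder"),
    class = "ad_model"
  )
}

#' LOF novelty scores for query molecules
#'
#' @param model an `ad_model` from [fit_ad()].
#' @param query_features numeric matrix with the same feature width.
#' @return Numeric vector of LOF scores (1 = density typical of the
#'   training cloud; larger = sparser than its neighbourhood).
#' @export
lof_scores <- function(model, query_features) {
  stopifnot(inherits(model, "ad_model"))
  Q <- as.matrix(query_features)
  if (nrow(Q) == 0) return(numeric(0))
  if (ncol(Q) != ncol(model$X)) {
    abort(sprintf("query has %d features, model was fitted on %d",
                  ncol(Q), ncol(model$X)))
  }
  D <- pairwise_dist(Q, model$X, model$metric)
  k <- model$k
  vapply(seq_len(nrow(Q)), function(i) {
    o <- order(D[i, ])[seq_len(k)]
    dists <- D[i, o]
    reach <- pmax(dists, model$kdist[o])
    lrd_q <- 1 / pmax(mean(reach), .Machine$double.eps)
    mean(model$lrd[o]) / lrd_q
  }, 1)
}

#' Flag out-of-domain molecules
#'
#' @param model an `ad_model`.
#' @param query_features numeric matrix.
#' @return Logical vector; `TRUE` marks out-of-domain queries (LOF above
#'   the model's threshold).
#' @export
flag_outliers <- function(model, query_features) {
  lof_scores(model, query_features) > model$threshold
}

#' Multi-encoder applicability-domain consensus
#'
#' Combines per-encoder out-of-domain flags: `"all"` marks a molecule out
#' of domain only when every encoder flags it (the permissive reading);
#' `"any"` when at least one does (the restrictive reading). `"all"` flags
#' are always a subset of `"any"` flags.
#'
#' @param flags named list (or data frame) of logical vectors, one per
#'   encoder, equal lengths.
#' @param mode `"all"` or `"any"`.
#' @return Logical vector.
#' @export
ad_consensus <- function(flags, mode = c("all", "any")) {
  mode <- match.arg(mode)
  flags <- lapply(flags, as.logical)
  lens <- unique(lengths(flags))
  if (length(lens) != 1) abort("per-encoder flag vectors differ in length")
  m <- do.call(cbind, flags)
  if (mode == "all") rowSums(m) == ncol(m) else rowSums(m) >= 1
}

#' Applicability-domain report for a set of encoders
#'
#' Fits one AD model per encoder on its training features, flags the query
#' molecules per encoder, and appends both consensus verdicts.
#'
#' @param train_features named list of training feature matrices.
#' @param query_features named list of query feature matrices (same names).
#' @param molecule_ids optional ids for the query rows.
#' @param n_neighbors,threshold passed to [fit_ad()].
#' @param metrics optional named character vector of per-encoder metrics.
#' @return A tibble: `molecule`, one logical column per encoder,
#'   `consensus_all`, `consensus_any`.
#' @export
ad_report <- function(train_features, query_features, molecule_ids = NULL,
                      n_neighbors = 20, threshold = 1.5, metrics = NULL) {
  stopifnot(identical(sort(names(train_features)), sort(names(query_features))))
  flags <- lapply(names(train_features), function(nm) {
    met <- if (!is.null(metrics) && nm %in% names(metrics)) metrics[[nm]] else "euclidean"
    m <- fit_ad(train_features[[nm]], n_neighbors = n_neighbors,
                threshold = threshold, metric = met, encoder = nm)
    flag_outliers(m, query_features[[nm]])
  })
  names(flags) <- names(train_features)
  n <- length(flags[[1]])
  out <- tibble(molecule = molecule_ids %||%
                  rownames(as.matrix(query_features[[1]])) %||%
                  sprintf("mol%05d", seq_len(n)))
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out$consensus_all <- ad_consensus(flags, "all")
  out$consensus_any <- ad_consensus(flags, "any")
  out
}
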