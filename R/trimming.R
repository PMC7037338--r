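# FloWPS core operators: per-query relevant-feature selection (parameter m)
# and nearest-neighbour windowing (parameter k).

#' Trimming parameters
#'
#' `m` controls relevant-feature selection: a feature is kept for a query
#' only if at least `m` training projections lie strictly above and at
#' least `m` strictly below the query on that axis (`m = 0` keeps all
#' features). `k` is the number of Euclidean nearest neighbours retained
#' for training; `k` equal to the pool size means no sample selection.
#'
#' @param m non-negative integer.
#' @param k positive integer.
#' @return a `TrimmingParams` list.
#' @export
trimming_params <- function(m, k) {
  stopifnot(length(m) == 1, length(k) == 1, m >= 0, k >= 1,
            m == as.integer(m), k == as.integer(k))
  structure(list(m = as.integer(m), k = as.integer(k)),
            class = "TrimmingParams")
}

#' Relevant-feature mask for a query sample
#'
#' A feature is relevant when the query value has at least `m` training
#' values strictly above it and at least `m` strictly below it on that
#' feature's axis; values exactly equal to the query support neither side.
#' Keeping only relevant features prevents the base learner from
#' extrapolating beyond the training cloud at the query point.
#'
#' @param train_values numeric matrix (training pool x features).
#' @param query_values numeric vector of the query sample.
#' @param m non-negative integer.
#' @return logical vector over features (`TRUE` = relevant). May be
#'   all-`FALSE`; callers treat that as a degenerate mask.
#' @export
relevant_features <- function(train_values, query_values, m) {
  stopifnot(is.matrix(train_values),
            length(query_values) == ncol(train_values), m >= 0)
  if (m == 0)
    return(structure(rep(TRUE, ncol(train_values)),
                     names = colnames(train_values)))
  qrep <- rep(query_values, each = nrow(train_values))
  below <- colSums(train_values < qrep)
  above <- colSums(train_values > qrep)
  below >= m & above >= m
}

#' Nearest training neighbours of a query in a masked subspace
#'
#' Euclidean distances are computed on the (already masked) values as
#' given; no per-window rescaling is applied. Distance ties are broken by
#' ascending training-pool index, making the selection deterministic.
#'
#' @param train_values_masked numeric matrix restricted to the relevant
#'   features.
#' @param query_values_masked query vector in the same subspace.
#' @param k number of neighbours, `1 <= k <= nrow(train_values_masked)`.
#' @return integer vector of the `k` selected row indices, in ascending
#'   index order.
#' @export
nearest_neighbors <- function(train_values_masked, query_values_masked, k) {
  stopifnot(is.matrix(train_values_masked))
  n <- nrow(train_values_masked)
  if (ncol(train_values_masked) == 0)
    stop("degenerate (empty) feature mask: no subspace for distances")
  stopifnot(k >= 1, k <= n,
            length(query_values_masked) == ncol(train_values_masked))
  d2 <- rowSums(sweep(train_values_masked, 2, query_values_masked)^2)
  ord <- order(d2)                     # radix sort: stable, index tie-break
  sort(ord[seq_len(k)])
}

#' Trim a training pool around a query sample
#'
#' Composes [relevant_features()] and [nearest_neighbors()]. A degenerate
#' all-false mask falls back to the full feature set (flagged), so a
#' prediction is always possible. If the selected neighbours carry a
#' single class, the context is flagged `single_class` and the engine
#' scores the query with that class's trivial score.
#'
#' @param pool a labelled `ExpressionDataset` acting as the training pool
#'   (the query itself must not be in it).
#' @param query_values query expression vector over the pool's features.
#' @param params a [trimming_params()] object; `k` larger than the pool is
#'   capped to the pool size (no selection).
#' @param query_index optional identifier stored in the context.
#' @return a `TrimmedContext` with `feature_mask`, `neighbor_indices`,
#'   `degenerate`, `single_class`, `query_index`.
#' @export
trim <- function(pool, query_values, params, query_index = NA) {
  stopifnot(inherits(pool, "ExpressionDataset"),
            inherits(params, "TrimmingParams"))
  n <- nrow(pool$values)
  if (params$m > floor(n / 2))
    stop(sprintf("m = %d exceeds floor(pool/2) = %d", params$m, floor(n / 2)))
  mask <- relevant_features(pool$values, query_values, params$m)
  degenerate <- !any(mask)
  eff <- if (degenerate) rep(TRUE, length(mask)) else mask
  k <- min(params$k, n)
  nb <- nearest_neighbors(pool$values[, eff, drop = FALSE],
                          query_values[eff], k)
  single <- !is.null(pool$labels) &&
    length(unique(pool$labels[nb])) < 2
  structure(list(feature_mask = mask,
                 neighbor_indices = nb,
                 degenerate = degenerate,
                 single_class = single,
                 query_index = query_index),
            class = "TrimmedContext")
}
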