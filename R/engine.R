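# The FloWPS meta-classifier: for every held-out sample i, an inner
# leave-one-out over the preceding dataset D_i evaluates every trimming
# parameter pair (m, k); the prediction-accountable set collects the pairs
# whose inner AUC is within a confidence factor of the best, and the final
# score for i averages the query predictions over that set.

#' Trimming-parameter grid
#'
#' @param m_values non-negative integers (relevant-feature threshold).
#' @param k_values positive integers (neighbour counts); values larger
#'   than a window's training pool are capped to the pool size.
#' @param confidence_p confidence threshold for the prediction-accountable
#'   set, conventionally between 0.90 and 0.95.
#' @return a `GridSpec`.
#' @export
grid_spec <- function(m_values, k_values, confidence_p = 0.92) {
  m_values <- sort(unique(as.integer(m_values)))
  k_values <- sort(unique(as.integer(k_values)))
  stopifnot(length(m_values) >= 1, length(k_values) >= 1,
            all(m_values >= 0), all(k_values >= 1),
            confidence_p > 0, confidence_p <= 1)
  structure(list(m_values = m_values, k_values = k_values,
                 confidence_p = confidence_p),
            class = "GridSpec")
}

#' Default quasi-geometric grid for a dataset of n samples
#'
#' `m` ranges over a quasi-geometric ladder capped at `floor((n-2)/2)`;
#' `k` over ~8 quasi-geometric values from 5 up to `n - 2` (the inner
#' training-pool size). Coarse by construction: the engine performs
#' `N * (N-1) * |grid|` base-learner fits.
#'
#' @param n number of samples in the dataset.
#' @param confidence_p confidence threshold, default 0.92.
#' @param n_k approximate number of k values.
#' @return a `GridSpec`.
#' @export
default_grid <- function(n, confidence_p = 0.92, n_k = 8) {
  stopifnot(n >= 6)
  m_cap <- floor((n - 2) / 2)
  ladder <- c(0L, 1L, 2L, 3L, 5L, 8L, 12L, 18L, 27L, 40L, 60L, 90L)
  m_values <- ladder[ladder <= m_cap]
  k_min <- min(5L, n - 2L)
  k_values <- unique(round(exp(seq(log(k_min), log(n - 2), length.out = n_k))))
  grid_spec(m_values, k_values, confidence_p)
}

# Scores (and optionally importances) for one query against one training
# pool, across the whole (m, k) grid. Projection counts, per-feature
# squared differences and distance orderings are computed once per
# (query, m) and shared across all k.
cell_scores <- function(pool_X, pool_y, qx, grid, spec,
                        seed_base, i, j, want_importance = FALSE) {
  npool <- nrow(pool_X)
  nm <- length(grid$m_values); nk <- length(grid$k_values)
  qrep <- rep(qx, each = npool)
  below <- colSums(pool_X < qrep)
  above <- colSums(pool_X > qrep)
  diffs2 <- (pool_X - qrep)^2
  scores <- matrix(NA_real_, nm, nk)
  single <- matrix(FALSE, nm, nk)
  degenerate <- logical(nm)
  imps <- if (want_importance) vector("list", nm * nk) else NULL
  alpha_full <- numeric(npool)   # svm dual warm start, shared across cells
  warm <- FALSE
  Xb <- if (spec$method == "bernoulli_nb")
    pool_X > spec$hyperparams$binarize_threshold else NULL
  for (mi in seq_len(nm)) {
    m <- grid$m_values[mi]
    mask <- if (m == 0) rep(TRUE, ncol(pool_X)) else below >= m & above >= m
    if (!any(mask)) {
      degenerate[mi] <- TRUE
      mask <- rep(TRUE, ncol(pool_X))   # fall back to the full feature set
    }
    d2 <- as.vector(diffs2 %*% mask)
    ord <- order(d2)
    if (spec$method == "svm_linear") {
      # fast path: ascending k gives nested neighbour sets, so each
      # window's dual solution warm-starts the next (and the next m's);
      # any clamped start is admissible, the optimum is unique
      qm <- cbind(matrix(qx[mask], nrow = 1), 1)
      hp <- spec$hyperparams
      for (ki in seq_len(nk)) {
        k_eff <- min(grid$k_values[ki], npool)
        nb <- sort(ord[seq_len(k_eff)])
        ysub <- pool_y[nb]
        if (all(ysub == ysub[1])) {
          scores[mi, ki] <- as.numeric(ysub[1])
          single[mi, ki] <- TRUE
          next
        }
        fit <- fit_svm(pool_X[nb, mask, drop = FALSE], ysub, hp,
                       spec$balanced_classes,
                       alpha0 = if (warm) alpha_full[nb])
        alpha_full[nb] <- fit$alpha
        warm <- TRUE
        scores[mi, ki] <- plogis(qm %*% fit$w)[, 1]
        if (want_importance) {
          emb <- numeric(ncol(pool_X))
          emb[mask] <- abs(fit$w[-length(fit$w)])
          imps[[(ki - 1) * nm + mi]] <- emb
        }
      }
      next
    }
    if (spec$method == "bernoulli_nb") {
      # fast path: binarised feature counts are integers and windows are
      # nested in k, so per-class counts update incrementally; results are
      # exactly those of refitting each window from scratch
      hp <- spec$hyperparams
      cp <- cn <- numeric(ncol(pool_X))
      n1 <- 0L; n0 <- 0L; prev_k <- 0L
      qxm <- matrix(qx[mask], nrow = 1)
      for (ki in seq_len(nk)) {
        k_eff <- min(grid$k_values[ki], npool)
        if (k_eff > prev_k) {
          new <- ord[(prev_k + 1):k_eff]
          ynew <- pool_y[new]
          newp <- new[ynew == 1L]; newn <- new[ynew == 0L]
          if (length(newp)) cp <- cp + colSums(Xb[newp, , drop = FALSE])
          if (length(newn)) cn <- cn + colSums(Xb[newn, , drop = FALSE])
          n1 <- n1 + length(newp); n0 <- n0 + length(newn)
          prev_k <- k_eff
        }
        if (n1 == 0L || n0 == 0L) {
          scores[mi, ki] <- as.numeric(n1 > 0L)
          single[mi, ki] <- TRUE
          next
        }
        st <- bnb_state(cp[mask], cn[mask], n1, n0, hp)
        scores[mi, ki] <- predict_bnb(st, qxm)
        if (want_importance) {
          emb <- numeric(ncol(pool_X))
          emb[mask] <- st$count_pos + st$count_neg
          imps[[(ki - 1) * nm + mi]] <- emb
        }
      }
      next
    }
    for (ki in seq_len(nk)) {
      k_eff <- min(grid$k_values[ki], npool)
      nb <- sort(ord[seq_len(k_eff)])
      ysub <- pool_y[nb]
      if (all(ysub == ysub[1])) {
        scores[mi, ki] <- as.numeric(ysub[1])
        single[mi, ki] <- TRUE
        next
      }
      model <- fit_learner(spec, pool_X[nb, mask, drop = FALSE], ysub,
                           seed = derive_seed(seed_base, i, j, mi, ki))
      scores[mi, ki] <- predict_score(model, qx[mask])
      if (want_importance) {
        emb <- numeric(ncol(pool_X))
        emb[mask] <- extract_importance(model)
        imps[[(ki - 1) * nm + mi]] <- emb
      }
    }
  }
  list(scores = scores, single = single, degenerate = degenerate,
       importance = imps)
}

#' Inner leave-one-out scores over the preceding dataset
#'
#' For a held-out sample `i` and fixed trimming parameters, classify every
#' sample `j != i` of the preceding dataset `D_i` from the remaining
#' `N - 2` samples, trimming the pool around each `j`. Single-class
#' trimmed windows yield the trivial score of the class present.
#'
#' @param ds a labelled `ExpressionDataset`.
#' @param i held-out sample index.
#' @param params a [trimming_params()].
#' @param spec a [learner_spec()].
#' @param seed integer run seed.
#' @return numeric vector of scores for the samples of `D_i`, named by
#'   sample id, with a logical `single_class` attribute.
#' @export
inner_scores <- function(ds, i, params, spec, seed = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels))
  grid <- grid_spec(params$m, params$k, confidence_p = 0.92)
  idx <- setdiff(seq_len(nrow(ds$values)), i)
  out <- numeric(length(idx)); flags <- logical(length(idx))
  for (jj in seq_along(idx)) {
    pool <- idx[-jj]
    cs <- cell_scores(ds$values[pool, , drop = FALSE], ds$labels[pool],
                      ds$values[idx[jj], ], grid, spec, seed, i, jj)
    out[jj] <- cs$scores[1, 1]
    flags[jj] <- cs$single[1, 1]
  }
  names(out) <- ds$sample_ids[idx]
  attr(out, "single_class") <- flags
  out
}

#' Evaluate the trimming grid for one held-out sample
#'
#' Computes `AUC_i(m, k)`, the inner leave-one-out ROC AUC over `D_i` at
#' every grid cell, together with the query scores `P_i(m, k)` from models
#' trimmed around sample `i` on the full `D_i`.
#'
#' @inheritParams inner_scores
#' @param grid a [grid_spec()].
#' @param want_importance also extract feature importances of the query
#'   models (only for methods that support it).
#' @return a `GridResult`: `auc` and `query_scores` matrices (m x k),
#'   degeneracy flags, and optionally per-cell importance vectors.
#' @export
grid_evaluate <- function(ds, i, grid, spec, seed = 1,
                          want_importance = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels),
            inherits(grid, "GridSpec"))
  n <- nrow(ds$values)
  idx <- setdiff(seq_len(n), i)
  lab <- ds$labels[idx]
  nm <- length(grid$m_values); nk <- length(grid$k_values)
  inner <- array(NA_real_, c(length(idx), nm, nk))
  single_any <- matrix(FALSE, nm, nk)
  for (jj in seq_along(idx)) {
    pool <- idx[-jj]
    cs <- cell_scores(ds$values[pool, , drop = FALSE], ds$labels[pool],
                      ds$values[idx[jj], ], grid, spec, seed, i, jj)
    inner[jj, , ] <- cs$scores
    single_any <- single_any | cs$single
  }
  auc <- matrix(NA_real_, nm, nk,
                dimnames = list(m = grid$m_values, k = grid$k_values))
  for (mi in seq_len(nm)) for (ki in seq_len(nk))
    auc[mi, ki] <- roc_auc(inner[, mi, ki], lab)
  qs <- cell_scores(ds$values[idx, , drop = FALSE], ds$labels[idx],
                    ds$values[i, ], grid, spec, seed, i, 0L,
                    want_importance = want_importance)
  query_scores <- qs$scores
  dimnames(query_scores) <- dimnames(auc)
  structure(list(auc = auc, query_scores = query_scores,
                 inner_scores = inner,
                 degenerate_m = qs$degenerate,
                 single_class = qs$single,
                 single_class_inner = single_any,
                 importance = qs$importance,
                 grid = grid, sample_id = ds$sample_ids[i]),
            class = "GridResult")
}

#' Prediction-accountable set
#'
#' All grid cells whose inner AUC strictly exceeds
#' `confidence_p * max(AUC)`; the argmax cells are always included (this
#' matters only for `confidence_p = 1` or an all-zero AUC surface).
#'
#' @param gr a `GridResult`, or a plain numeric AUC matrix.
#' @param confidence_p the confidence threshold in (0, 1].
#' @return an `AccountableSet`: logical membership matrix `member`, data
#'   frame `pairs` (m, k), and `max_auc`.
#' @export
accountable_set <- function(gr, confidence_p = 0.92) {
  auc <- if (inherits(gr, "GridResult")) gr$auc else as.matrix(gr)
  stopifnot(length(auc) >= 1, confidence_p > 0, confidence_p <= 1)
  mx <- max(auc)
  member <- auc > confidence_p * mx
  member[auc == mx] <- TRUE
  idx <- which(member, arr.ind = TRUE)
  mv <- rownames(auc) %||% as.character(seq_len(nrow(auc)))
  kv <- colnames(auc) %||% as.character(seq_len(ncol(auc)))
  pairs <- data.frame(m = as.integer(mv[idx[, 1]]),
                      k = as.integer(kv[idx[, 2]]))
  structure(list(member = member, pairs = pairs, max_auc = mx,
                 confidence_p = confidence_p),
            class = "AccountableSet")
}

check_flowps_inputs <- function(ds, min_n = 6) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$labels)) stop("dataset has no labels; use attach_labels()")
  n <- nrow(ds$values)
  if (n < min_n) stop("need at least ", min_n, " samples")
  if (min(table(ds$labels)) < 2)
    stop("need at least 2 samples in each class")
  n
}

#' Run the FloWPS meta-classifier (outer leave-one-out)
#'
#' For every sample `i`: evaluate the full trimming grid on `D_i`
#' ([grid_evaluate()]), form the prediction-accountable set `S_i`
#' ([accountable_set()]), and average the query scores over `S_i` into the
#' final score `P_Fi`. When the base method supports it, per-feature
#' importances of the query models are averaged over `S_i` (features
#' outside a window's relevant set contribute 0) and then over samples
#' into a dataset-level importance profile.
#'
#' @param ds a labelled `ExpressionDataset` with at least 6 samples and 2
#'   per class.
#' @param spec a [learner_spec()].
#' @param grid a [grid_spec()]; default [default_grid()] for the dataset
#'   size.
#' @param seed integer run seed; all per-fit seeds derive from it.
#' @param importance extract feature importances (`NULL` = auto: yes when
#'   the method supports it).
#' @return a `FloWPSOutput`: `scores` (P_Fi per sample),
#'   `accountable_sets`, `auc_array` (sample x m x k), `query_scores`
#'   array, `importance_sample` (sample x feature), `importance`
#'   (dataset-level), provenance fields.
#' @export
flowps <- function(ds, spec, grid = NULL, seed = 1, importance = NULL) {
  n <- check_flowps_inputs(ds)
  stopifnot(inherits(spec, "LearnerSpec"))
  if (is.null(grid)) grid <- default_grid(n)
  stopifnot(inherits(grid, "GridSpec"))
  if (max(grid$m_values) > floor((n - 2) / 2))
    stop("grid m_values exceed floor((N-2)/2) = ", floor((n - 2) / 2))
  want_imp <- importance %||% (spec$method %in% IMPORTANCE_METHODS)
  if (want_imp && !spec$method %in% IMPORTANCE_METHODS)
    stop("UNSUPPORTED_IMPORTANCE: no importance for ", spec$method)
  nm <- length(grid$m_values); nk <- length(grid$k_values)
  s <- ncol(ds$values)
  scores <- numeric(n)
  auc_array <- array(NA_real_, c(n, nm, nk),
                     dimnames = list(sample = ds$sample_ids,
                                     m = grid$m_values, k = grid$k_values))
  query_array <- auc_array
  sets <- vector("list", n)
  imp_sample <- if (want_imp)
    matrix(0, n, s, dimnames = list(ds$sample_ids, ds$feature_ids)) else NULL
  for (i in seq_len(n)) {
    gr <- grid_evaluate(ds, i, grid, spec, seed = seed,
                        want_importance = want_imp)
    auc_array[i, , ] <- gr$auc
    query_array[i, , ] <- gr$query_scores
    set <- accountable_set(gr, grid$confidence_p)
    sets[[i]] <- set
    scores[i] <- mean(gr$query_scores[set$member])
    if (want_imp) {
      cells <- which(set$member)
      vecs <- gr$importance[cells]
      vecs <- vecs[!vapply(vecs, is.null, logical(1))]
      if (length(vecs))
        imp_sample[i, ] <- Reduce(`+`, vecs) / length(vecs)
    }
  }
  names(scores) <- ds$sample_ids
  structure(list(scores = scores,
                 labels = ds$labels,
                 accountable_sets = sets,
                 auc_array = auc_array,
                 query_scores = query_array,
                 importance_sample = imp_sample,
                 importance = if (want_imp) colMeans(imp_sample) else NULL,
                 grid = grid, spec = spec, seed = seed,
                 baseline = FALSE),
            class = "FloWPSOutput")
}

#' Plain leave-one-out baseline (no trimming)
#'
#' The no-FloWPS reference: each sample is scored by the base learner
#' fitted on all other samples with all features (equivalently, trimming
#' with `m = 0`, `k = N - 1`). Shares the `FloWPSOutput` schema so results
#' compare head-to-head.
#'
#' @inheritParams flowps
#' @return a `FloWPSOutput` with `baseline = TRUE`.
#' @export
flowps_baseline <- function(ds, spec, seed = 1, importance = NULL) {
  n <- check_flowps_inputs(ds, min_n = 3)
  stopifnot(inherits(spec, "LearnerSpec"))
  want_imp <- importance %||% (spec$method %in% IMPORTANCE_METHODS)
  s <- ncol(ds$values)
  scores <- numeric(n)
  imp_sample <- if (want_imp)
    matrix(0, n, s, dimnames = list(ds$sample_ids, ds$feature_ids)) else NULL
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    model <- fit_learner(spec, ds$values[idx, , drop = FALSE],
                         ds$labels[idx],
                         seed = derive_seed(seed, i, 0L, 1L, 1L))
    scores[i] <- predict_score(model, ds$values[i, ])
    if (want_imp) imp_sample[i, ] <- extract_importance(model)
  }
  names(scores) <- ds$sample_ids
  structure(list(scores = scores, labels = ds$labels,
                 accountable_sets = NULL,
                 auc_array = NULL, query_scores = NULL,
                 importance_sample = imp_sample,
                 importance = if (want_imp) colMeans(imp_sample) else NULL,
                 grid = grid_spec(0, n - 1),
                 spec = spec, seed = seed, baseline = TRUE),
            class = "FloWPSOutput")
}

#' Leave-one-out ROC AUC of a run
#' @param out a `FloWPSOutput`.
#' @return the ROC AUC of its scores against the true labels.
#' @export
loo_auc <- function(out) {
  stopifnot(inherits(out, "FloWPSOutput"))
  roc_auc(out$scores, out$labels)
}

#' @export
print.FloWPSOutput <- function(x, ...) {
  cat(sprintf("FloWPSOutput (%s%s): %d samples, LOO AUC = %.3f\n",
              x$spec$method, if (x$baseline) ", baseline" else "",
              length(x$scores), loo_auc(x)))
  invisible(x)
}

#' Persist per-run grid artifacts
#'
#' Writes the inner AUC tensor and accountable-set membership in long TSV
#' form (`sample_id`, `m`, `k`, `auc`, `query_score`, `in_accountable_set`)
#' so the set contract can be re-checked post hoc.
#'
#' @param out a non-baseline `FloWPSOutput`.
#' @param path output TSV path.
#' @export
write_grid_report <- function(out, path) {
  stopifnot(inherits(out, "FloWPSOutput"), !out$baseline)
  dn <- dimnames(out$auc_array)
  long <- expand.grid(sample_id = dn$sample, m = as.integer(dn$m),
                      k = as.integer(dn$k), stringsAsFactors = FALSE)
  long$auc <- as.vector(out$auc_array)
  long$query_score <- as.vector(out$query_scores)
  member <- vapply(seq_along(dn$sample), function(i)
    as.vector(out$accountable_sets[[i]]$member),
    logical(length(dn$m) * length(dn$k)))
  long$in_accountable_set <- as.vector(t(member))
  utils::write.table(long[order(long$sample_id, long$m, long$k), ],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
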