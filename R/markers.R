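# Core marker gene selection: per-gene ROC AUC ranking stabilised by
# leave-one-out cross-validation.

# Per-column Mann-Whitney AUC of `values` as a score for labels == 1,
# ties contributing 1/2. Returns raw (unfolded) AUC per feature.
column_auc <- function(values, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  a <- apply(values, 2, function(x) {
    r <- rank(x)                       # average ranks handle ties -> 1/2
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  names(a) <- colnames(values)
  a
}

#' Per-gene discriminative AUC
#'
#' ROC AUC of each single feature used as a score for the responder class,
#' computed by the Mann-Whitney rank formulation (ties contribute 1/2).
#' With `fold = TRUE` (default) the value is orientation-folded as
#' `max(a, 1 - a)` so down-regulated markers rank as high as up-regulated
#' ones. A constant feature gives 0.5.
#'
#' @param ds a labelled `ExpressionDataset`.
#' @param fold fold orientation so that both directions score alike.
#' @return named numeric vector, one AUC per feature.
#' @export
per_gene_auc <- function(ds, fold = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels))
  a <- column_auc(ds$values, ds$labels)
  if (fold) pmax(a, 1 - a) else a
}

#' Select the core marker gene set
#'
#' For each of the N leave-one-out folds the features are ranked by folded
#' AUC on the N-1 retained samples and the `top_n` best are recorded. The
#' core set contains the features selected in at least
#' `stability_fraction` of folds, ordered by their mean rank across folds.
#' Defaults (`top_n = 20`, `stability_fraction = 1`) reproduce the 7-20
#' core-gene scale typical of clinical cohorts of this size.
#'
#' @param ds a labelled `ExpressionDataset`.
#' @param top_n number of top-ranked features retained per fold.
#' @param stability_fraction required fraction of folds, in (0, 1].
#' @param fold_auc rank by folded (`max(a, 1-a)`, default) or raw AUC.
#' @return a `MarkerReport` with elements `per_feature_auc` (full data,
#'   folded per `fold_auc`), `core_set`, `selection_frequency`,
#'   `mean_rank`, `top_n`, `stability_fraction`.
#' @export
select_core_markers <- function(ds, top_n = 20, stability_fraction = 1,
                                fold_auc = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels),
            top_n >= 1, stability_fraction > 0, stability_fraction <= 1)
  n <- nrow(ds$values); s <- ncol(ds$values)
  top_n <- min(top_n, s)
  count <- integer(s); rank_sum <- numeric(s)
  names(count) <- names(rank_sum) <- ds$feature_ids
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    lab <- ds$labels[keep]
    if (length(unique(lab)) < 2) next
    a <- column_auc(ds$values[keep, , drop = FALSE], lab)
    if (fold_auc) a <- pmax(a, 1 - a)
    rk <- rank(-a, ties.method = "first")
    sel <- rk <= top_n
    count[sel] <- count[sel] + 1L
    rank_sum <- rank_sum + rk
  }
  freq <- count / n
  in_core <- freq >= stability_fraction
  if (!any(in_core))
    stop("empty core marker set: lower stability_fraction or raise top_n")
  mean_rank <- rank_sum / n
  core <- ds$feature_ids[in_core]
  core <- core[order(mean_rank[in_core])]
  full_auc <- column_auc(ds$values, ds$labels)
  if (fold_auc) full_auc <- pmax(full_auc, 1 - full_auc)
  structure(list(per_feature_auc = full_auc,
                 core_set = core,
                 selection_frequency = freq,
                 mean_rank = mean_rank,
                 top_n = top_n,
                 stability_fraction = stability_fraction),
            class = "MarkerReport")
}

#' @export
print.MarkerReport <- function(x, ...) {
  cat(sprintf("MarkerReport: %d core markers (top_n = %d, stability >= %.2f)\n",
              length(x$core_set), x$top_n, x$stability_fraction))
  cat("  ", paste(utils::head(x$core_set, 10), collapse = ", "),
      if (length(x$core_set) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.MarkerReport <- function(x, ...) {
  ids <- names(x$per_feature_auc)
  data.frame(feature_id = ids,
             folded_auc = unname(x$per_feature_auc),
             selection_frequency = unname(x$selection_frequency[ids]),
             mean_rank = unname(x$mean_rank[ids]),
             in_core_set = ids %in% x$core_set,
             stringsAsFactors = FALSE)
}

#' Write a marker report as TSV
#' @param report a `MarkerReport`.
#' @param path output path.
#' @export
write_marker_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
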