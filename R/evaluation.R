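# Classifier metrics, cost-balanced thresholding, paired method
# comparison and cross-method importance correlation analysis.

#' ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen responder scores above a randomly
#' chosen non-responder, with ties counting 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(c(-Inf, Inf))
  c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
}

#' Cost-balanced discrimination threshold
#'
#' Chooses the threshold tau minimising the penalty `B * FP + FN`, where a
#' sample is called positive iff its score is `>= tau`. `B > 1` penalises
#' false positives (safer not to treat), `B < 1` false negatives (refusing
#' a helpful drug is worse). Candidate thresholds are the midpoints of
#' consecutive distinct scores plus infinite sentinels; penalty ties are
#' broken toward the smallest tau (favouring sensitivity).
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels.
#' @param B positive relative balance factor.
#' @return the chosen tau.
#' @export
choose_threshold <- function(scores, labels, B) {
  stopifnot(length(scores) == length(labels), B > 0)
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present")
  cand <- threshold_candidates(scores)
  pen <- vapply(cand, function(tau) {
    pos_call <- scores >= tau
    B * sum(pos_call & labels == 0) + sum(!pos_call & labels == 1)
  }, numeric(1))
  cand[which.min(pen)]                  # which.min -> first = smallest tau
}

#' Sensitivity and specificity at a threshold
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels.
#' @param tau threshold; positive call iff score `>= tau`.
#' @return named vector `c(SN, SP)` with `SN = TP/(TP+FN)`,
#'   `SP = TN/(TN+FP)`.
#' @export
sensitivity_specificity <- function(scores, labels, tau) {
  stopifnot(length(scores) == length(labels))
  pos_call <- scores >= tau
  tp <- sum(pos_call & labels == 1); fn <- sum(!pos_call & labels == 1)
  tn <- sum(!pos_call & labels == 0); fp <- sum(pos_call & labels == 0)
  c(SN = tp / (tp + fn), SP = tn / (tn + fp))
}

#' Paired t-test on AUC values with vs without trimming
#'
#' @param auc_with,auc_without equal-length numeric vectors (>= 2).
#' @return list with `t`, `p` (two-sided), `df`, `mean_difference`,
#'   `degenerate` (`TRUE` when all differences are equal, in which case
#'   `t`/`p` are `NA` rather than a division by zero).
#' @export
paired_ttest <- function(auc_with, auc_without) {
  stopifnot(length(auc_with) == length(auc_without), length(auc_with) >= 2)
  d <- auc_with - auc_without
  n <- length(d)
  s <- sd(d)
  if (s == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1,
                mean_difference = mean(d), degenerate = TRUE))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Pairwise correlation of feature-importance profiles
#'
#' Pearson on the raw importance vectors and Spearman on their ranks
#' (average-rank ties), for every pair of methods. A constant vector makes
#' its correlations undefined; those entries are `NA` and flagged, rather
#' than propagating NaN.
#'
#' @param profiles named list mapping method name to an importance vector;
#'   all vectors must share the identical feature set (>= 3 features).
#' @return a `CorrelationMatrix`: list with matrices `pearson`,
#'   `spearman`, logical matrix `undefined`.
#' @export
importance_correlations <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  feats <- names(profiles[[1]])
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("importance vectors have mismatched feature sets")
  if (!is.null(feats)) {
    for (p in profiles)
      if (!identical(names(p), feats))
        stop("importance vectors have mismatched feature sets")
  }
  if (lens[1] < 3) stop("need at least 3 features")
  methods <- names(profiles)
  q <- length(profiles)
  pe <- sp <- matrix(NA_real_, q, q, dimnames = list(methods, methods))
  undef <- matrix(FALSE, q, q, dimnames = list(methods, methods))
  const <- vapply(profiles, function(v) sd(v) == 0, logical(1))
  for (a in seq_len(q)) for (b in seq_len(q)) {
    if (a == b) { pe[a, b] <- sp[a, b] <- 1; next }
    if (const[a] || const[b]) { undef[a, b] <- TRUE; next }
    pe[a, b] <- cor(profiles[[a]], profiles[[b]])
    sp[a, b] <- cor(rank(profiles[[a]]), rank(profiles[[b]]))
  }
  structure(list(pearson = pe, spearman = sp, undefined = undef),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("Pearson:\n"); print(round(x$pearson, 3))
  cat("Spearman:\n"); print(round(x$spearman, 3))
  invisible(x)
}

#' Per-run metric table across balance factors
#'
#' For each configured balance factor B, chooses the penalty-optimal
#' threshold on the run's LOO scores and reports SN/SP there (an optimism
#' caveat: the threshold is selected on the same prediction set it is
#' evaluated on, as is conventional for these tables).
#'
#' @param out a `FloWPSOutput`.
#' @param B_values positive balance factors.
#' @param equalize_classes subsample (deterministically, by run seed) the
#'   larger class to the smaller before choosing tau, as used for
#'   equalized-cohort summaries; default off.
#' @return data frame with columns `B`, `tau`, `SN`, `SP`, plus the run
#'   AUC as an attribute.
#' @export
balance_table <- function(out, B_values = c(0.1, 0.25, 1, 4, 10),
                          equalize_classes = FALSE) {
  stopifnot(inherits(out, "FloWPSOutput"), all(B_values > 0))
  scores <- out$scores; labels <- out$labels
  if (equalize_classes) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    keep <- with_local_seed(out$seed, {
      if (n1 > n0) c(sample(which(labels == 1), n0), which(labels == 0))
      else c(which(labels == 1), sample(which(labels == 0), n1))
    })
    keep <- sort(keep)
    scores <- scores[keep]; labels <- labels[keep]
  }
  rows <- lapply(B_values, function(B) {
    tau <- choose_threshold(scores, labels, B)
    snsp <- sensitivity_specificity(scores, labels, tau)
    data.frame(B = B, tau = tau, SN = snsp["SN"], SP = snsp["SP"],
               row.names = NULL)
  })
  res <- do.call(rbind, rows)
  attr(res, "auc") <- roc_auc(out$scores, out$labels)
  res
}

#' Run a full trimming-vs-baseline experiment
#'
#' For each dataset and base method: a baseline LOO run and a FloWPS run,
#' AUC plus SN/SP at every balance factor, the paired t-test of AUC with
#' vs without trimming across datasets, dataset-level importance profiles
#' and their cross-method correlations (methods supporting importance
#' only). Summaries use the median across datasets.
#'
#' @param datasets a named list of labelled `ExpressionDataset`s, or of
#'   [synthetic_config()]s (generated on the fly).
#' @param methods character vector of base method names, or list of
#'   [learner_spec()]s.
#' @param grid `NULL` (per-dataset default) or a [grid_spec()].
#' @param B_values balance factors for the SN/SP tables.
#' @param seed run seed.
#' @param out_dir optional directory; when given, per-sample scores/calls,
#'   per-dataset metrics, importance vectors and correlation matrices are
#'   written there as TSV.
#' @param equalize_classes passed to [balance_table()].
#' @return an `ExperimentResult` list: `per_dataset` metric data frame,
#'   `summary` (per method medians and paired t), `correlations` (per
#'   dataset, with and without trimming), `importances`.
#' @export
run_experiment <- function(datasets, methods, grid = NULL,
                           B_values = c(0.1, 0.25, 1, 4, 10),
                           seed = 1, out_dir = NULL,
                           equalize_classes = FALSE) {
  if (inherits(datasets, "ExpressionDataset") ||
      inherits(datasets, "SyntheticConfig")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d)
    if (inherits(d, "SyntheticConfig")) generate_synthetic(d) else d)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  if (is.character(methods)) {
    methods <- lapply(methods, learner_spec)
  }
  names(methods) <- vapply(methods, function(m) m$method, character(1))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  per_rows <- list(); correlations <- list(); importances <- list()
  for (dn in names(datasets)) {
    ds <- datasets[[dn]]
    g <- grid %||% default_grid(nrow(ds$values))
    prof_with <- list(); prof_without <- list()
    for (mn in names(methods)) {
      spec <- methods[[mn]]
      base <- flowps_baseline(ds, spec, seed = seed)
      flow <- flowps(ds, spec, grid = g, seed = seed)
      for (run in list(base, flow)) {
        bt <- balance_table(run, B_values, equalize_classes)
        per_rows[[length(per_rows) + 1]] <- data.frame(
          dataset = dn, method = mn,
          flowps = !run$baseline, auc = loo_auc(run),
          B = bt$B, tau = bt$tau, SN = bt$SN, SP = bt$SP)
      }
      if (spec$method %in% IMPORTANCE_METHODS) {
        prof_without[[mn]] <- base$importance
        prof_with[[mn]] <- flow$importance
        importances[[paste(dn, mn, sep = ".")]] <-
          data.frame(dataset = dn, method = mn,
                     feature_id = names(flow$importance),
                     importance_flowps = unname(flow$importance),
                     importance_baseline = unname(base$importance))
      }
      if (!is.null(out_dir)) {
        calls <- vapply(B_values, function(B) {
          tau <- choose_threshold(flow$scores, flow$labels, B)
          as.integer(flow$scores >= tau)
        }, integer(length(flow$scores)))
        colnames(calls) <- paste0("call_at_B_", B_values)
        utils::write.table(
          data.frame(sample_id = names(flow$scores),
                     P_Fi = unname(flow$scores), calls),
          file.path(out_dir, paste0("scores_", dn, "_", mn, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (length(prof_with) >= 2) {
      correlations[[dn]] <- list(
        with_flowps = importance_correlations(prof_with),
        without_flowps = importance_correlations(prof_without))
    }
  }
  per_dataset <- do.call(rbind, per_rows)

  auc_tab <- unique(per_dataset[, c("dataset", "method", "flowps", "auc")])
  summary <- do.call(rbind, lapply(names(methods), function(mn) {
    w <- auc_tab$auc[auc_tab$method == mn & auc_tab$flowps]
    wo <- auc_tab$auc[auc_tab$method == mn & !auc_tab$flowps]
    tt <- if (length(w) >= 2) paired_ttest(w, wo)
          else list(t = NA_real_, p = NA_real_)
    data.frame(method = mn,
               median_auc_without = median(wo), median_auc_with = median(w),
               paired_t = tt$t, paired_p = tt$p)
  }))
  res <- structure(list(per_dataset = per_dataset, summary = summary,
                        correlations = correlations,
                        importances = importances,
                        seed = seed),
                   class = "ExperimentResult")
  if (!is.null(out_dir)) {
    utils::write.table(per_dataset, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(importances))
      utils::write.table(do.call(rbind, importances),
                         file.path(out_dir, "importances.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (dn in names(correlations)) {
      for (mode in c("with_flowps", "without_flowps")) {
        cm <- correlations[[dn]][[mode]]
        utils::write.table(
          data.frame(method = rownames(cm$pearson),
                     round(cm$pearson, 4)),
          file.path(out_dir, sprintf("correlation_%s_%s.tsv", dn, mode)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  res
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult over",
      length(unique(x$per_dataset$dataset)), "dataset(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
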