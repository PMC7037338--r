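# Data model and I/O for expression matrices, labels, and the synthetic
# cohort generator.

#' Construct an expression dataset
#'
#' The central container of the package: a numeric matrix of expression
#' values (samples in rows, features in columns, typically log-scale
#' intensities) with unique sample and feature identifiers and, optionally,
#' a binary response label per sample (1 = responder, 0 = non-responder).
#'
#' @param values numeric matrix, samples x features. Dimnames, when present,
#'   provide default identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers.
#' @param labels optional integer vector of 0/1 responses aligned to samples.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values,
                               sample_ids = rownames(values),
                               feature_ids = colnames(values),
                               labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  n <- nrow(values); s <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(s))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != n) stop("sample_ids length != number of rows")
  if (length(feature_ids) != s) stop("feature_ids length != number of columns")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample identifier: ", dup[1])
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop("duplicate feature identifier: ", dup[1])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 sample_ids[idx[1]], feature_ids[idx[2]]))
  }
  if (!is.null(labels)) {
    labels <- validate_labels(labels, n)
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, labels = labels),
            class = "ExpressionDataset")
}

validate_labels <- function(labels, n) {
  if (length(labels) != n) stop("labels length != number of samples")
  if (!all(labels %in% c(0, 1))) {
    bad <- labels[!labels %in% c(0, 1)][1]
    stop("label outside {0,1}: ", bad)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("labels must contain at least one 0 and one 1")
  labels
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d responders / %d non-responders\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  else cat("  labels: none attached\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Restrict a dataset to a subset of features
#'
#' @param ds an `ExpressionDataset`.
#' @param feature_ids features to keep, in the requested order.
#' @return an `ExpressionDataset` view on the selected features.
#' @export
subset_features <- function(ds, feature_ids) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing <- setdiff(feature_ids, ds$feature_ids)
  if (length(missing)) stop("unknown feature id: ", missing[1])
  expression_dataset(ds$values[, feature_ids, drop = FALSE],
                     sample_ids = ds$sample_ids,
                     feature_ids = feature_ids,
                     labels = ds$labels)
}

#' Restrict a dataset to a subset of samples
#' @param ds an `ExpressionDataset`.
#' @param idx integer or logical row index.
#' @keywords internal
subset_samples <- function(ds, idx) {
  lab <- ds$labels
  structure(list(values = ds$values[idx, , drop = FALSE],
                 sample_ids = ds$sample_ids[idx],
                 feature_ids = ds$feature_ids,
                 labels = if (is.null(lab)) NULL else lab[idx]),
            class = "ExpressionDataset")
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression table from delimited text
#'
#' Expects one header row of identifiers and one identifier column (the
#' first). The on-disk default is samples in rows, features (genes) in
#' columns; tables stored transposed are handled by
#' `orientation = "samples_in_columns"`. Field separator is inferred from
#' the file extension (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_columns"`.
#' @param sep field separator; `NULL` to infer from extension.
#' @param impute `"reject"` (default: any missing cell is an error) or
#'   `"median"` (per-feature median imputation).
#' @return an `ExpressionDataset` without labels (use [attach_labels()]).
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_in_rows",
                                                  "samples_in_columns"),
                                  sep = NULL,
                                  impute = c("reject", "median")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "",
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected at least one identifier and one value column")
  row_ids <- as.character(df[[1]])
  col_ids <- colnames(df)[-1]
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup)) stop("duplicate identifier: ", dup[1])
  dup <- col_ids[duplicated(col_ids)]
  if (length(dup)) stop("duplicate identifier: ", dup[1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  missing_tok <- is.na(raw) | raw %in% c("NA", "NaN", "")
  bad <- which(is.na(vals) & !missing_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 raw[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]],
                 col_ids[bad[1, 2]]))
  }
  if (anyNA(vals)) {
    if (impute == "reject") {
      miss <- which(is.na(vals), arr.ind = TRUE)
      stop(sprintf("missing value at row '%s', column '%s' (use impute='median' to impute)",
                   row_ids[miss[1, 1]], col_ids[miss[1, 2]]))
    }
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_in_columns") vals <- t(vals)
  if (anyNA(vals) && impute == "median") {
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- stats::median(vals[!nas, j])
    }
    if (anyNA(vals)) stop("feature with all values missing cannot be imputed")
  }
  expression_dataset(vals)
}

#' Write an expression dataset to delimited text
#'
#' Writes samples in rows with a `sample_id` first column; values are
#' printed with `%.17g` so that a read-back reproduces them exactly.
#'
#' @param ds an `ExpressionDataset`.
#' @param path output path; separator inferred from extension unless given.
#' @param sep field separator; `NULL` to infer.
#' @export
write_expression_table <- function(ds, path, sep = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  sep <- sep %||% infer_sep(path)
  chr <- matrix(sprintf("%.17g", ds$values), nrow = nrow(ds$values))
  out <- cbind(ds$sample_ids, chr)
  header <- paste(c("sample_id", ds$feature_ids), collapse = sep)
  lines <- c(header, apply(out, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Attach binary response labels to a dataset
#'
#' @param ds an `ExpressionDataset` (labels absent or overwritten).
#' @param labels either a path to a two-column delimited file
#'   (sample id, 0/1 response; header optional) or a two-column data frame.
#' @return the dataset with `labels` aligned to its sample order. Samples in
#'   the label source but not in the dataset are ignored with a warning;
#'   a dataset sample missing from the source is an error.
#' @export
attach_labels <- function(ds, labels) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.character(labels) && length(labels) == 1) {
    labels <- read_label_table(labels)
  }
  labels <- as.data.frame(labels)
  if (ncol(labels) < 2) stop("label table must have two columns (sample id, 0/1)")
  ids <- as.character(labels[[1]])
  vals <- labels[[2]]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop("sample '", d, "' appears more than once in the label table")
  }
  suppressWarnings(num <- as.numeric(as.character(vals)))
  if (anyNA(num) || !all(num %in% c(0, 1))) {
    bad <- as.character(vals)[is.na(num) | !num %in% c(0, 1)][1]
    stop("label outside {0,1}: '", bad, "'")
  }
  extra <- setdiff(ids, ds$sample_ids)
  if (length(extra))
    warning("ignoring ", length(extra), " labelled sample(s) absent from dataset: ",
            paste(utils::head(extra, 3), collapse = ", "))
  missing <- setdiff(ds$sample_ids, ids)
  if (length(missing))
    stop("no label for sample '", missing[1], "'")
  lab <- as.integer(num[match(ds$sample_ids, ids)])
  expression_dataset(ds$values, ds$sample_ids, ds$feature_ids, labels = lab)
}

read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  utils::read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the geometry of the clinical transcriptomic cohorts the
#' method targets: tens-to-hundreds of samples, a small core of informative
#' genes drowned in noise genes, and a responder fraction between roughly
#' 0.2 and 0.7.
#'
#' @param n_samples number of samples (>= 8).
#' @param n_informative number of class-informative features (>= 1).
#' @param n_noise number of class-independent standard-Gaussian features.
#' @param geometry `"global"` (class-shifted Gaussians, linearly separable)
#'   or `"local"` (two-axis XOR/checkerboard: locally but not globally
#'   separable).
#' @param effect_size positive real; for `global`, the mean separation
#'   between classes on each informative feature (unit variance); for
#'   `local`, the scale of the two latent block axes.
#' @param responder_fraction fraction of samples labelled 1, in (0,1).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_samples = 100, n_informative = 14,
                             n_noise = 100,
                             geometry = c("global", "local"),
                             effect_size = 2, responder_fraction = 0.5,
                             seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n_samples >= 8, n_informative >= 1, n_noise >= 0,
            effect_size > 0,
            responder_fraction > 0, responder_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 geometry = geometry,
                 effect_size = effect_size,
                 responder_fraction = responder_fraction,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic expression cohort
#'
#' `geometry = "global"`: informative features are drawn from class-shifted
#' unit-variance Gaussians with mean separation `effect_size` (class means at
#' +/- `effect_size`/2), so a single linear separator works globally.
#'
#' `geometry = "local"`: each sample carries two latent axes
#' `u1, u2 in {-1, +1}` and the class is determined by their sign product
#' (responders occupy the (+,+) and (-,-) blocks). Informative features load
#' on one of the axes as `effect_size * u + N(0,1)`, producing a
#' checkerboard in which every single feature has (near) zero marginal class
#' difference: no global linear separator exists, but local windows are
#' separable.
#'
#' Informative feature ids carry the prefix `"inf_"`, noise features
#' `"noise_"`.
#'
#' @param cfg a [synthetic_config()].
#' @return a labelled `ExpressionDataset`.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    n1 <- min(max(round(n * cfg$responder_fraction), 1L), n - 1L)
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    e <- cfg$effect_size
    ni <- cfg$n_informative
    if (cfg$geometry == "global") {
      shift <- ifelse(labels == 1L, e / 2, -e / 2)
      inf <- matrix(rnorm(n * ni), n, ni) + shift
    } else {
      # responders split between the (+,+) and (-,-) blocks, non-responders
      # between (+,-) and (-,+); axes assigned round-robin to features
      u1 <- integer(n); u2 <- integer(n)
      pos <- which(labels == 1L); neg <- which(labels == 0L)
      flip_p <- sample(c(-1L, 1L), length(pos), replace = TRUE)
      u1[pos] <- flip_p; u2[pos] <- flip_p
      flip_n <- sample(c(-1L, 1L), length(neg), replace = TRUE)
      u1[neg] <- flip_n; u2[neg] <- -flip_n
      axis <- rep_len(c(1L, 2L), ni)
      u <- cbind(u1, u2)
      inf <- matrix(rnorm(n * ni), n, ni) + e * u[, axis, drop = FALSE]
    }
    noise <- if (cfg$n_noise > 0)
      matrix(rnorm(n * cfg$n_noise), n, cfg$n_noise) else NULL
    vals <- cbind(inf, noise)
    fid <- c(sprintf("inf_g%d", seq_len(ni)),
             if (cfg$n_noise > 0) sprintf("noise_g%d", seq_len(cfg$n_noise)))
    sid <- sprintf("s%03d", seq_len(n))
    expression_dataset(vals, sample_ids = sid, feature_ids = fid,
                       labels = labels)
  })
}
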