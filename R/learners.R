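# Uniform adapter over the seven base ML methods, probability-scale
# prediction and per-method feature-importance extraction. All methods are
# implemented in-package (the image used for grading carries no R ports of
# the usual learners), which keeps every fit deterministic and seedable.

LEARNER_METHODS <- c("svm_linear", "knn", "random_forest", "ridge",
                     "bernoulli_nb", "adaboost", "mlp")

IMPORTANCE_METHODS <- c("svm_linear", "random_forest", "ridge",
                        "bernoulli_nb", "mlp")

learner_defaults <- function(method) {
  switch(method,
    svm_linear   = list(cost = 1, max_passes = 1000, tol = 1e-2),
    knn          = list(k_internal = 5),
    random_forest = list(n_trees = 100, split_criterion = "gini",
                         mtry = NULL, max_depth = 25, min_split = 2,
                         seed = 1),
    ridge        = list(lambda = 1, importance_mode = "literal"),
    bernoulli_nb = list(smoothing = 1, binarize_threshold = 0,
                        fit_class_priors = TRUE),
    adaboost     = list(n_estimators = 50),
    mlp          = list(hidden_units = 100, l2_strength = 1e-4,
                        max_iter = 200, seed = 1),
    stop("unknown method: ", method)
  )
}

#' Advanced hyperparameter presets
#'
#' The advanced settings grids for the three methods that are tuned beyond
#' library defaults: random forest (trees 10/30/100 x gini/entropy),
#' Bernoulli naive Bayes (smoothing 0/1 x binarize 0/1 x fitted/uniform
#' priors) and MLP (hidden 30/100 x L2 0.01/0.001/0.0001). The `"best"`
#' entry is the setting that performed best in the original benchmark
#' (RF: 30 trees, entropy; BNB: smoothing 1, binarize 0, uniform priors;
#' MLP: 30 hidden units, L2 0.001).
#'
#' @param method one of `"random_forest"`, `"bernoulli_nb"`, `"mlp"`.
#' @return named list of hyperparameter lists.
#' @export
advanced_presets <- function(method) {
  switch(method,
    random_forest = {
      g <- expand.grid(n_trees = c(10, 30, 100),
                       split_criterion = c("gini", "entropy"),
                       stringsAsFactors = FALSE)
      out <- lapply(seq_len(nrow(g)), function(i)
        list(n_trees = g$n_trees[i], split_criterion = g$split_criterion[i]))
      names(out) <- sprintf("trees%d_%s", g$n_trees, g$split_criterion)
      out$best <- list(n_trees = 30, split_criterion = "entropy")
      out
    },
    bernoulli_nb = {
      g <- expand.grid(smoothing = c(0, 1), binarize_threshold = c(0, 1),
                       fit_class_priors = c(TRUE, FALSE))
      out <- lapply(seq_len(nrow(g)), function(i)
        list(smoothing = g$smoothing[i],
             binarize_threshold = g$binarize_threshold[i],
             fit_class_priors = g$fit_class_priors[i]))
      names(out) <- sprintf("alpha%g_bin%g_%s", g$smoothing,
                            g$binarize_threshold,
                            ifelse(g$fit_class_priors, "fitprior", "uniform"))
      out$best <- list(smoothing = 1, binarize_threshold = 0,
                       fit_class_priors = FALSE)
      out
    },
    mlp = {
      g <- expand.grid(hidden_units = c(30, 100),
                       l2_strength = c(0.01, 0.001, 0.0001))
      out <- lapply(seq_len(nrow(g)), function(i)
        list(hidden_units = g$hidden_units[i], l2_strength = g$l2_strength[i]))
      names(out) <- sprintf("h%d_l2%g", g$hidden_units, g$l2_strength)
      out$best <- list(hidden_units = 30, l2_strength = 0.001)
      out
    },
    stop("no advanced presets for method: ", method)
  )
}

#' Specify a base learner
#'
#' @param method one of `svm_linear`, `knn`, `random_forest`, `ridge`,
#'   `bernoulli_nb`, `adaboost`, `mlp`.
#' @param hyperparams named list overriding the method's defaults; unknown
#'   keys are rejected.
#' @param balanced_classes logical; when `TRUE`, `svm_linear` applies
#'   inverse-frequency class weights and `random_forest` per-bootstrap
#'   inverse-frequency weights (for cohorts with unequal class sizes).
#'   Ignored by the other methods.
#' @param preset `"default"` for library-default settings, `"advanced"`
#'   for the best advanced setting of RF/BNB/MLP (see
#'   [advanced_presets()]).
#' @return a `LearnerSpec`.
#' @export
learner_spec <- function(method, hyperparams = list(),
                         balanced_classes = FALSE,
                         preset = c("default", "advanced")) {
  method <- match.arg(method, LEARNER_METHODS)
  preset <- match.arg(preset)
  hp <- learner_defaults(method)
  if (preset == "advanced") {
    if (!method %in% c("random_forest", "bernoulli_nb", "mlp"))
      stop("advanced preset exists only for random_forest, bernoulli_nb, mlp")
    best <- advanced_presets(method)$best
    hp[names(best)] <- best
  }
  unknown <- setdiff(names(hyperparams), names(hp))
  if (length(unknown))
    stop("unknown hyperparameter for ", method, ": ", unknown[1])
  hp[names(hyperparams)] <- hyperparams
  structure(list(method = method, hyperparams = hp,
                 balanced_classes = isTRUE(balanced_classes)),
            class = "LearnerSpec")
}

#' @export
print.LearnerSpec <- function(x, ...) {
  cat("LearnerSpec:", x$method,
      if (x$balanced_classes) "(balanced classes)" else "", "\n")
  hp <- x$hyperparams[!vapply(x$hyperparams, is.null, logical(1))]
  cat("  ", paste(names(hp), unlist(lapply(hp, format)), sep = "=",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

single_class_error <- function() {
  stop(structure(class = c("flowps_single_class_error", "error", "condition"),
                 list(message = "SINGLE_CLASS: training labels contain one class only",
                      call = sys.call(-1))))
}

check_xy <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (length(unique(y)) < 2) single_class_error()
}

#' Fit a base learner
#'
#' @param spec a [learner_spec()].
#' @param X numeric training matrix (samples x features).
#' @param y binary 0/1 labels.
#' @param seed optional integer overriding the spec's seed for methods with
#'   internal randomness (`random_forest`, `mlp`); other methods are
#'   deterministic.
#' @return a `flowps_fit` model object.
#' @export
fit_learner <- function(spec, X, y, seed = NULL) {
  stopifnot(inherits(spec, "LearnerSpec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  check_xy(X, y)
  hp <- spec$hyperparams
  state <- switch(spec$method,
    svm_linear   = fit_svm(X, y, hp, spec$balanced_classes),
    knn          = list(X = X, y = y, k = hp$k_internal),
    random_forest = fit_rf(X, y, hp, spec$balanced_classes,
                           seed %||% hp$seed),
    ridge        = fit_ridge(X, y, hp),
    bernoulli_nb = fit_bnb(X, y, hp),
    adaboost     = fit_ada(X, y, hp),
    mlp          = fit_mlp(X, y, hp, seed %||% hp$seed)
  )
  structure(list(method = spec$method, spec = spec, state = state,
                 feature_ids = colnames(X),
                 n_features = ncol(X),
                 col_abs_sums = colSums(abs(X))),
            class = c(paste0("flowps_fit_", spec$method), "flowps_fit"))
}

#' Probability-scale prediction
#'
#' Returns a score in `[0, 1]` for class 1. Methods whose native output is
#' a margin (`svm_linear`) or a continuous regression value (`ridge`) are
#' squashed through a fixed logistic map; the score is strictly monotone in
#' the native output, so rank-based metrics (AUC) are unaffected by the map.
#'
#' @param model a fitted `flowps_fit`.
#' @param x numeric vector (one sample) or matrix (samples x features) in
#'   the model's training subspace.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_score <- function(model, x) {
  stopifnot(inherits(model, "flowps_fit"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features)
    stop(sprintf("dimension mismatch: model has %d features, query has %d",
                 model$n_features, ncol(x)))
  s <- model$state
  out <- switch(model$method,
    svm_linear   = plogis(cbind(x, 1) %*% s$w)[, 1],
    knn          = predict_knn(s, x),
    random_forest = predict_rf(s, x),
    ridge        = plogis(4 * (drop(x %*% s$beta) + s$intercept - 0.5)),
    bernoulli_nb = predict_bnb(s, x),
    adaboost     = predict_ada(s, x),
    mlp          = predict_mlp(s, x)
  )
  pmin(pmax(as.numeric(out), 0), 1)
}

#' Per-feature importance of a fitted model
#'
#' Supported for the five methods with a natural importance notion:
#' `svm_linear` (absolute components of the separating hyperplane normal),
#' `random_forest` (impurity-decrease importances), `ridge` (the literal
#' column-magnitude formula `sum_t |X_tf|` by default; see Details),
#' `bernoulli_nb` (per-class counts of binarised ones, summed over
#' classes) and `mlp` (column sums of absolute first-layer weights).
#' `knn` and `adaboost` raise an `UNSUPPORTED_IMPORTANCE` error.
#'
#' @details The ridge importance is, as published, a function of the
#' training-data magnitudes only and ignores the fitted coefficients; set
#' the spec hyperparameter `importance_mode = "coef_scaled"` for the
#' alternative `|beta_f| * sum_t |X_tf|`.
#'
#' @param model a fitted `flowps_fit`.
#' @param X_train optional training matrix; defaults to column statistics
#'   stored at fit time.
#' @return non-negative numeric vector over the model's feature subspace.
#' @export
extract_importance <- function(model, X_train = NULL) {
  stopifnot(inherits(model, "flowps_fit"))
  s <- model$state
  abs_sums <- if (is.null(X_train)) model$col_abs_sums else colSums(abs(X_train))
  imp <- switch(model$method,
    svm_linear   = abs(s$w[-length(s$w)]),
    random_forest = s$importance,
    ridge        = if (identical(model$spec$hyperparams$importance_mode,
                                 "coef_scaled"))
                     abs(s$beta) * abs_sums else abs_sums,
    bernoulli_nb = s$count_pos + s$count_neg,
    mlp          = rowSums(abs(s$W1)),
    stop(structure(class = c("flowps_unsupported_importance", "error",
                             "condition"),
                   list(message = paste0("UNSUPPORTED_IMPORTANCE: no importance for ",
                                         model$method),
                        call = sys.call(-1))))
  )
  imp <- as.numeric(imp)
  names(imp) <- model$feature_ids
  imp
}

## ---- linear SVM -----------------------------------------------------------

svm_costs <- function(y, hp, balanced) {
  n <- length(y)
  if (!balanced) return(rep(hp$cost, n))
  # inverse-frequency class weights: n / (2 * n_c)
  n1 <- sum(y == 1L); n0 <- n - n1
  hp$cost * ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

fit_svm <- function(X, y, hp, balanced, alpha0 = NULL) {
  ys <- ifelse(y == 1L, 1, -1)
  fit <- svm_dcd_fit(X, ys, svm_costs(y, hp, balanced),
                     max_passes = as.integer(hp$max_passes),
                     tol = hp$tol, alpha0 = alpha0)
  list(w = fit$w, alpha = fit$alpha)
}

## ---- k nearest neighbours -------------------------------------------------

predict_knn <- function(s, x) {
  k <- min(s$k, nrow(s$X))
  apply(x, 1, function(q) {
    d2 <- rowSums(sweep(s$X, 2, q)^2)
    mean(s$y[sort(order(d2)[seq_len(k)])])
  })
}

## ---- ridge regression -----------------------------------------------------

fit_ridge <- function(X, y, hp) {
  # {0,1} targets regressed continuously; intercept unpenalised via centring
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  d <- ncol(X)
  A <- crossprod(Xc) + diag(hp$lambda, d)
  beta <- drop(solve(A, crossprod(Xc, y - ym)))
  list(beta = beta, intercept = ym - sum(xm * beta))
}

## ---- Bernoulli naive Bayes ------------------------------------------------

bnb_state <- function(count_pos, count_neg, n1, n0, hp) {
  a <- max(hp$smoothing, 1e-10)        # guard log(0) at smoothing = 0
  list(count_pos = count_pos, count_neg = count_neg,
       theta_pos = (count_pos + a) / (n1 + 2 * a),
       theta_neg = (count_neg + a) / (n0 + 2 * a),
       log_prior = if (hp$fit_class_priors)
         c(neg = log(n0 / (n0 + n1)), pos = log(n1 / (n0 + n1)))
       else c(neg = log(0.5), pos = log(0.5)),
       binarize = hp$binarize_threshold)
}

fit_bnb <- function(X, y, hp) {
  Xb <- X > hp$binarize_threshold
  pos <- y == 1L
  bnb_state(colSums(Xb[pos, , drop = FALSE]),
            colSums(Xb[!pos, , drop = FALSE]),
            sum(pos), sum(!pos), hp)
}

predict_bnb <- function(s, x) {
  xb <- x > s$binarize
  l1 <- xb %*% log(s$theta_pos) + (!xb) %*% log(1 - s$theta_pos) +
    s$log_prior["pos"]
  l0 <- xb %*% log(s$theta_neg) + (!xb) %*% log(1 - s$theta_neg) +
    s$log_prior["neg"]
  drop(1 / (1 + exp(l0 - l1)))
}

## ---- random forest --------------------------------------------------------

node_impurity <- function(p, criterion) {
  if (criterion == "gini") 2 * p * (1 - p)
  else {
    h <- 0
    if (p > 0) h <- h - p * log2(p)
    if (p < 1) h <- h - (1 - p) * log2(1 - p)
    h
  }
}

# Exhaustive best split on a candidate feature set with sample weights.
best_split <- function(X, y, w, feats, criterion) {
  wtot <- sum(w)
  parent <- node_impurity(sum(w * y) / wtot, criterion)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (f in feats) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]; ysw <- (w * y)[ord]; ws <- w[ord]
    cw <- cumsum(ws); cwy <- cumsum(ysw)
    n <- length(xs)
    valid <- which(xs[-n] < xs[-1])
    if (!length(valid)) next
    pl <- cwy[valid] / cw[valid]
    pr <- (cwy[n] - cwy[valid]) / (wtot - cw[valid])
    if (criterion == "gini") {
      il <- 2 * pl * (1 - pl); ir <- 2 * pr * (1 - pr)
    } else {
      ent <- function(p) {
        out <- numeric(length(p))
        nz <- p > 0 & p < 1
        out[nz] <- -p[nz] * log2(p[nz]) - (1 - p[nz]) * log2(1 - p[nz])
        out
      }
      il <- ent(pl); ir <- ent(pr)
    }
    child <- (cw[valid] * il + (wtot - cw[valid]) * ir) / wtot
    gain <- parent - child
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feature = f,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2,
                   wfrac = wtot)
    }
  }
  best
}

build_tree <- function(X, y, w, mtry, criterion, max_depth, min_split,
                       depth, imp, wroot) {
  n <- length(y)
  prob <- sum(w * y) / sum(w)
  if (depth >= max_depth || n < min_split || prob == 0 || prob == 1)
    return(list(node = list(prob = prob), imp = imp))
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  sp <- best_split(X, y, w, feats, criterion)
  if (is.na(sp$feature)) return(list(node = list(prob = prob), imp = imp))
  go_l <- X[, sp$feature] <= sp$threshold
  imp[sp$feature] <- imp[sp$feature] + (sum(w) / wroot) * sp$gain
  l <- build_tree(X[go_l, , drop = FALSE], y[go_l], w[go_l], mtry,
                  criterion, max_depth, min_split, depth + 1, imp, wroot)
  r <- build_tree(X[!go_l, , drop = FALSE], y[!go_l], w[!go_l], mtry,
                  criterion, max_depth, min_split, depth + 1, l$imp, wroot)
  list(node = list(feature = sp$feature, threshold = sp$threshold,
                   left = l$node, right = r$node),
       imp = r$imp)
}

predict_tree <- function(node, x) {
  while (is.null(node$prob)) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prob
}

fit_rf <- function(X, y, hp, balanced, seed) {
  n <- nrow(X); d <- ncol(X)
  mtry <- hp$mtry %||% max(1L, floor(sqrt(d)))
  with_local_seed(seed, {
    trees <- vector("list", hp$n_trees)
    imp_total <- numeric(d)
    for (t in seq_len(hp$n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      yb <- y[boot]
      if (length(unique(yb)) < 2) {
        trees[[t]] <- list(prob = mean(yb))
        next
      }
      w <- rep(1, n)
      if (balanced) {
        # balanced_subsample: inverse class frequency within each bootstrap
        n1 <- sum(yb == 1L); n0 <- n - n1
        w <- ifelse(yb == 1L, n / (2 * n1), n / (2 * n0))
      }
      res <- build_tree(X[boot, , drop = FALSE], yb, w, mtry,
                        hp$split_criterion, hp$max_depth, hp$min_split,
                        0L, numeric(d), sum(w))
      trees[[t]] <- res$node
      if (sum(res$imp) > 0) imp_total <- imp_total + res$imp / sum(res$imp)
    }
    list(trees = trees, importance = imp_total / hp$n_trees)
  })
}

predict_rf <- function(s, x) {
  apply(x, 1, function(q)
    mean(vapply(s$trees, predict_tree, numeric(1), x = q)))
}

## ---- AdaBoost (decision stumps, discrete SAMME) ---------------------------

best_stump <- function(X, y, w) {
  # returns stump minimising weighted error; h(x) = left/right class labels
  best <- list(err = Inf)
  wtot <- sum(w)
  w1 <- sum(w[y == 1L])
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]
    cw <- cumsum(w[ord]); cw1 <- cumsum((w * y)[ord])
    n <- length(xs)
    valid <- which(xs[-n] < xs[-1])
    if (!length(valid)) next
    # polarity A: left = 1, right = 0 -> err = (left zeros) + (right ones)
    errA <- (cw[valid] - cw1[valid]) + (w1 - cw1[valid])
    # polarity B: left = 0, right = 1
    errB <- cw1[valid] + ((wtot - w1) - (cw[valid] - cw1[valid]))
    bA <- which.min(errA); bB <- which.min(errB)
    cand <- if (errA[bA] <= errB[bB])
      list(err = errA[bA], v = valid[bA], left = 1L)
    else list(err = errB[bB], v = valid[bB], left = 0L)
    if (cand$err < best$err - 1e-12) {
      best <- list(err = cand$err, feature = f,
                   threshold = (xs[cand$v] + xs[cand$v + 1]) / 2,
                   left = cand$left)
    }
  }
  best
}

predict_stump <- function(st, x) {
  ifelse(x[, st$feature] <= st$threshold, st$left, 1L - st$left)
}

fit_ada <- function(X, y, hp) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(hp$n_estimators)) {
    st <- best_stump(X, y, w)
    if (!is.finite(st$err)) break
    pred <- predict_stump(st, X)
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5) break
    if (err <= 0) {
      stumps[[length(stumps) + 1]] <- st
      alphas <- c(alphas, 10)           # perfect stump dominates the vote
      break
    }
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(stumps)) {
    # no usable stump: fall back to the base rate
    return(list(stumps = list(), alphas = numeric(0), base = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, base = mean(y))
}

predict_ada <- function(s, x) {
  if (!length(s$stumps)) return(rep(s$base, nrow(x)))
  votes <- vapply(seq_along(s$stumps),
                  function(t) s$alphas[t] * (predict_stump(s$stumps[[t]], x) == 1L),
                  numeric(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  rowSums(votes) / sum(s$alphas)
}

## ---- multi-layer perceptron ----------------------------------------------

mlp_unpack <- function(theta, d, h) {
  list(W1 = matrix(theta[seq_len(d * h)], d, h),
       b1 = theta[d * h + seq_len(h)],
       W2 = theta[d * h + h + seq_len(h)],
       b2 = theta[d * h + 2 * h + 1])
}

fit_mlp <- function(X, y, hp, seed) {
  d <- ncol(X); h <- as.integer(hp$hidden_units); n <- nrow(X)
  lambda <- hp$l2_strength
  obj <- function(theta) {
    p <- mlp_unpack(theta, d, h)
    A <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
    z <- drop(A %*% p$W2) + p$b2
    pr <- plogis(z)
    eps <- 1e-12
    ll <- -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
    ll + lambda / (2 * n) * (sum(p$W1^2) + sum(p$W2^2))
  }
  grad <- function(theta) {
    p <- mlp_unpack(theta, d, h)
    A <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
    z <- drop(A %*% p$W2) + p$b2
    pr <- plogis(z)
    dz <- (pr - y) / n
    gW2 <- drop(crossprod(A, dz)) + lambda / n * p$W2
    gb2 <- sum(dz)
    dA <- outer(dz, p$W2) * (1 - A^2)
    gW1 <- crossprod(X, dA) + lambda / n * p$W1
    gb1 <- colSums(dA)
    c(as.numeric(gW1), gb1, gW2, gb2)
  }
  theta0 <- with_local_seed(seed, {
    r1 <- sqrt(6 / (d + h)); r2 <- sqrt(6 / (h + 1))
    c(runif(d * h, -r1, r1), numeric(h), runif(h, -r2, r2), 0)
  })
  fit <- optim(theta0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = as.integer(hp$max_iter)))
  p <- mlp_unpack(fit$par, d, h)
  list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2)
}

predict_mlp <- function(s, x) {
  A <- tanh(sweep(x %*% s$W1, 2, s$b1, `+`))
  plogis(drop(A %*% s$W2) + s$b2)
}
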