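methods_all <- c("svm_linear", "knn", "random_forest", "ridge",
                 "bernoulli_nb", "adaboost", "mlp")

test_that("all seven methods run under the single adapter contract", {
  ds <- tiny_dataset(n = 16, s = 4, seed = 1, separation = 3)
  q <- c(3, 0, 0, 0)                       # deep inside the class-1 region
  for (m in methods_all) {
    spec <- learner_spec(m, if (m == "mlp") list(hidden_units = 8) else list())
    fit <- fit_learner(spec, ds$values, ds$labels)
    sc <- predict_score(fit, ds$values)
    expect_length(sc, 16)
    expect_true(all(sc >= 0 & sc <= 1), info = m)
    expect_gt(predict_score(fit, q), 0.5)
    # determinism under fixed seed
    fit2 <- fit_learner(spec, ds$values, ds$labels)
    expect_identical(predict_score(fit2, ds$values), sc, info = m)
    # single-class training data raises the SINGLE_CLASS condition
    expect_error(fit_learner(spec, ds$values[ds$labels == 1, ],
                             ds$labels[ds$labels == 1]),
                 class = "flowps_single_class_error")
  }
})

test_that("dimension mismatches and unknown hyperparameters are rejected", {
  ds <- tiny_dataset()
  expect_error(learner_spec("svm_linear", list(gamma = 1)), "gamma")
  expect_error(learner_spec("gradient_boost"))
  fit <- fit_learner(learner_spec("ridge"), ds$values, ds$labels)
  expect_error(predict_score(fit, c(1, 2)), "mismatch")
})

test_that("knn score is the neighbour vote fraction", {
  X <- cbind(c(0, 0.1, 0.2, 5, 6))
  y <- c(1L, 1L, 0L, 1L, 0L)
  fit <- fit_learner(learner_spec("knn", list(k_internal = 3)), X, y)
  expect_equal(predict_score(fit, 0.05), 2 / 3)
})

test_that("advanced presets carry the published best settings", {
  expect_equal(advanced_presets("bernoulli_nb")$best,
               list(smoothing = 1, binarize_threshold = 0,
                    fit_class_priors = FALSE))
  expect_equal(advanced_presets("random_forest")$best,
               list(n_trees = 30, split_criterion = "entropy"))
  expect_equal(advanced_presets("mlp")$best,
               list(hidden_units = 30, l2_strength = 0.001))
  expect_length(advanced_presets("random_forest"), 7)  # 6 grid + best
  expect_length(advanced_presets("bernoulli_nb"), 9)   # 8 grid + best
  expect_length(advanced_presets("mlp"), 7)            # 6 grid + best
  spec <- learner_spec("bernoulli_nb", preset = "advanced")
  expect_false(spec$hyperparams$fit_class_priors)
  expect_error(learner_spec("knn", preset = "advanced"), "advanced")
})

test_that("svm importance is the absolute hyperplane normal", {
  set.seed(41)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(f1 = rnorm(n) + 4 * y, f2 = rnorm(n))
  fit <- fit_learner(learner_spec("svm_linear"), X, y)
  imp <- extract_importance(fit)
  expect_gt(imp[["f1"]], imp[["f2"]])
  expect_true(all(imp >= 0))
})

test_that("bernoulli_nb importance is the summed per-class count of binarised ones", {
  X <- cbind(f = c(-1, 2, 3), g = c(0, 0, 0))
  y <- c(0L, 1L, 1L)
  fit <- fit_learner(learner_spec("bernoulli_nb"), X, y)
  imp <- extract_importance(fit)
  expect_equal(imp[["f"]], 2)              # class 0: 0 ones, class 1: 2 ones
  expect_equal(imp[["g"]], 0)              # all-zero column
})

test_that("ridge importance follows the literal column-magnitude formula", {
  X <- cbind(f = c(1, -2, 3, -4), g = c(0.1, 0.2, -0.1, 0.3))
  y <- c(0L, 0L, 1L, 1L)
  fit <- fit_learner(learner_spec("ridge"), X, y)
  expect_equal(extract_importance(fit),
               c(f = 10, g = 0.7))
  alt <- fit_learner(learner_spec("ridge",
                                  list(importance_mode = "coef_scaled")),
                     X, y)
  expect_equal(extract_importance(alt),
               abs(alt$state$beta) * c(10, 0.7), ignore_attr = TRUE)
})

test_that("importance separates signal from noise for every supporting method", {
  ds <- tiny_dataset(n = 30, s = 5, seed = 6, separation = 4)
  for (m in c("svm_linear", "random_forest", "mlp")) {
    spec <- learner_spec(m, if (m == "mlp") list(hidden_units = 8) else list())
    imp <- extract_importance(fit_learner(spec, ds$values, ds$labels))
    expect_gt(imp[[1]], max(imp[-1]))      # f1 carries the separation
  }
  for (m in c("knn", "adaboost")) {
    fit <- fit_learner(learner_spec(m), ds$values, ds$labels)
    expect_error(extract_importance(fit),
                 class = "flowps_unsupported_importance")
  }
})

test_that("prediction is invariant to feature order", {
  ds <- tiny_dataset(n = 20, s = 4, seed = 8, separation = 3)
  perm <- c(3, 1, 4, 2)
  for (m in c("svm_linear", "ridge", "bernoulli_nb", "knn")) {
    spec <- learner_spec(m)
    a <- predict_score(fit_learner(spec, ds$values, ds$labels),
                       ds$values[5, ])
    b <- predict_score(fit_learner(spec, ds$values[, perm], ds$labels),
                       ds$values[5, perm])
    expect_equal(a, b, tolerance = 1e-8, info = m)
  }
})

test_that("class balancing upweights the minority class for svm", {
  set.seed(51)
  # 5 positives vs 45 negatives, overlapping clouds
  y <- c(rep(1L, 5), rep(0L, 45))
  X <- cbind(rnorm(50) + 1.2 * y, rnorm(50))
  plain <- fit_learner(learner_spec("svm_linear"), X, y)
  bal <- fit_learner(learner_spec("svm_linear", balanced_classes = TRUE),
                     X, y)
  expect_gt(mean(predict_score(bal, X[y == 1, ])),
            mean(predict_score(plain, X[y == 1, ])))
})

test_that("random forest and mlp are reproducible given a seed and react to it", {
  ds <- tiny_dataset(n = 20, s = 4, seed = 9, separation = 2)
  spec <- learner_spec("random_forest", list(n_trees = 15))
  a <- predict_score(fit_learner(spec, ds$values, ds$labels, seed = 7),
                     ds$values)
  b <- predict_score(fit_learner(spec, ds$values, ds$labels, seed = 7),
                     ds$values)
  c3 <- predict_score(fit_learner(spec, ds$values, ds$labels, seed = 8),
                      ds$values)
  expect_identical(a, b)
  expect_false(identical(a, c3))
  auc <- naive_auc(a, ds$labels)
  expect_gt(auc, 0.9)
})

test_that("svm solver matches a reference QP on a tiny separable problem", {
  # two points, one per class: analytic SVM solution w = (x+ - x-) * 2 /
  # ||x+ - x-||^2 when unconstrained by C; with bias regularised the
  # margin midpoint still scores 0.5
  X <- cbind(c(-1, 1))
  y <- c(0L, 1L)
  fit <- fit_learner(learner_spec("svm_linear", list(tol = 1e-6)), X, y)
  sc_mid <- predict_score(fit, 0)
  expect_equal(sc_mid, 0.5, tolerance = 1e-3)
  expect_gt(predict_score(fit, 1), predict_score(fit, -1))
})
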