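test_that("roc_auc matches hand-derived values and the pair oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(81)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    lab <- integer(n); lab[sample(n, sample(n - 1, 1))] <- 1L
    if (all(lab == lab[1])) next
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(roc_auc(sc, lab), naive_auc(sc, lab))
  }
})

test_that("roc_auc is rank-invariant and complement-symmetric", {
  set.seed(82)
  sc <- runif(30); lab <- rep(c(0L, 1L), 15)
  a <- roc_auc(sc, lab)
  expect_equal(roc_auc(plogis(5 * sc - 2), lab), a)
  expect_equal(roc_auc(sc, lab) + roc_auc(1 - sc, lab), 1)
})

test_that("choose_threshold minimises the penalty with the stated tie-break", {
  expect_equal(choose_threshold(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1), B = 1),
               0.5)
  sc <- c(0.3, 0.5, 0.6, 0.9); lab <- c(1, 0, 1, 0)
  expect_equal(choose_threshold(sc, lab, B = 1e6), Inf)   # FP dominates
  expect_equal(choose_threshold(sc, lab, B = 1e-6), -Inf) # FN dominates
  set.seed(83)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    lab <- integer(n); lab[sample(n, sample(n - 1, 1))] <- 1L
    if (all(lab == lab[1])) next
    sc <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    B <- sample(c(0.1, 0.25, 1, 4, 10), 1)
    expect_equal(choose_threshold(sc, lab, B), naive_threshold(sc, lab, B))
  }
})

test_that("sensitivity and specificity follow the >= tau call rule", {
  expect_equal(sensitivity_specificity(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                                       0.5),
               c(SN = 1, SP = 1))
  expect_equal(sensitivity_specificity(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                                       0.95),
               c(SN = 0, SP = 1))
  sc <- c(0.2, 0.6, 0.4, 0.8); lab <- c(0, 1, 0, 1)
  expect_equal(sensitivity_specificity(sc, lab, 0.5), c(SN = 1, SP = 1))
  expect_equal(sensitivity_specificity(sc, lab, 0.3), c(SN = 1, SP = 0.5))
})

test_that("tau is non-decreasing in B, hence SN non-increasing and SP non-decreasing", {
  set.seed(84)
  Bs <- c(0.1, 0.25, 1, 4, 10)
  for (rep in 1:40) {
    n <- sample(8:25, 1)
    lab <- integer(n); lab[sample(n, sample(n - 1, 1))] <- 1L
    if (all(lab == lab[1])) next
    sc <- round(runif(n), 2)
    taus <- vapply(Bs, function(B) choose_threshold(sc, lab, B), numeric(1))
    expect_false(is.unsorted(taus))       # tolerates repeated +/-Inf
    snsp <- vapply(taus, function(t) sensitivity_specificity(sc, lab, t),
                   numeric(2))
    expect_true(all(diff(snsp["SN", ]) <= 0))
    expect_true(all(diff(snsp["SP", ]) >= 0))
  }
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  w <- c(0.8, 0.75, 0.9); wo <- w - c(0.1, 0.05, 0.15)
  tt <- paired_ttest(w, wo)
  expect_equal(tt$t, 3.4641, tolerance = 1e-4)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  expect_equal(tt$df, 2)
  # antisymmetry
  expect_equal(paired_ttest(wo, w)$t, -tt$t)
  deg <- paired_ttest(c(0.7, 0.8), c(0.7, 0.8))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
})

test_that("importance correlations: identity, reversal, hand-derived Spearman, flags", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  cm <- importance_correlations(list(m1 = v, m2 = v))
  expect_equal(cm$pearson["m1", "m2"], 1)
  expect_equal(cm$spearman["m1", "m2"], 1)
  rev <- importance_correlations(list(m1 = v,
                                      m2 = setNames(rev(unname(v)),
                                                    names(v))))
  expect_equal(rev$spearman["m1", "m2"], -1)
  sp <- importance_correlations(list(m1 = v,
                                     m2 = c(a = 1, b = 3, c = 2, d = 4)))
  expect_equal(sp$spearman["m1", "m2"], 0.8)  # 1 - 6*2/(4*15)
  flat <- importance_correlations(list(m1 = v, m2 = v * 0))
  expect_true(flat$undefined["m1", "m2"])
  expect_true(is.na(flat$pearson["m1", "m2"]))
  expect_error(importance_correlations(list(m1 = v, m2 = v[1:3])),
               "mismatch")
})

test_that("balance_table reports SN/SP per B with monotone behaviour", {
  ds <- generate_synthetic(synthetic_config(24, 4, 4, "global", 4, 0.5,
                                            seed = 85))
  out <- flowps_baseline(ds, learner_spec("ridge"))
  bt <- balance_table(out)
  expect_identical(bt$B, c(0.1, 0.25, 1, 4, 10))
  expect_true(all(diff(bt$tau) >= 0))
  expect_true(all(diff(bt$SN) <= 0))
  expect_true(all(diff(bt$SP) >= 0))
})

test_that("run_experiment produces the comparison schema and is reproducible", {
  datasets <- list(d1 = synthetic_config(16, 3, 3, "local", 3, 0.5, seed = 1),
                   d2 = synthetic_config(16, 3, 3, "local", 3, 0.5, seed = 2),
                   d3 = synthetic_config(16, 3, 3, "local", 3, 0.5, seed = 3))
  g <- grid_spec(c(0, 1), c(6, 10, 14))
  res <- run_experiment(datasets, c("ridge", "bernoulli_nb"), grid = g,
                        seed = 4)
  expect_s3_class(res, "ExperimentResult")
  expect_setequal(res$summary$method, c("ridge", "bernoulli_nb"))
  expect_true(all(c("median_auc_without", "median_auc_with", "paired_p")
                  %in% names(res$summary)))
  expect_equal(nrow(res$per_dataset), 3 * 2 * 2 * 5)  # ds x method x run x B
  expect_length(res$correlations, 3)
  # reproducibility
  res2 <- run_experiment(datasets, c("ridge", "bernoulli_nb"), grid = g,
                         seed = 4)
  expect_identical(res$per_dataset, res2$per_dataset)
  expect_identical(res$summary, res2$summary)
})

test_that("run_experiment persists TSV reports when asked", {
  dir <- withr::local_tempdir()
  res <- run_experiment(list(synthetic_config(14, 3, 2, "global", 3, 0.5,
                                              seed = 9)),
                        "ridge", grid = grid_spec(0, c(6, 12)),
                        seed = 1, out_dir = dir)
  expect_true(file.exists(file.path(dir, "metrics.tsv")))
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  sc <- list.files(dir, pattern = "^scores_")
  expect_length(sc, 1)
  tab <- read.delim(file.path(dir, sc))
  expect_true(all(c("sample_id", "P_Fi", "call_at_B_0.1") %in% names(tab)))
})
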