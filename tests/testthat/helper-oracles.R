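# Naive re-implementations used as independent oracles: straightforward
# enumeration, no shared code with the package internals.

naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

naive_relevant <- function(train, query, m) {
  sapply(seq_len(ncol(train)), function(s) {
    above <- sum(train[, s] > query[s])
    below <- sum(train[, s] < query[s])
    above >= m && below >= m
  })
}

naive_knn <- function(train, query, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query)^2)))
  # ties by ascending index: order on (distance, index)
  ord <- order(d, seq_along(d))
  sort(ord[seq_len(k)])
}

naive_threshold <- function(scores, labels, B) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  best_tau <- NA; best_pen <- Inf
  for (tau in cand) {
    fp <- sum(scores >= tau & labels == 0)
    fn <- sum(scores < tau & labels == 1)
    pen <- B * fp + fn
    if (pen < best_pen) { best_pen <- pen; best_tau <- tau }
  }
  best_tau
}

naive_accountable <- function(auc, p) {
  mx <- max(auc)
  sel <- matrix(FALSE, nrow(auc), ncol(auc))
  for (a in seq_len(nrow(auc))) for (b in seq_len(ncol(auc))) {
    if (auc[a, b] > p * mx || auc[a, b] == mx) sel[a, b] <- TRUE
  }
  sel
}

# small labelled dataset with both classes, for adapter-level tests
tiny_dataset <- function(n = 12, s = 4, seed = 42, separation = 2) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  vals <- matrix(rnorm(n * s), n, s)
  vals[, 1] <- vals[, 1] + separation * labels
  expression_dataset(vals, sample_ids = paste0("s", seq_len(n)),
                     feature_ids = paste0("f", seq_len(s)),
                     labels = labels)
}
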