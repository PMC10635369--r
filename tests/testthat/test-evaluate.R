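# brute-force AUC oracle: pairwise win fraction with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

test_that("roc_auc equals the pairwise-comparison statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "undefined metric")
  # tied/untied mixtures against the brute-force oracle
  with_seed(31, {
    for (rep in 1:20) {
      n <- sample(6:200, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
      y <- rbinom(n, 1, 0.3)
      if (sum(y) == 0 || sum(y) == n) next
      expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
    }
  })
})

test_that("average_precision implements the recall-weighted sum", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # worked 3-point case: AP = 0.5*0.5 + 0.5*(2/3) = 7/12
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(0, 1, 1)), 7 / 12)
  expect_error(average_precision(c(0.3, 0.2), c(0, 0)), "undefined metric")
  # invariance under strictly monotone score transforms
  with_seed(13, {
    s <- runif(50); y <- rbinom(50, 1, 0.3); y[1] <- 1; y[2] <- 0
    expect_equal(average_precision(s, y), average_precision(exp(3 * s), y))
    expect_equal(roc_auc(s, y), roc_auc(s^3, y))
  })
})

test_that("binary annotation AP is precision x recall", {
  # constructed contingency: TP=72, FP=18, FN=8 -> P=0.8, R=0.9
  pred <- c(rep(1, 90), rep(0, 30))
  truth <- c(rep(1, 72), rep(0, 18), rep(1, 8), rep(0, 22))
  expect_equal(binary_annotation_ap(pred, truth), 0.8 * 0.9)
  expect_equal(binary_annotation_ap(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_error(binary_annotation_ap(c(0, 0), c(1, 0)), "no positives")
  # P x R equals the Eq.-5 sum truncated at the single informative threshold
  tp <- sum(pred & truth)
  r1 <- tp / sum(truth); p1 <- tp / sum(pred)
  expect_equal(binary_annotation_ap(pred, truth), r1 * p1)
})

test_that("top-k precision/recall matches a sort-and-count oracle", {
  with_seed(41, {
    n <- 20
    s <- runif(n); y <- rbinom(n, 1, 0.4); y[1] <- 1
    pairs <- data.frame(i = sample(100, n), j = sample(200:300, n))
    L <- 12
    res <- topk_precision_recall(s, y, pairs, L)
    for (r in seq_len(nrow(res))) {
      k <- res$k[r]
      ord <- order(-s, pairs$i, pairs$j)
      tp <- sum(y[ord][seq_len(k)])
      expect_equal(res$precision[r], tp / k)
      expect_equal(res$recall[r], tp / sum(y))
    }
    expect_equal(res$k, pmax(1, floor(L * c(1, 1/2, 1/5, 1/10))))
  })
  # all positives in top k -> precision 1; k = n -> recall 1
  s <- c(0.9, 0.8, 0.1, 0.05); y <- c(1, 1, 0, 0)
  pairs <- data.frame(i = 1:4, j = 11:14)
  res <- topk_precision_recall(s, y, pairs, L = 2, fractions = 1)
  expect_equal(res$precision, 1)
  res2 <- topk_precision_recall(s, y, pairs, L = 4, fractions = 1)
  expect_equal(res2$recall, 1)
  expect_warning(topk_precision_recall(s, y, pairs, L = 40, fractions = 1),
                 "clamped")
})

test_that("feature stats are the grand mean and grand population SD", {
  expect_equal(feature_stats(matrix(0.5, 3, 4)),
               list(feature_mean = 0.5, feature_variance = 0))
  expect_equal(feature_stats(matrix(c(-1, 1), 2, 1)),
               list(feature_mean = 0, feature_variance = 1))
  expect_error(feature_stats(matrix(numeric(0), 0, 0)), "empty")
  with_seed(17, {
    x <- matrix(rnorm(60), 6, 10)
    fs <- feature_stats(x)
    # two-pass oracle
    mu <- sum(x) / length(x)
    expect_equal(fs$feature_mean, mu)
    expect_equal(fs$feature_variance, sqrt(sum((x - mu)^2) / length(x)))
  })
})

test_that("a random scorer has AP near the contact ratio and AUC near 0.5", {
  with_seed(23, {
    y <- rbinom(4000, 1, 0.2)
    s <- runif(4000)
    expect_lt(abs(average_precision(s, y) - mean(y)), 0.05)
    expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
  })
})

test_that("cross-validation partitions by sequence and is seed-stable", {
  ds <- with_seed(2, make_benchmark(n_sequences = 6, residues_range = c(10, 12),
                                    n_helices_range = c(2, 2), seed = 4))
  entries <- benchmark_entries(ds)
  cfg <- model_config(hidden_sizes = c(32, 16, 16, 8, 8, 4), epochs = 4,
                      seed = 1)
  rep1 <- cross_validate(entries, cfg, k = 3, repeats = 2, seed = 9)
  # every sequence held out exactly once per repeat
  for (r in 1:2) {
    held <- rep1$per_sequence$sequence_id[rep1$per_sequence$repeat_ == r]
    expect_setequal(held, vapply(entries, function(d) d$id, ""))
    expect_equal(length(held), length(entries))
  }
  rep2 <- cross_validate(entries, cfg, k = 3, repeats = 2, seed = 9)
  expect_identical(rep1$per_sequence, rep2$per_sequence)
  expect_error(cross_validate(entries, cfg, k = 10), "fewer sequences")
})

test_that("compare_sources counts improved sequences", {
  mk <- function(aps) {
    structure(list(per_sequence = data.frame(
      sequence_id = sprintf("s%d", seq_along(aps)), ap = aps,
      auc = 0.9, n_pairs = 10, n_contacts = 2),
      mean_ap = mean(aps), mean_auc = 0.9), class = "MetricsReport")
  }
  same <- compare_sources(NULL, mk(c(0.5, 0.6)), mk(c(0.5, 0.6)))
  expect_equal(same$n_improved, 0)
  all_up <- compare_sources(NULL, mk(c(0.7, 0.8)), mk(c(0.5, 0.6)))
  expect_equal(all_up$pct_improved, 100)
  # recount oracle on a mixed table
  mixed <- compare_sources(NULL, mk(c(0.7, 0.4, 0.9)), mk(c(0.5, 0.6, 0.8)))
  expect_equal(mixed$n_improved, sum(mixed$table$ap_delta > 0))
  expect_error(compare_sources(NULL, mk(c(0.5)), mk(c(0.5, 0.6))), "mismatched")
})
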