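ps_from_labels <- function(truth, predicted, K = max(truth, predicted)) {
  probs <- t(vapply(predicted, encode_one_hot, numeric(K), K = K))
  prediction_set(truth, probs, predicted = predicted)
}

test_that("accuracy and MAE follow their definitions", {
  ps <- ps_from_labels(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(accuracy(ps), 1)
  expect_equal(mean_absolute_error(ps), 0)
  ps2 <- ps_from_labels(c(1, 3), c(3, 1))
  expect_equal(accuracy(ps2), 0)
  expect_equal(mean_absolute_error(ps2), 2)
  ps3 <- ps_from_labels(c(1, 2, 3, 4), c(1, 2, 3, 3))
  expect_equal(accuracy(ps3), 0.75)
  expect_equal(mean_absolute_error(ps3), 0.25)
})

test_that("MAE dominates the error rate and vanishes iff accuracy is 1", {
  set.seed(21)
  for (i in 1:100) {
    K <- sample(2:7, 1)
    n <- sample(5:40, 1)
    ps <- ps_from_labels(sample.int(K, n, TRUE), sample.int(K, n, TRUE), K)
    expect_gte(mean_absolute_error(ps) - (1 - accuracy(ps)), -1e-12)
    expect_identical(mean_absolute_error(ps) == 0, accuracy(ps) == 1)
  }
})

test_that("Kendall tau handles perfect, reversed and independent labels", {
  expect_equal(kendall_tau(ps_from_labels(c(1, 2, 2, 3), c(1, 2, 2, 3))), 1)
  expect_equal(kendall_tau(ps_from_labels(1:5, 5:1)), -1)
  set.seed(22)
  ps <- ps_from_labels(sample.int(7, 10000, TRUE), sample.int(7, 10000, TRUE))
  expect_lt(abs(kendall_tau(ps)), 0.05)
  # constant predictions have no defined rank correlation
  expect_true(is.na(kendall_tau(ps_from_labels(c(1, 2, 3), c(2, 2, 2)))))
})

test_that("tau-b matches explicit pair counting on random small sets", {
  set.seed(23)
  for (i in 1:100) {
    K <- sample(3:6, 1)
    n <- sample(8:25, 1)
    truth <- sample.int(K, n, TRUE)
    pred <- sample.int(K, n, TRUE)
    if (sd(truth) == 0 || sd(pred) == 0) next
    ps <- ps_from_labels(truth, pred, K)
    expect_equal(kendall_tau(ps), brute_tau_b(truth, pred),
                 tolerance = 1e-6)
  }
})

test_that("macro AUROC matches a rank-sum oracle and handles edge cases", {
  set.seed(24)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(8:25, 1)
    truth <- sample.int(K, n, TRUE)
    if (length(unique(truth)) < 2) next
    probs <- t(replicate(n, random_simplex(K)))
    ps <- prediction_set(truth, probs)
    oracle <- mean(sapply(sort(unique(truth)), function(k)
      brute_auc(truth == k, probs[, k])))
    expect_equal(macro_auroc(ps), oracle, tolerance = 1e-6)
  }
  # one-hot probabilities equal to the truth give a perfect score
  ps <- ps_from_labels(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(macro_auroc(ps), 1)
  # constant scores are uninformative
  ps2 <- prediction_set(c(1, 1, 2, 2), matrix(0.5, 4, 2))
  expect_equal(macro_auroc(ps2), 0.5)
  expect_error(macro_auroc(ps_from_labels(c(2, 2), c(1, 2), K = 3)),
               "single class")
})

test_that("the ordinal classification index honours its contract", {
  # zero on a diagonal confusion matrix
  expect_equal(uoc_index(ps_from_labels(1:4, 1:4)), 0)
  # farther misclassification scores strictly higher
  near <- uoc_index(ps_from_labels(c(1, 2, 3, 4), c(1, 2, 3, 3)))
  far <- uoc_index(ps_from_labels(c(1, 2, 3, 4), c(1, 2, 3, 2)))
  expect_gt(near, 0)
  expect_gt(far, near)
  # invariant to duplicating every observation (prevalence rescaling)
  t1 <- c(1, 2, 3, 3, 4); p1 <- c(1, 3, 3, 4, 4)
  expect_equal(uoc_index(ps_from_labels(rep(t1, 3), rep(p1, 3))),
               uoc_index(ps_from_labels(t1, p1)))
  # bounded on the 0-100 scale, worst case at maximal displacement
  worst <- uoc_index(ps_from_labels(c(1, 4), c(4, 1)))
  expect_lte(worst, 100)
  expect_gt(worst, 50)
  # a replacement index can be plugged in
  ps <- ps_from_labels(c(1, 2), c(2, 2))
  expect_equal(uoc_index(ps, index_fun = function(cm) 42), 42)
})

test_that("Gini sparsity spans uniform to one-hot", {
  expect_equal(gini_sparsity(rep(1 / 7, 7)), 0)
  expect_equal(gini_sparsity(encode_one_hot(3, 7)), 6 / 7)
  expect_equal(gini_sparsity(c(0.5, 0.5, 0, 0)), 0.5)
  set.seed(25)
  for (i in 1:200) {
    K <- sample(2:9, 1)
    p <- random_simplex(K)
    g <- gini_sparsity(p)
    expect_gte(g, 0)
    expect_lte(g, (K - 1) / K)
    expect_equal(g, gini_sparsity(sample(p)))   # permutation-invariant
  }
  # mean over a prediction set
  ps <- prediction_set(c(1, 2), rbind(c(1, 0), c(0.5, 0.5)))
  expect_equal(gini_sparsity(ps), mean(c(0.5, 0)))
})

test_that("metric report collects all metrics and serialises", {
  ps <- small_prediction_set(40, 4, seed = 26)
  rep <- metric_report(ps)
  expect_named(rep, c("accuracy", "mae", "uoc", "kendall_tau",
                      "macro_auroc", "mean_gini"))
  expect_true(all(is.finite(unlist(rep))))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_metric_report(rep, csv, json)
  back <- read.csv(csv)
  expect_equal(back$mae, rep$mae)
  expect_match(readLines(json), "\"accuracy\":")
  cm <- tempfile(fileext = ".csv")
  write_confusion_matrix(ps, cm)
  expect_equal(sum(read.csv(cm, row.names = 1)), ps$n)
})
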