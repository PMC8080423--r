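test_that("head stack follows the protocol and sizes its output by loss", {
  h <- build_head(7, "ce")
  types <- sapply(h$layers, `[[`, "type")
  expect_equal(types, c("dropout", "dense", "dropout", "dense", "dense"))
  expect_equal(sapply(h$layers[c(2, 4)], `[[`, "units"), c(512, 256))
  expect_equal(sapply(h$layers[c(1, 3)], `[[`, "p"), c(0.2, 0.2))
  expect_equal(h$output_width, 7)
  expect_equal(build_head(7, "oe")$output_width, 6)
  expect_equal(build_head(4, "bu")$output_width, 1)
  expect_equal(build_head(4, "pu")$output_width, 1)
  expect_equal(build_head(5, "ho2")$output_width, 5)
  expect_output(print(h), "dense\\(512, relu\\)")
})

test_that("stratified folds partition the data and preserve class ratios", {
  set.seed(31)
  for (rep in 1:20) {
    K <- sample(2:7, 1)
    counts <- sample(8:25, K, replace = TRUE)
    y <- rep(seq_len(K), times = counts)
    nf <- sample(2:8, 1)
    f <- stratified_folds(y, nf, seed = rep)
    expect_setequal(unique(f), seq_len(nf))
    expect_equal(length(f), length(y))
    tab <- table(factor(f, levels = seq_len(nf)), y)
    for (k in seq_len(K))
      expect_lt(max(abs(tab[, k] - counts[k] / nf)), 1)
  }
  y <- rep(1:7, each = 10)
  expect_true(all(table(stratified_folds(y, 10, 1), y) == 1))
  expect_true(all(table(stratified_folds(y, 70, 1)) == 1))   # leave-one-out
  expect_identical(stratified_folds(y, 10, 5), stratified_folds(y, 10, 5))
})

test_that("lambda tuning selects sensible penalty weights", {
  cfg1 <- train_config(loss = "co2", lambda_grid = 0.3)
  expect_equal(tune_lambda(grade ~ ., data.frame(grade = 1, x = 1), cfg1),
               0.3)
  expect_error(train_config(loss = "co2", lambda_grid = numeric(0)))
  # on easy data an absurdly large penalty weight loses to lambda = 0
  d <- sample_ordinal_features(ordinal_dataset_spec(
    K = 3, n_per_class = 40, feature_dim = 2, class_separation = 4,
    seed = 32))
  cfg <- train_config(loss = "co2", lambda_grid = c(0, 5000),
                      inner_folds = 3, epochs = 25, lr = 0.1, seed = 33)
  lam <- tune_lambda(grade ~ ., d, cfg)
  expect_equal(lam, 0)
  expect_identical(lam, tune_lambda(grade ~ ., d, cfg))  # deterministic
})

test_that("run_experiment aggregates folds and is reproducible", {
  d <- sample_ordinal_features(ordinal_dataset_spec(
    K = 3, n_per_class = 30, feature_dim = 2, class_separation = 5,
    seed = 34))
  cfg <- train_config(loss = "co2", lambda_grid = 1, epochs = 25, lr = 0.1,
                      outer_folds = 3, seed = 35)
  res <- run_experiment(grade ~ ., d, cfg)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$folds), 3)
  expect_true(all(res$folds$accuracy > 0.95))   # near-separable data
  expect_equal(res$mean[["mae"]], mean(res$folds$mae))
  expect_equal(res$sd[["mae"]], sd(res$folds$mae))
  res2 <- run_experiment(grade ~ ., d, cfg)
  expect_equal(res$folds, res2$folds)
  expect_output(print(res), "3 outer folds")
  # a training split losing an entire class is refused with a hint
  tiny <- d[c(1:4, 31:34, 61), ]          # a single class-3 observation
  cfg_bad <- train_config(loss = "ce", outer_folds = 4, epochs = 2,
                          seed = 36)
  expect_error(run_experiment(grade ~ ., tiny, cfg_bad), "absent")
})

test_that("CO with a zero-lambda grid reproduces the CE experiment", {
  d <- sample_ordinal_features(ordinal_dataset_spec(
    K = 3, n_per_class = 25, feature_dim = 2, class_separation = 2,
    seed = 37))
  cfg_ce <- train_config(loss = "ce", epochs = 20, lr = 0.1,
                         outer_folds = 3, seed = 38)
  cfg_co <- train_config(loss = "co", lambda_grid = 0, epochs = 20,
                         lr = 0.1, outer_folds = 3, seed = 38)
  rce <- run_experiment(grade ~ ., d, cfg_ce)
  rco <- run_experiment(grade ~ ., d, cfg_co)
  expect_equal(rce$folds, rco$folds, tolerance = 1e-10)
})

test_that("league table marks similarity with the paired t-test", {
  mk <- function(vals, seed) {
    cfg <- train_config(loss = "ce", outer_folds = length(vals), seed = seed)
    structure(list(folds = data.frame(accuracy = NA, mae = vals, uoc = NA,
                                      kendall_tau = NA, macro_auroc = NA,
                                      mean_gini = NA,
                                      fold = seq_along(vals)),
                   mean = c(mae = mean(vals)), sd = c(mae = sd(vals)),
                   chosen_lambda = 0, config = cfg),
              class = "experiment_result")
  }
  # identical folds: p = 1, similar
  lt <- compare_models(list(a = mk(c(1, 2, 3), 1), b = mk(c(1, 2, 3), 2)))
  expect_true(all(lt$similar))
  expect_equal(sum(lt$best), 1)
  # constant nonzero difference: zero variance, treated as dissimilar
  lt2 <- compare_models(list(a = mk(c(2, 3, 4, 5, 6), 1),
                             b = mk(c(1, 2, 3, 4, 5), 2)))
  expect_equal(lt2$p_value[!lt2$best], 0)
  expect_false(any(lt2$similar[!lt2$best]))
  expect_true(lt2$best[2])   # lower MAE wins
  # generic case agrees with the textbook formula
  set.seed(39)
  a <- runif(10, 1, 2); b <- a + rnorm(10, 0.05, 0.1)
  lt3 <- compare_models(list(a = mk(a, 1), b = mk(b, 2)))
  expect_equal(lt3$p_value[!lt3$best],
               brute_paired_t_p(if (lt3$best[1]) b else a,
                                if (lt3$best[1]) a else b),
               tolerance = 1e-6)
  # higher-is-better metrics choose the maximum
  mk_acc <- function(vals, seed) {
    r <- mk(vals, seed); r$folds$accuracy <- vals; r
  }
  lt4 <- compare_models(list(lo = mk_acc(c(.5, .6, .7), 1),
                             hi = mk_acc(c(.8, .9, .95), 2)),
                        metric = "accuracy")
  expect_true(lt4$best[2])
  out <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  write_league_table(lt4, out, md)
  expect_equal(nrow(read.csv(out)), 2)
  expect_match(readLines(md)[1], "model")
})

test_that("prediction CSVs carry labels, probabilities and classes", {
  ps <- small_prediction_set(15, 4, seed = 40)
  path <- tempfile(fileext = ".csv")
  write_predictions(ps, path)
  back <- read.csv(path)
  expect_equal(names(back), c("true_label", paste0("p", 1:4), "predicted"))
  expect_equal(back$predicted, ps$predicted)
  expect_equal(rowSums(back[paste0("p", 1:4)]), rep(1, 15), tolerance = 1e-6)
})
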