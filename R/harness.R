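#' Experiment configuration
#'
#' Collects every knob of the training and evaluation protocol: the loss
#' and its penalty-weight grid, the decoding rule, the optimisation
#' schedule (100 epochs from learning rate `1e-4`, reduced by 10% after
#' 10 stagnant epochs), and the cross-validation layout (10 stratified
#' outer folds with nested 5-fold tuning of `lambda` on each training
#' split).
#'
#' @param loss Loss name, one of [ordinal_loss_names()].
#' @param lambda_grid Candidate penalty weights for the nested tuning of
#'   the `"co"`/`"co2"`/`"ho2"` losses; a single value skips the inner
#'   cross-validation.
#' @param delta,boundary_mode,tau Passed to [loss_config()].
#' @param rule Decoding rule, `"mode"` or `"mean"`.
#' @param epochs,lr,batch_size,patience,factor,min_delta Training
#'   schedule (see [ordfit()]).
#' @param outer_folds,inner_folds Stratified fold counts for the outer
#'   evaluation and the nested tuning loop.
#' @param hidden Hidden-layer width of the reference model (0 = linear).
#' @param selection_metric Inner-loop model-selection metric:
#'   `"mae"` (default), `"accuracy"`, `"uoc"` or `"kendall_tau"`.
#' @param seed Master seed; folds and per-fold training derive their own
#'   seeds from it.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(loss = "co2", lambda_grid = c(0.01, 0.1, 1, 10),
                         delta = 0.05, boundary_mode = "non_overlapping",
                         tau = 1, rule = c("mode", "mean"),
                         epochs = 100L, lr = 1e-4, batch_size = 32L,
                         patience = 10L, factor = 0.9, min_delta = 1e-4,
                         outer_folds = 10L, inner_folds = 5L, hidden = 0L,
                         selection_metric = c("mae", "accuracy", "uoc",
                                              "kendall_tau"),
                         seed = 1L) {
  loss <- match.arg(loss, ordinal_loss_names())
  rule <- match.arg(rule)
  selection_metric <- match.arg(selection_metric)
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0),
            outer_folds >= 2, inner_folds >= 2, epochs >= 1,
            factor > 0, factor < 1)
  structure(list(loss = loss, lambda_grid = lambda_grid, delta = delta,
                 boundary_mode = boundary_mode, tau = tau, rule = rule,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), factor = factor,
                 min_delta = min_delta,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 hidden = as.integer(hidden),
                 selection_metric = selection_metric,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Classification head layer stack
#'
#' The dense head placed on top of any feature-extracting backbone:
#' dropout (p = 0.2), a 512-unit ReLU layer, dropout (p = 0.2), a 256-unit
#' ReLU layer, and the output layer whose width depends on the loss —
#' `K` score neurons for the softmax losses, `K - 1` threshold logits for
#' the cumulative encoding, and a single unit for the binomial (sigmoid)
#' and Poisson (rate) heads.
#'
#' @param K Number of classes.
#' @param loss_name Loss name, one of [ordinal_loss_names()].
#' @return An object of class `"head_spec"`: a list with `layers` and
#'   `output_width`.
#' @export
build_head <- function(K, loss_name) {
  loss_name <- match.arg(loss_name, ordinal_loss_names())
  stopifnot(K >= 2, K == round(K))
  ow <- output_width(loss_name, as.integer(K))
  structure(list(
    layers = list(
      list(type = "dropout", p = 0.2),
      list(type = "dense", units = 512L, activation = "relu"),
      list(type = "dropout", p = 0.2),
      list(type = "dense", units = 256L, activation = "relu"),
      list(type = "dense", units = ow,
           activation = switch(loss_name, oe = "sigmoid", bu = "sigmoid",
                               pu = "softplus", "softmax"))),
    output_width = ow, loss = loss_name, K = as.integer(K)),
    class = "head_spec")
}

#' @export
print.head_spec <- function(x, ...) {
  cat(sprintf("head for %s loss (K = %d): ", x$loss, x$K))
  cat(paste(vapply(x$layers, function(l)
    if (l$type == "dropout") sprintf("dropout(%.2g)", l$p)
    else sprintf("dense(%d, %s)", l$units, l$activation),
    character(1)), collapse = " -> "), "\n")
  invisible(x)
}

#' Stratified fold assignment
#'
#' Partitions observations into `n_folds` folds preserving the class
#' ratios: within each class the (shuffled) observations are dealt
#' cyclically across folds, so every fold's per-class count differs from
#' the proportional share by less than one observation, and
#' `n_folds = N` gives a leave-one-out partition.
#'
#' @param labels Integer class vector.
#' @param n_folds Number of folds, between 2 and `length(labels)`.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  n <- length(labels)
  stopifnot(n_folds >= 2, n_folds <= n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  ord <- perm[order(labels[perm])]   # grouped by class, shuffled within
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(n_folds), n)
  folds
}

#' Tune the penalty weight by nested cross-validation
#'
#' For each candidate in `config$lambda_grid`, runs `inner_folds`-fold
#' stratified cross-validation on the supplied training split and scores
#' the held-out predictions with the configured selection metric; returns
#' the best candidate, breaking ties toward the smallest weight.  A
#' single-element grid is returned immediately without inner
#' cross-validation.
#'
#' @param formula,data Training split (outer-fold training data).
#' @param config A [train_config()].
#' @return The chosen `lambda` (numeric scalar).
#' @export
tune_lambda <- function(formula, data, config) {
  stopifnot(inherits(config, "train_config"))
  grid <- sort(config$lambda_grid)
  if (length(grid) == 0L) stop("lambda grid is empty", call. = FALSE)
  if (length(grid) == 1L) return(grid)
  y <- as.integer(stats::model.response(stats::model.frame(formula, data)))
  K <- max(y)
  folds <- stratified_folds(y, config$inner_folds, seed = config$seed + 977L)
  score <- vapply(grid, function(lam) {
    vals <- vapply(seq_len(config$inner_folds), function(f) {
      fit <- ordfit(formula, data[folds != f, , drop = FALSE],
                    loss = config$loss, lambda = lam, delta = config$delta,
                    boundary_mode = config$boundary_mode, tau = config$tau,
                    hidden = config$hidden, epochs = config$epochs,
                    lr = config$lr, batch_size = config$batch_size,
                    patience = config$patience, factor = config$factor,
                    min_delta = config$min_delta, rule = config$rule,
                    seed = config$seed + 31L * f, K = K)
      test <- data[folds == f, , drop = FALSE]
      ps <- prediction_set(y[folds == f],
                           predict(fit, test, type = "probs"),
                           rule = config$rule)
      selection_value(ps, config$selection_metric)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  if (config$selection_metric %in% c("accuracy", "kendall_tau"))
    score <- -score                      # turn into lower-is-better
  grid[which.min(score)]                  # which.min ties to smallest lambda
}

selection_value <- function(ps, metric) {
  switch(metric, mae = mean_absolute_error(ps), accuracy = accuracy(ps),
         uoc = uoc_index(ps), kendall_tau = kendall_tau(ps))
}

#' Run the full cross-validated experiment for one configuration
#'
#' The complete protocol: stratified outer folds; on each outer training
#' split, nested tuning of `lambda` (for the penalty losses with a grid
#' of more than one value); training with the plateau schedule; and
#' evaluation of all metrics on the held-out fold with the configured
#' decoding rule.  Results are aggregated as mean and standard deviation
#' over folds.
#'
#' @param formula Model formula, e.g. `grade ~ .`.
#' @param data Full data frame.
#' @param config A [train_config()].
#' @return An object of class `"experiment_result"`: list with `folds`
#'   (per-fold metric data frame), `mean`, `sd`, `chosen_lambda`,
#'   `config`.
#' @export
run_experiment <- function(formula, data, config) {
  stopifnot(inherits(config, "train_config"))
  y <- as.integer(stats::model.response(stats::model.frame(formula, data)))
  K <- max(y)
  folds <- stratified_folds(y, config$outer_folds, seed = config$seed)
  tunable <- config$loss %in% c("co", "co2", "ho2") &&
    length(config$lambda_grid) > 1L
  per_fold <- vector("list", config$outer_folds)
  lambdas <- numeric(config$outer_folds)
  for (f in seq_len(config$outer_folds)) {
    train <- data[folds != f, , drop = FALSE]
    ytr <- y[folds != f]
    if (length(unique(ytr)) < K)
      stop("a class is absent from the training split of fold ", f,
           "; use fewer folds or more data per class", call. = FALSE)
    lam <- if (tunable) tune_lambda(formula, train, config)
           else config$lambda_grid[1L]
    lambdas[f] <- lam
    fit <- ordfit(formula, train, loss = config$loss, lambda = lam,
                  delta = config$delta,
                  boundary_mode = config$boundary_mode, tau = config$tau,
                  hidden = config$hidden, epochs = config$epochs,
                  lr = config$lr, batch_size = config$batch_size,
                  patience = config$patience, factor = config$factor,
                  min_delta = config$min_delta, rule = config$rule,
                  seed = config$seed + 1009L * f, K = K)
    test <- data[folds == f, , drop = FALSE]
    ps <- prediction_set(y[folds == f],
                         predict(fit, test, type = "probs"),
                         rule = config$rule)
    per_fold[[f]] <- metric_report(ps)
  }
  fold_df <- do.call(rbind, per_fold)
  fold_df$fold <- seq_len(config$outer_folds)
  structure(list(folds = fold_df,
                 mean = colMeans(fold_df[ordinal_metric_names()],
                                 na.rm = TRUE),
                 sd = vapply(fold_df[ordinal_metric_names()],
                             stats::sd, numeric(1), na.rm = TRUE),
                 chosen_lambda = lambdas, config = config),
            class = "experiment_result")
}

ordinal_metric_names <- function()
  c("accuracy", "mae", "uoc", "kendall_tau", "macro_auroc", "mean_gini")

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: %s loss, %d outer folds (rule: %s)\n",
              x$config$loss, x$config$outer_folds, x$config$rule))
  for (m in ordinal_metric_names())
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  if (x$config$loss %in% c("co", "co2", "ho2"))
    cat("  chosen lambda per fold:",
        paste(format(x$chosen_lambda), collapse = " "), "\n")
  invisible(x)
}

#' League table with paired-t-test similarity marks
#'
#' Given cross-validation results for several configurations on the same
#' fold layout, identifies the best configuration under `metric` and
#' marks every other configuration as statistically similar to it when
#' the two-sided paired t-test over per-fold values has `p > alpha`
#' (the bold/italic convention of results tables; `alpha = 0.1` reflects
#' the small 10-fold sample).  Identical per-fold values give `p = 1`;
#' constant nonzero differences have zero variance, an undefined t
#' statistic, and are treated as dissimilar (`p = 0`).
#'
#' @param results Named list of [run_experiment()] results.
#' @param metric One of `"accuracy"`, `"mae"`, `"uoc"`, `"kendall_tau"`,
#'   `"macro_auroc"`, `"mean_gini"`.
#' @param alpha Similarity threshold on the paired p-value.
#' @return A data frame (class `"league_table"`) with one row per
#'   configuration: mean, sd, p-value against the best, `best` and
#'   `similar` flags, and `wins` (1 for the best, plus every similar
#'   configuration when counting shared wins is desired downstream).
#' @export
compare_models <- function(results, metric = "mae", alpha = 0.1) {
  stopifnot(length(results) >= 2, !is.null(names(results)),
            all(vapply(results, inherits, logical(1), "experiment_result")))
  metric <- match.arg(metric, ordinal_metric_names())
  vals <- vapply(results, function(r) r$folds[[metric]],
                 numeric(nrow(results[[1L]]$folds)))
  lower_better <- metric %in% c("mae", "uoc")
  means <- colMeans(vals)
  best <- if (lower_better) which.min(means) else which.max(means)
  p <- vapply(seq_along(results), function(i) {
    if (i == best) return(1)
    d <- vals[, i] - vals[, best]
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    stats::t.test(vals[, i], vals[, best], paired = TRUE)$p.value
  }, numeric(1))
  out <- data.frame(model = names(results), mean = means,
                    sd = apply(vals, 2L, stats::sd), p_value = p,
                    best = seq_along(results) == best,
                    similar = p > alpha, row.names = NULL)
  out$wins <- as.integer(out$best)
  attr(out, "metric") <- metric
  attr(out, "alpha") <- alpha
  class(out) <- c("league_table", "data.frame")
  out
}

#' @export
print.league_table <- function(x, ...) {
  cat(sprintf("league table on %s (paired t-test, alpha = %.2g)\n",
              attr(x, "metric"), attr(x, "alpha")))
  mark <- ifelse(x$best, "  [best]", ifelse(x$similar, "  [similar]", ""))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %.4f +/- %.4f  p = %.3g%s\n", x$model[i],
                x$mean[i], x$sd[i], x$p_value[i], mark[i]))
  invisible(x)
}

#' Write a league table as CSV or Markdown
#'
#' @param x A [compare_models()] league table.
#' @param csv,markdown Output paths (`NULL` skips).
#' @return The table, invisibly.
#' @export
write_league_table <- function(x, csv = NULL, markdown = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(markdown)) {
    hdr <- "| model | mean | sd | p | flag |"
    sep <- "|---|---|---|---|---|"
    rows <- sprintf("| %s | %.4f | %.4f | %.3g | %s |", x$model, x$mean,
                    x$sd, x$p_value,
                    ifelse(x$best, "best", ifelse(x$similar, "similar", "")))
    writeLines(c(hdr, sep, rows), markdown)
  }
  invisible(x)
}

#' Write per-observation predictions as CSV
#'
#' One row per observation: the true label, the `K` class probabilities,
#' and the decoded class.
#'
#' @param preds A [prediction_set()].
#' @param path Output CSV path.
#' @return The file path, invisibly.
#' @export
write_predictions <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_set"))
  df <- data.frame(true_label = preds$truth, preds$probs,
                   predicted = preds$predicted)
  names(df) <- c("true_label", paste0("p", seq_len(preds$K)), "predicted")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
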