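#' Bundle predictions for evaluation
#'
#' A prediction set pairs, for `N` observations, the true ordinal labels,
#' the predicted class-probability matrix, and the decoded classes; all
#' evaluation metrics consume this container.
#'
#' @param truth Integer vector of true classes in `1..K`.
#' @param probs `N x K` matrix of predicted class probabilities (rows on
#'   the simplex).
#' @param predicted Optional integer vector of decoded classes; when
#'   omitted it is derived from `probs` with `rule`.
#' @param rule Decoding rule, `"mode"` (argmax) or `"mean"` (expectation
#'   trick); see [predict_mode()].
#' @return An object of class `"prediction_set"` with elements `truth`,
#'   `probs`, `predicted`, `K`, `n`.
#' @export
prediction_set <- function(truth, probs, predicted = NULL,
                           rule = c("mode", "mean")) {
  rule <- match.arg(rule)
  probs <- as.matrix(probs)
  K <- ncol(probs)
  truth <- as.integer(truth)
  stopifnot(K >= 2, nrow(probs) == length(truth), length(truth) >= 1,
            all(truth >= 1L & truth <= K))
  apply(probs, 1L, check_probs)
  if (is.null(predicted)) {
    decode <- if (rule == "mode") predict_mode else predict_expectation
    predicted <- apply(probs, 1L, decode)
  }
  predicted <- as.integer(predicted)
  stopifnot(length(predicted) == length(truth),
            all(predicted >= 1L & predicted <= K))
  structure(list(truth = truth, probs = probs, predicted = predicted,
                 K = K, n = length(truth)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set: %d observations, %d ordered classes\n",
              x$n, x$K))
  invisible(x)
}

#' Ordinal evaluation metrics
#'
#' Scalar metrics over a [prediction_set()]:
#' * `accuracy()`: fraction of exact class matches;
#' * `mean_absolute_error()`: mean `|k - k_hat|` in class units, the
#'   standard ordinal error that charges distant confusions more;
#' * `kendall_tau()`: Kendall's tau-b rank correlation between truth and
#'   prediction (tie-corrected, appropriate for heavily tied class data);
#' * `macro_auroc()`: one-vs-rest ROC AUC per class, macro-averaged over
#'   the classes present in the truth (errors if only one class occurs);
#' * `gini_sparsity()`: mean Gini concentration coefficient of the
#'   predicted probability vectors, 0 for uniform and `(K-1)/K` for a
#'   one-hot — a sparsity measure of how peaked the predictions are.
#'
#' @param preds A [prediction_set()].
#' @return A numeric scalar.
#' @export
accuracy <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  mean(preds$predicted == preds$truth)
}

#' @rdname accuracy
#' @export
mean_absolute_error <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  mean(abs(preds$predicted - preds$truth))
}

#' @rdname accuracy
#' @export
kendall_tau <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  if (preds$n < 2 || stats::sd(preds$truth) == 0 ||
      stats::sd(preds$predicted) == 0)
    return(NA_real_)
  stats::cor(preds$truth, preds$predicted, method = "kendall")
}

#' @rdname accuracy
#' @export
macro_auroc <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  present <- sort(unique(preds$truth))
  if (length(present) < 2L)
    stop("macro AUROC is undefined with a single class in the truth",
         call. = FALSE)
  aucs <- vapply(present, function(k) {
    resp <- as.integer(preds$truth == k)
    as.numeric(pROC::auc(resp, preds$probs[, k],
                         levels = c(0L, 1L), direction = "<", quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}

#' @rdname accuracy
#' @param probs For `gini_sparsity()`: either a single probability vector
#'   or a [prediction_set()] (mean Gini over its rows).
#' @export
gini_sparsity <- function(probs) {
  if (inherits(probs, "prediction_set"))
    return(mean(apply(probs$probs, 1L, gini_sparsity)))
  check_probs(probs)
  K <- length(probs)
  sum(abs(outer(probs, probs, "-"))) / (2 * K * sum(probs))
}

#' Uniform ordinal classification index
#'
#' A single 0-100 score combining misclassification and ordinal
#' displacement, lower is better.  The confusion matrix is first
#' row-normalised (each true class contributes equally, making the index
#' invariant to class prevalence), then every cell is charged
#' `1(wrong) + |k - k_hat| / (K - 1)` scaled to a 0-100 range:
#' 0 for a diagonal matrix, and strictly larger the farther mass sits from
#' the diagonal.  The exact index published for this purpose is defined in
#' its own literature; any drop-in replacement with the same contract can
#' be supplied through `index_fun(cm)` operating on the raw confusion
#' matrix.
#'
#' @param preds A [prediction_set()].
#' @param index_fun Optional replacement `function(cm)` mapping a `K x K`
#'   confusion matrix (rows = truth) to a scalar.
#' @return Scalar in `[0, 100]`.
#' @export
uoc_index <- function(preds, index_fun = NULL) {
  stopifnot(inherits(preds, "prediction_set"))
  cm <- confusion_matrix(preds)
  if (!is.null(index_fun)) return(index_fun(cm))
  K <- nrow(cm)
  rows <- which(rowSums(cm) > 0)
  Q <- cm[rows, , drop = FALSE] / rowSums(cm)[rows]
  d <- abs(outer(rows, seq_len(K), "-"))
  cost <- (d > 0) + d / (K - 1)           # per-cell charge in [0, 2]
  100 * sum(Q * cost) / (2 * length(rows))
}

#' Confusion matrix of a prediction set
#'
#' @param preds A [prediction_set()].
#' @return Integer `K x K` matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  K <- preds$K
  cm <- table(factor(preds$truth, levels = seq_len(K)),
              factor(preds$predicted, levels = seq_len(K)))
  m <- matrix(as.integer(cm), K, K,
              dimnames = list(truth = seq_len(K), predicted = seq_len(K)))
  m
}

#' Full metric report
#'
#' Computes all evaluation metrics at once.
#'
#' @param preds A [prediction_set()].
#' @return A one-row `data.frame` with columns `accuracy`, `mae`, `uoc`,
#'   `kendall_tau`, `macro_auroc`, `mean_gini`.
#' @export
metric_report <- function(preds) {
  data.frame(accuracy = accuracy(preds),
             mae = mean_absolute_error(preds),
             uoc = uoc_index(preds),
             kendall_tau = kendall_tau(preds),
             macro_auroc = tryCatch(macro_auroc(preds),
                                    error = function(e) NA_real_),
             mean_gini = gini_sparsity(preds))
}

#' Write a metric report or confusion matrix to disk
#'
#' `write_metric_report()` writes the one-row report as CSV and, when
#' `json` is given, as a flat JSON object; `write_confusion_matrix()`
#' writes the `K x K` table as CSV.
#'
#' @param report A [metric_report()] data frame.
#' @param preds A [prediction_set()].
#' @param csv,json Output paths (`json = NULL` skips JSON).
#' @return The input, invisibly.
#' @export
write_metric_report <- function(report, csv, json = NULL) {
  utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json)) {
    vals <- vapply(report, function(v) sprintf("%.10g", v), character(1))
    writeLines(paste0("{", paste(sprintf('"%s": %s', names(report), vals),
                                 collapse = ", "), "}"), json)
  }
  invisible(report)
}

#' @rdname write_metric_report
#' @export
write_confusion_matrix <- function(preds, csv) {
  utils::write.csv(confusion_matrix(preds), csv)
  invisible(preds)
}
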