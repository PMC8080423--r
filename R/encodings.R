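#' Ordinal label encodings
#'
#' Ordered classes `1..K` admit two standard vector representations: the
#' one-hot vector used by cross-entropy training, and the cumulative
#' (ordinal) code of `K - 1` binary threshold indicators, where bit `m`
#' says "the true class exceeds class m".  These helpers map between the
#' integer class index, the two encodings, and back from (possibly noisy)
#' model outputs.
#'
#' @param k_star Integer true class index, 1-based, in `1..K`.
#' @param K Integer number of ordered classes, at least 2.
#'
#' @return `encode_one_hot()` returns a length-`K` 0/1 vector with a single
#'   1 at position `k_star`; `encode_cumulative()` returns a length-`K-1`
#'   0/1 vector whose entry `m` is 1 iff `m < k_star`.
#'
#' @examples
#' encode_one_hot(3, 4)      # 0 0 1 0
#' encode_cumulative(3, 4)   # 1 1 0
#' decode_cumulative(c(0.9, 0.8, 0.2))  # 3
#' @export
encode_one_hot <- function(k_star, K) {
  check_label(k_star, K)
  v <- numeric(K)
  v[k_star] <- 1
  v
}

#' @rdname encode_one_hot
#' @export
encode_cumulative <- function(k_star, K) {
  check_label(k_star, K)
  as.numeric(seq_len(K - 1) < k_star)
}

#' Decode cumulative model outputs to a class index
#'
#' Inverts the cumulative encoding by counting outputs above `threshold`:
#' the predicted class is `1 + sum(outputs > threshold)`.  Counting (rather
#' than scanning for the first sub-threshold output) makes the rule well
#' defined for non-monotone raw outputs.
#'
#' @param outputs Numeric vector of length `K - 1`, entries in `[0, 1]`
#'   (typically per-threshold sigmoid outputs).
#' @param threshold Decision threshold, default 0.5.
#' @return Integer class index in `1..K`.
#' @export
decode_cumulative <- function(outputs, threshold = 0.5) {
  check_unit_interval(outputs)
  1L + sum(outputs > threshold)
}

#' Convert cumulative outputs to a full class-probability vector
#'
#' Raw threshold outputs need not be monotone, so they are first projected
#' onto monotone non-increasing codes by a running minimum
#' (`c'_m = min(c_1, ..., c_m)`; idempotent, exact on valid codes) and then
#' differenced: `p_1 = 1 - c'_1`, `p_k = c'_{k-1} - c'_k`,
#' `p_K = c'_{K-1}`.  The result is a valid probability vector, so models
#' trained on the cumulative encoding can be scored with the same
#' probability-based metrics (AUROC, Gini sparsity) as softmax models.
#'
#' @inheritParams decode_cumulative
#' @return Numeric probability vector of length `K = length(outputs) + 1`.
#' @examples
#' cumulative_to_probabilities(c(0.8, 0.3, 0.1))  # 0.2 0.5 0.2 0.1
#' @export
cumulative_to_probabilities <- function(outputs) {
  check_unit_interval(outputs)
  cm <- cummin(outputs)
  K <- length(outputs) + 1L
  c(1 - cm[1L], if (K > 2L) -diff(cm), cm[K - 1L])
}

# -- validation helpers -------------------------------------------------

check_label <- function(k_star, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("K must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(k_star) || length(k_star) != 1L || k_star != round(k_star) ||
      k_star < 1 || k_star > K)
    stop("k_star must be an integer in 1..K", call. = FALSE)
  invisible(TRUE)
}

check_unit_interval <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1))
    stop("outputs must be numeric values in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

check_probs <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 2L || anyNA(p))
    stop("probs must be a numeric vector of length >= 2", call. = FALSE)
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  invisible(TRUE)
}
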