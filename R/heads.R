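#' Parametric unimodal output heads
#'
#' Both heads turn a single scalar network output into a full class
#' distribution that is unimodal by construction.
#'
#' `binomial_probabilities()` maps a sigmoid output `q` to the binomial
#' PMF with `K - 1` trials: `p_k = choose(K-1, k-1) q^(k-1) (1-q)^(K-k)`,
#' so `q = 0` concentrates on class 1 and `q = 1` on class `K`.
#'
#' `poisson_probabilities()` evaluates the log Poisson PMF at the first
#' `K` support points, `s_k = (k-1) log(rate) - rate - log((k-1)!)`, and
#' normalises with a temperature softmax `softmax(s / tau)`.  The log-PMF
#' is concave in `k`, and the softmax is monotone, so the result is
#' unimodal for any rate and temperature.
#'
#' @param q Success probability in `[0, 1]`.
#' @param rate Positive Poisson rate.
#' @param K Number of classes, at least 2.
#' @param tau Positive softmax temperature (1 reproduces the plain
#'   softmax; large values flatten the distribution).
#' @return Numeric probability vector of length `K`.
#' @examples
#' binomial_probabilities(0.5, 3)   # 0.25 0.50 0.25
#' poisson_probabilities(1, 3)      # 0.4 0.4 0.2
#' @export
binomial_probabilities <- function(q, K) {
  stopifnot(K >= 2, K == round(K))
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a probability in [0, 1]", call. = FALSE)
  stats::dbinom(0:(K - 1L), size = K - 1L, prob = q)
}

#' @rdname binomial_probabilities
#' @export
poisson_probabilities <- function(rate, K, tau = 1) {
  stopifnot(K >= 2, K == round(K), is.numeric(tau), tau > 0)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("rate must be a positive real", call. = FALSE)
  k <- 0:(K - 1L)
  s <- k * log(rate) - rate - lgamma(k + 1)
  softmax(s / tau)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Turn a class distribution into a predicted class
#'
#' `predict_mode()` is the argmax rule, with ties broken toward the lowest
#' class index.  `predict_expectation()` is the "expectation trick": the
#' probability-weighted mean class index `sum(k * p_k)`, rounded half-up
#' and clamped to `1..K`.  The two rules can disagree on skewed or
#' multimodal distributions.
#'
#' @param probs Class-probability vector of length `K`.
#' @return Integer class index in `1..K`.
#' @examples
#' predict_mode(c(0.45, 0.1, 0.45))         # 1 (tie to lowest)
#' predict_expectation(c(0.45, 0.1, 0.45))  # 2 (mean is 2.0)
#' @export
predict_mode <- function(probs) {
  check_probs(probs)
  which.max(probs)  # which.max already takes the first (lowest) maximum
}

#' @rdname predict_mode
#' @export
predict_expectation <- function(probs) {
  check_probs(probs)
  K <- length(probs)
  ev <- sum(seq_len(K) * probs)
  as.integer(min(max(floor(ev + 0.5), 1L), K))
}
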