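#' Loss configuration
#'
#' Bundles the hyperparameters shared by the ordinal losses: the penalty
#' weight `lambda`, the consecutive-probability margin `delta`, and the
#' boundary convention of the penalty sums.
#'
#' The printed form of the CO/CO2/HO2 penalties runs the "left" sum over
#' `k <= k*` and the "right" sum over `k >= k*`, so the pair at `k = k*`
#' appears in both sums and even a perfect prediction is charged at least
#' `2 * delta` at the peak when `k* < K`.  With
#' `boundary_mode = "non_overlapping"` (the default) the left sum runs over
#' `k < k*` only, which makes the zero set of the penalty exactly the
#' delta-strict unimodal distributions peaked at the true class.
#' `"as_printed"` keeps the literal overlapping form; both conventions are
#' supported everywhere a penalty is computed.
#'
#' @param lambda Non-negative penalty weight (relative importance of the
#'   unimodality terms against the base term).
#' @param delta Margin in `[0, 1)` required between consecutive class
#'   probabilities; 0.05 is the empirically suggested default.
#' @param boundary_mode `"non_overlapping"` or `"as_printed"`; see Details.
#' @param tau Positive softmax temperature used by the Poisson head.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(lambda = 1, delta = 0.05,
                        boundary_mode = c("non_overlapping", "as_printed"),
                        tau = 1) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            is.numeric(delta), length(delta) == 1L, delta >= 0, delta < 1,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(lambda = lambda, delta = delta,
                 boundary_mode = boundary_mode, tau = tau),
            class = "loss_config")
}

# Probabilities are clamped before any log so that degenerate model outputs
# give large finite losses, never Inf/NaN.
.log_eps <- 1e-12

loss_value <- function(base_term, penalty_term, lambda) {
  structure(list(total = base_term + lambda * penalty_term,
                 base_term = base_term,
                 penalty_term = penalty_term,
                 lambda = lambda),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("loss: total %.6g = base %.6g + lambda %.4g * penalty %.6g\n",
              x$total, x$base_term, x$lambda, x$penalty_term))
  invisible(x)
}

#' Cross-entropy of a single prediction
#'
#' `-log(p[k_star])` with natural logarithm; the probability at the true
#' class is clamped below at `1e-12` so the loss stays finite.
#'
#' @param k_star True class index in `1..K`.
#' @param probs Predicted class-probability vector of length `K`.
#' @return A `"loss_value"` with zero penalty term.
#' @examples
#' cross_entropy(3, c(0.1, 0.2, 0.6, 0.1))$total  # -log(0.6)
#' @export
cross_entropy <- function(k_star, probs) {
  check_probs(probs)
  check_label(k_star, length(probs))
  loss_value(-log(max(probs[k_star], .log_eps)), 0, 0)
}

#' Unimodality margin penalty over consecutive class probabilities
#'
#' Sums hinge ("ReLU") terms over adjacent class pairs: left of the true
#' class the probabilities must rise by at least `delta` per step, right of
#' it they must fall by at least `delta`.  With `delta = 0` this is the CO
#' penalty; with a positive margin it is the CO2/HO2 penalty.  The
#' `boundary_mode` of `config` selects whether the pair at `k = k*` is
#' charged from both sides (see [loss_config()]).
#'
#' @inheritParams cross_entropy
#' @param config A [loss_config()]; only `delta` and `boundary_mode` are
#'   used (the weight `lambda` is applied by the callers).
#' @return Non-negative numeric scalar.
#' @examples
#' unimodal_penalty(1, c(0.4, 0.1, 0.5), loss_config(delta = 0))     # 0.4
#' unimodal_penalty(2, c(0.2, 0.5, 0.3), loss_config(delta = 0))     # 0
#' @export
unimodal_penalty <- function(k_star, probs, config = loss_config()) {
  check_probs(probs)
  K <- length(probs)
  check_label(k_star, K)
  stopifnot(inherits(config, "loss_config"))
  d <- config$delta
  k <- seq_len(K - 1L)
  step <- probs[k + 1L] - probs[k]           # p_{k+1} - p_k
  left_max <- if (config$boundary_mode == "non_overlapping") k_star - 1L
              else k_star
  left  <- k <= left_max                      # rising side: want step >= delta
  right <- k >= k_star                        # falling side: want -step >= delta
  sum(pmax(0, d - step)[left]) + sum(pmax(0, d + step)[right])
}

#' Ordinal losses CO, CO2 and HO2
#'
#' The three unimodality-promoting losses for ordinal classes:
#' * `co_loss()`: cross-entropy plus `lambda` times the consecutive-pair
#'   penalty with zero margin (flat distributions are not charged);
#' * `co2_loss()`: the same with margin `delta`, requiring consecutive
#'   probabilities to differ by at least `delta`;
#' * `ho2_loss()`: the margin penalty added to the entropy
#'   `H(p) = -sum(p * log p)` of the prediction instead of cross-entropy,
#'   so the true class enters only through the penalty and near-flat
#'   distributions are discouraged without forcing a one-hot target.
#'
#' @inheritParams cross_entropy
#' @param config A [loss_config()] providing `lambda`, `delta` and the
#'   boundary convention.  `co_loss()` forces `delta = 0`.
#' @return A `"loss_value"` with fields `total`, `base_term` and
#'   `penalty_term` (`total = base_term + lambda * penalty_term`).
#' @examples
#' co_loss(1, c(0.4, 0.1, 0.5), loss_config(lambda = 1))$total   # 1.3163
#' co2_loss(1, c(0.4, 0.1, 0.5), loss_config(lambda = 1))$total  # 1.3663
#' @export
co_loss <- function(k_star, probs, config = loss_config()) {
  config$delta <- 0
  ce <- cross_entropy(k_star, probs)
  loss_value(ce$base_term, unimodal_penalty(k_star, probs, config),
             config$lambda)
}

#' @rdname co_loss
#' @export
co2_loss <- function(k_star, probs, config = loss_config()) {
  ce <- cross_entropy(k_star, probs)
  loss_value(ce$base_term, unimodal_penalty(k_star, probs, config),
             config$lambda)
}

#' @rdname co_loss
#' @export
ho2_loss <- function(k_star, probs, config = loss_config()) {
  check_probs(probs)
  check_label(k_star, length(probs))
  loss_value(entropy_nats(probs), unimodal_penalty(k_star, probs, config),
             config$lambda)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Ordinal-encoding loss
#'
#' Mean binary cross-entropy of the `K - 1` threshold outputs against the
#' cumulative encoding of the true class.  Each output makes the binary
#' decision "class exceeds threshold m".
#'
#' @param k_star True class index in `1..K`.
#' @param raw_outputs Length-`K-1` vector of per-threshold probabilities in
#'   `[0, 1]` (sigmoid outputs).
#' @return A `"loss_value"` with zero penalty term.
#' @examples
#' oe_loss(2, c(0.5, 0.5))$total  # log(2)
#' @export
oe_loss <- function(k_star, raw_outputs) {
  check_unit_interval(raw_outputs)
  K <- length(raw_outputs) + 1L
  check_label(k_star, K)
  t <- encode_cumulative(k_star, K)
  p <- pmin(pmax(raw_outputs, .log_eps), 1 - .log_eps)
  loss_value(-mean(t * log(p) + (1 - t) * log(1 - p)), 0, 0)
}

#' Binomial- and Poisson-unimodal losses
#'
#' Negative log of the probability that the parametric unimodal head
#' assigns to the true class: `bu_loss()` evaluates the binomial head
#' ([binomial_probabilities()]) at its scalar success probability `q`,
#' `pu_loss()` the temperature-softmax Poisson head
#' ([poisson_probabilities()]) at its rate.  Because the heads are unimodal
#' by construction, these are the "parametric" baselines the margin
#' penalties are contrasted with.
#'
#' @inheritParams cross_entropy
#' @param q Binomial head success probability in `[0, 1]`.
#' @param rate Positive Poisson rate.
#' @param K Number of classes.
#' @param config A [loss_config()]; only the temperature `tau` is used.
#' @return A `"loss_value"` with zero penalty term.
#' @examples
#' bu_loss(2, q = 0.5, K = 3)$total    # -log(0.5)
#' pu_loss(1, rate = 1, K = 3)$total   # -log(0.4)
#' @export
bu_loss <- function(k_star, q, K) {
  p <- binomial_probabilities(q, K)
  loss_value(-log(max(p[k_star], .log_eps)), 0, 0)
}

#' @rdname bu_loss
#' @export
pu_loss <- function(k_star, rate, K, config = loss_config()) {
  p <- poisson_probabilities(rate, K, tau = config$tau)
  loss_value(-log(max(p[k_star], .log_eps)), 0, 0)
}

#' Evaluate a loss by name
#'
#' Dispatch table used by the training harness: the softmax losses
#' (`"ce"`, `"co"`, `"co2"`, `"ho2"`) take a probability vector, `"oe"`
#' takes `K - 1` threshold outputs, `"bu"` and `"pu"` take the scalar head
#' parameter.
#'
#' @param name One of `"ce"`, `"oe"`, `"bu"`, `"pu"`, `"co"`, `"co2"`,
#'   `"ho2"`.
#' @param k_star True class index.
#' @param output Loss-specific model output (see Details).
#' @param K Number of classes (needed for `"bu"`/`"pu"`).
#' @param config A [loss_config()].
#' @return A `"loss_value"`.
#' @export
evaluate_loss <- function(name, k_star, output, K = length(output),
                          config = loss_config()) {
  switch(match.arg(name, ordinal_loss_names()),
         ce  = cross_entropy(k_star, output),
         co  = co_loss(k_star, output, config),
         co2 = co2_loss(k_star, output, config),
         ho2 = ho2_loss(k_star, output, config),
         oe  = oe_loss(k_star, output),
         bu  = bu_loss(k_star, output, K),
         pu  = pu_loss(k_star, output, K, config))
}

#' @rdname evaluate_loss
#' @export
ordinal_loss_names <- function() c("ce", "oe", "bu", "pu", "co", "co2", "ho2")
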