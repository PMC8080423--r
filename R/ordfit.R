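#' Fit an ordinal classifier under a chosen loss
#'
#' Trains the reference score network (linear by default, optionally one
#' hidden ReLU layer) on a labelled feature table under any of the seven
#' supported losses: plain cross-entropy (`"ce"`), the cumulative ordinal
#' encoding (`"oe"`), the binomial and Poisson unimodal heads (`"bu"`,
#' `"pu"`), and the unimodality-penalty losses (`"co"`, `"co2"`, `"ho2"`).
#' Optimisation is Adam over mini-batches with a reduce-on-plateau
#' learning-rate schedule: the rate is multiplied by `factor` whenever the
#' epoch-mean training loss has not improved by more than `min_delta` for
#' `patience` consecutive epochs.
#'
#' The response may be an integer vector in `1..K`, or a factor/ordered
#' factor whose level order defines the class order.  Features are
#' standardised internally (training means and standard deviations are
#' stored and reapplied by `predict()`).
#'
#' @param formula Model formula, e.g. `grade ~ .`.
#' @param data Data frame holding the response and features.
#' @param loss Loss name, one of [ordinal_loss_names()].
#' @param lambda,delta,boundary_mode Penalty weight, margin and boundary
#'   convention for the `"co"`/`"co2"`/`"ho2"` losses; see [loss_config()].
#' @param tau Softmax temperature of the Poisson head.
#' @param hidden Width of the optional hidden ReLU layer (0 = linear).
#' @param epochs,lr,batch_size,patience,factor,min_delta Training
#'   schedule; defaults follow the protocol of 100 epochs starting at
#'   learning rate `1e-4` with a 10% reduction after 10 stagnant epochs.
#'   Small desk-scale feature problems usually want a larger `lr`.
#' @param rule Default decoding rule for predictions: `"mode"` (argmax) or
#'   `"mean"` (expectation trick).
#' @param seed Integer seed making initialisation and batch order
#'   reproducible; `NULL` leaves the RNG state alone.
#' @param K Number of classes; inferred from the response when omitted
#'   (required if the training data may miss the extreme classes).
#'
#' @return An object of class `"ordfit"` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()` and
#'   `simulate()` methods.
#'
#' @examples
#' d <- sample_ordinal_features(ordinal_dataset_spec(
#'   K = 3, n_per_class = 30, feature_dim = 2, class_separation = 3,
#'   seed = 1))
#' fit <- ordfit(grade ~ ., d, loss = "co2", lambda = 1,
#'               epochs = 30, lr = 0.1, seed = 1)
#' table(truth = d$grade, pred = predict(fit, d))
#' @export
ordfit <- function(formula, data, loss = "co2",
                   lambda = 1, delta = 0.05,
                   boundary_mode = "non_overlapping", tau = 1,
                   hidden = 0L, epochs = 100L, lr = 1e-4,
                   batch_size = 32L, patience = 10L, factor = 0.9,
                   min_delta = 1e-4, rule = c("mode", "mean"),
                   seed = NULL, K = NULL) {
  loss <- match.arg(loss, ordinal_loss_names())
  rule <- match.arg(rule)
  stopifnot(epochs >= 1, factor > 0, factor < 1, batch_size >= 1)
  config <- loss_config(lambda = lambda, delta = delta,
                        boundary_mode = boundary_mode, tau = tau)
  mf <- stats::model.frame(formula, data)
  terms <- attr(mf, "terms")
  yraw <- stats::model.response(mf)
  lv <- NULL
  if (is.factor(yraw)) {
    lv <- levels(yraw)
    y <- as.integer(yraw)
  } else {
    y <- as.integer(yraw)
    if (any(y < 1L)) stop("integer responses must be 1-based class indices")
  }
  if (is.null(K)) K <- if (!is.null(lv)) length(lv) else max(y)
  stopifnot(K >= 2, all(y >= 1L & y <= K))
  X <- stats::model.matrix(terms, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  net <- train_scores_net(Xs, y, K, loss, config, hidden = hidden,
                          epochs = epochs, lr = lr,
                          batch_size = batch_size, patience = patience,
                          factor = factor, min_delta = min_delta,
                          seed = seed)
  fit <- structure(list(par = net$par, hidden = net$hidden, loss = loss,
                        config = config, K = K, levels = lv,
                        terms = stats::delete.response(terms),
                        center = ctr, scale = scl, rule = rule,
                        trace = net$trace, final_loss = net$final_loss,
                        y = y, n = length(y), seed = seed,
                        call = match.call()),
                   class = "ordfit")
  fit$fitted_probs <- predict(fit, data, type = "probs")
  fit
}

ordfit_scores <- function(object, newdata) {
  X <- stats::model.matrix(object$terms,
                           stats::model.frame(object$terms, newdata))
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  Xs <- scale(X, center = object$center, scale = object$scale)
  net_forward(Xs, object$par, object$hidden)$Z
}

#' Predict from an ordinal classifier
#'
#' @param object An [ordfit()] model.
#' @param newdata Data frame of features; the training data must be
#'   passed explicitly to reproduce fitted values.
#' @param type `"class"` for decoded class indices, `"probs"` for the
#'   `N x K` class-probability matrix, `"link"` for the raw output scores
#'   of the head (logits, threshold logits, or the scalar head output).
#' @param rule Decoding rule overriding the one stored in the model.
#' @param ... Unused.
#' @return Integer classes, a probability matrix, or a score matrix.
#' @export
predict.ordfit <- function(object, newdata,
                           type = c("class", "probs", "link"),
                           rule = NULL, ...) {
  type <- match.arg(type)
  Z <- ordfit_scores(object, newdata)
  if (type == "link") return(Z)
  P <- scores_to_probs(Z, object$loss, object$K, object$config)
  if (type == "probs") return(P)
  rule <- if (is.null(rule)) object$rule else match.arg(rule, c("mode", "mean"))
  decode <- if (rule == "mode") predict_mode else predict_expectation
  apply(P, 1L, decode)
}

#' @export
print.ordfit <- function(x, ...) {
  cat(sprintf("ordinal classifier (%s loss), K = %d classes, n = %d\n",
              x$loss, x$K, x$n))
  if (x$loss %in% c("co", "co2", "ho2"))
    cat(sprintf("  lambda = %.4g, delta = %.4g (%s pairs)\n",
                x$config$lambda,
                if (x$loss == "co") 0 else x$config$delta,
                x$config$boundary_mode))
  cat(sprintf("  backbone: %s, final training loss %.5g\n",
              if (x$hidden > 0) sprintf("MLP (%d hidden units)", x$hidden)
              else "linear", x$final_loss))
  invisible(x)
}

#' @export
summary.ordfit <- function(object, ...) {
  ps <- prediction_set(object$y, object$fitted_probs, rule = object$rule)
  out <- list(fit = object, train_metrics = metric_report(ps),
              confusion = confusion_matrix(ps))
  class(out) <- "summary.ordfit"
  out
}

#' @export
print.summary.ordfit <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set metrics:\n")
  print(x$train_metrics, row.names = FALSE)
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
coef.ordfit <- function(object, ...) object$par

#' @export
fitted.ordfit <- function(object, ...) {
  decode <- if (object$rule == "mode") predict_mode else predict_expectation
  apply(object$fitted_probs, 1L, decode)
}

#' Signed class-unit residuals
#'
#' `predicted - true` class index for each training observation, so the
#' mean absolute residual is the training MAE and the sign shows the
#' direction of the grading error.
#' @param object An [ordfit()] model.
#' @param ... Unused.
#' @export
residuals.ordfit <- function(object, ...) {
  fitted(object) - object$y
}

#' @export
plot.ordfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$epoch, x$trace$loss, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = sprintf("%s loss", x$loss), ...)
  graphics::plot(x$trace$epoch, x$trace$lr, type = "s",
                 xlab = "epoch", ylab = "learning rate",
                 main = "plateau schedule", ...)
  invisible(x)
}

#' Simulate class labels from predicted distributions
#'
#' Draws labels from the per-observation predicted class probabilities,
#' one column per simulation.
#'
#' @param object An [ordfit()] model.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param newdata Feature data frame (defaults to refusing silently-stale
#'   fitted values only when provided).
#' @param ... Unused.
#' @return Integer matrix `nrow(newdata) x nsim`.
#' @export
simulate.ordfit <- function(object, nsim = 1, seed = NULL,
                            newdata = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  P <- if (is.null(newdata)) object$fitted_probs
       else predict(object, newdata, type = "probs")
  out <- replicate(nsim, apply(P, 1L, function(p)
    sample.int(object$K, 1L, prob = p)))
  matrix(as.integer(out), nrow = nrow(P), ncol = nsim)
}
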