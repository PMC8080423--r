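# Reference gradient-trained model: a linear (or one-hidden-layer) score
# network whose output layer is sized by the loss -- K scores for the
# softmax losses, K-1 threshold logits for the cumulative encoding, one
# scalar for the binomial / Poisson heads.  Gradients are analytic; the
# optimizer is Adam with a reduce-on-plateau learning-rate schedule.

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

output_width <- function(loss, K) {
  switch(loss, ce = K, co = K, co2 = K, ho2 = K,
         oe = K - 1L, bu = 1L, pu = 1L,
         stop("unknown loss: ", loss))
}

# Masks and hinge terms of the consecutive-pair penalty for a batch.
# D[i, k] = p_k - p_{k+1}; left (rising) pairs charge ReLU(delta + D),
# right (falling) pairs charge ReLU(delta - D).
penalty_batch <- function(P, y, delta, boundary_mode) {
  n <- nrow(P); K <- ncol(P)
  D <- P[, -K, drop = FALSE] - P[, -1L, drop = FALSE]
  k <- matrix(seq_len(K - 1L), n, K - 1L, byrow = TRUE)
  left_max <- if (boundary_mode == "non_overlapping") y - 1L else y
  Lm <- k <= left_max                       # recycles y down columns
  Rm <- k >= y
  TL <- pmax(0, delta + D) * Lm
  TR <- pmax(0, delta - D) * Rm
  AL <- (delta + D > 0) * Lm                # active left hinges
  AR <- (delta - D > 0) * Rm
  G <- matrix(0, n, K)
  G[, -K] <- AL - AR
  G[, -1L] <- G[, -1L, drop = FALSE] - AL + AR
  list(value = rowSums(TL) + rowSums(TR), grad_p = G)
}

# Mean loss over the batch and its gradient with respect to the raw
# output scores Z.  `y` is the integer class vector.
batch_loss_grad <- function(Z, y, loss, K, config) {
  n <- length(y)
  eps <- .log_eps
  if (loss %in% c("ce", "co", "co2", "ho2")) {
    P <- row_softmax(Z)
    Pc <- pmax(P, eps)
    delta <- if (loss == "co") 0 else config$delta
    lambda <- if (loss == "ce") 0 else config$lambda
    if (loss == "ho2") {
      base <- -rowSums(P * log(Pc))
      gb <- -(log(Pc) + 1)                  # dH/dp
    } else {
      base <- -log(Pc[cbind(seq_len(n), y)])
      gb <- NULL                            # handled via softmax shortcut
    }
    pen <- if (lambda > 0)
      penalty_batch(P, y, delta, config$boundary_mode)
    else list(value = numeric(n), grad_p = NULL)
    g <- if (lambda > 0) lambda * pen$grad_p else NULL
    if (!is.null(gb)) g <- if (is.null(g)) gb else g + gb
    dZ <- matrix(0, n, K)
    if (!is.null(g))
      dZ <- P * (g - rowSums(P * g))        # through-softmax Jacobian
    if (loss != "ho2") {                    # CE part: p - onehot
      dZ <- dZ + P
      dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
    }
    list(loss = mean(base + lambda * pen$value), dZ = dZ / n)
  } else if (loss == "oe") {
    Tm <- outer(y, seq_len(K - 1L), function(a, b) as.numeric(b < a))
    C <- sigmoid(Z)
    Cc <- pmin(pmax(C, eps), 1 - eps)
    l <- -rowMeans(Tm * log(Cc) + (1 - Tm) * log(1 - Cc))
    list(loss = mean(l), dZ = (C - Tm) / ((K - 1L) * n))
  } else if (loss == "bu") {
    q <- sigmoid(drop(Z))
    qc <- pmin(pmax(q, 1e-9), 1 - 1e-9)
    l <- -stats::dbinom(y - 1L, size = K - 1L, prob = qc, log = TRUE)
    dz <- ((K - 1L) * q - (y - 1L)) / n
    list(loss = mean(l), dZ = matrix(dz, ncol = 1L))
  } else if (loss == "pu") {
    z <- drop(Z)
    r <- softplus(z) + 1e-6
    kk <- 0:(K - 1L)
    S <- outer(r, kk, function(ri, ki) ki * log(ri) - ri - lgamma(ki + 1))
    P <- row_softmax(S / config$tau)
    l <- -log(pmax(P[cbind(seq_along(y), y)], eps))
    Ek <- drop(P %*% kk)
    dr <- (Ek - (y - 1L)) / (config$tau * r)
    dz <- dr * sigmoid(z) / n
    list(loss = mean(l), dZ = matrix(dz, ncol = 1L))
  } else stop("unknown loss: ", loss)
}

# Class-probability matrix implied by raw scores under each loss family.
scores_to_probs <- function(Z, loss, K, config) {
  switch(loss,
    ce = , co = , co2 = , ho2 = row_softmax(Z),
    oe = t(apply(sigmoid(Z), 1L, cumulative_to_probabilities)),
    bu = t(vapply(sigmoid(drop(Z)), binomial_probabilities,
                  numeric(K), K = K)),
    pu = t(vapply(softplus(drop(Z)) + 1e-6, poisson_probabilities,
                  numeric(K), K = K, tau = config$tau)))
}

adam_new <- function(par) list(m = lapply(par, function(p) p * 0),
                               v = lapply(par, function(p) p * 0), t = 0)

adam_step <- function(par, grad, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(par)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grad[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

net_forward <- function(X, par, hidden) {
  if (hidden > 0L) {
    H <- pmax(X %*% par$W1 + rep(par$b1, each = nrow(X)), 0)
    list(Z = H %*% par$W2 + rep(par$b2, each = nrow(X)), H = H)
  } else {
    list(Z = X %*% par$W + rep(par$b, each = nrow(X)), H = NULL)
  }
}

net_backward <- function(X, fwd, dZ, par, hidden) {
  if (hidden > 0L) {
    dW2 <- t(fwd$H) %*% dZ
    db2 <- colSums(dZ)
    dH <- (dZ %*% t(par$W2)) * (fwd$H > 0)
    list(W1 = t(X) %*% dH, b1 = colSums(dH), W2 = dW2, b2 = db2)
  } else {
    list(W = t(X) %*% dZ, b = colSums(dZ))
  }
}

# Runs the full schedule; X is the already standardised design matrix.
train_scores_net <- function(X, y, K, loss, config, hidden = 0L,
                             epochs = 100L, lr = 1e-4, batch_size = 32L,
                             patience = 10L, factor = 0.9,
                             min_delta = 1e-4, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(X); d <- ncol(X)
  ow <- output_width(loss, K)
  par <- if (hidden > 0L)
    list(W1 = matrix(stats::rnorm(d * hidden, sd = 0.1), d, hidden),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * ow, sd = 0.1), hidden, ow),
         b2 = numeric(ow))
  else
    list(W = matrix(stats::rnorm(d * ow, sd = 0.1), d, ow), b = numeric(ow))
  state <- adam_new(par)
  best <- Inf; wait <- 0L
  trace <- data.frame(epoch = seq_len(epochs), loss = NA_real_, lr = NA_real_)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1L, n)]
      Xb <- X[b, , drop = FALSE]
      fwd <- net_forward(Xb, par, hidden)
      lg <- batch_loss_grad(fwd$Z, y[b], loss, K, config)
      grad <- net_backward(Xb, fwd, lg$dZ, par, hidden)
      upd <- adam_step(par, grad, state, lr)
      par <- upd$par; state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / n
    trace$loss[ep] <- ep_loss; trace$lr[ep] <- lr
    if (best - ep_loss > min_delta) {
      best <- ep_loss; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { lr <- lr * factor; wait <- 0L }
    }
  }
  list(par = par, hidden = hidden, trace = trace, final_loss = best)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
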