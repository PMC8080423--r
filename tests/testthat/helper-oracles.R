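# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (pairwise loops, direct enumeration) so they cannot
# share a bug with the vectorised implementations they check.

random_simplex <- function(K) {
  e <- -log(runif(K))
  e / sum(e)
}

# Strict unimodality check by direct pairwise inspection: rising by at
# least delta before the peak, falling by at least delta after it.
delta_unimodal_at <- function(p, k_star, delta) {
  K <- length(p)
  ok <- TRUE
  for (k in seq_len(K - 1)) {
    if (k < k_star) ok <- ok && (p[k + 1] - p[k] >= delta)
    if (k >= k_star) ok <- ok && (p[k] - p[k + 1] >= delta)
  }
  ok
}

# Penalty by direct summation of every hinge term (non-overlapping mode).
brute_penalty <- function(p, k_star, delta) {
  K <- length(p)
  tot <- 0
  for (k in seq_len(K - 1)) {
    if (k < k_star) tot <- tot + max(0, delta + p[k] - p[k + 1])
    if (k >= k_star) tot <- tot + max(0, delta + p[k + 1] - p[k])
  }
  tot
}

# Unimodal in the weak sense: no strict local minimum between two strict
# local maxima (plateaus allowed).  Collapse plateau runs, then the run
# signs must be non-increasing (+ runs before - runs).
weakly_unimodal <- function(p, tol = 1e-12) {
  s <- sign(diff(p))
  s <- s[abs(diff(p)) > tol]
  if (length(s) == 0) return(TRUE)
  s <- s[c(TRUE, diff(s) != 0)]
  all(diff(s) <= 0) && sum(s == 1) <= 1 && sum(s == -1) <= 1
}

# Kendall tau-b by explicit pair counting.
brute_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  tie_x <- sum(sapply(split(seq_along(x), x), function(g) choose(length(g), 2)))
  tie_y <- sum(sapply(split(seq_along(y), y), function(g) choose(length(g), 2)))
  (nc - nd) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# One-vs-rest AUC by the Mann-Whitney statistic with midrank ties.
brute_auc <- function(positive, score) {
  pos <- score[positive]
  neg <- score[!positive]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# Two-sided paired t-test p-value from the textbook formula.
brute_paired_t_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  2 * stats::pt(-abs(t), df = n - 1)
}

small_prediction_set <- function(n, K, seed) {
  set.seed(seed)
  probs <- t(replicate(n, random_simplex(K)))
  truth <- sample.int(K, n, replace = TRUE)
  prediction_set(truth, probs)
}
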