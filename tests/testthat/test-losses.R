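test_that("cross-entropy matches hand evaluation and clamps zeros", {
  expect_equal(cross_entropy(3, c(0.1, 0.2, 0.6, 0.1))$total, -log(0.6))
  expect_equal(cross_entropy(2, c(0, 1, 0))$total, 0)
  expect_equal(cross_entropy(1, rep(0.25, 4))$total, log(4))
  z <- cross_entropy(1, c(0, 1, 0))
  expect_true(is.finite(z$total))
  expect_equal(z$total, -log(1e-12))
})

test_that("unimodal penalty matches its worked examples", {
  expect_equal(unimodal_penalty(1, c(0.4, 0.1, 0.5), loss_config(delta = 0)),
               0.4)
  expect_equal(unimodal_penalty(1, c(0.4, 0.1, 0.5),
                                loss_config(delta = 0.05)), 0.45)
  expect_equal(unimodal_penalty(2, c(0.2, 0.5, 0.3), loss_config(delta = 0)),
               0)
  # one-hot closed form: delta * (max(k*-2, 0) + (K-1-k*))
  expect_equal(unimodal_penalty(3, encode_one_hot(3, 7),
                                loss_config(delta = 0.05)), 0.20)
})

test_that("CO, CO2 and HO2 combine base and penalty terms", {
  cfg <- loss_config(lambda = 1, delta = 0.05)
  expect_equal(co_loss(2, c(0.2, 0.5, 0.3), cfg)$total, -log(0.5))
  expect_equal(co_loss(1, c(0.4, 0.1, 0.5), cfg)$total, -log(0.4) + 0.4)
  expect_equal(co2_loss(1, c(0.4, 0.1, 0.5), cfg)$total, -log(0.4) + 0.45)
  expect_equal(ho2_loss(2, c(0, 1, 0), cfg)$total, 0)
  expect_equal(ho2_loss(2, rep(0.25, 4), cfg)$total, log(4) + 3 * 0.05)
  expect_equal(ho2_loss(3, encode_one_hot(3, 7), cfg)$total, 0.20)
  v <- co2_loss(1, c(0.4, 0.1, 0.5), loss_config(lambda = 2, delta = 0.05))
  expect_equal(v$total, v$base_term + 2 * v$penalty_term)
})

test_that("CO(lambda=0) is CE and CO2(delta=0) is CO on random draws", {
  set.seed(7)
  dev <- vapply(1:10000, function(i) {
    K <- sample(2:10, 1)
    p <- random_simplex(K)
    k <- sample.int(K, 1)
    lam <- runif(1, 0, 5)
    c(abs(co_loss(k, p, loss_config(lambda = 0))$total -
            cross_entropy(k, p)$total),
      abs(co2_loss(k, p, loss_config(lambda = lam, delta = 0))$total -
            co_loss(k, p, loss_config(lambda = lam))$total))
  }, numeric(2))
  expect_lt(max(dev), 1e-12)
})

test_that("penalty is zero exactly on delta-strict unimodal vectors", {
  set.seed(8)
  res <- vapply(1:10000, function(i) {
    K <- sample(3:8, 1)
    p <- random_simplex(K)
    k <- sample.int(K, 1)
    delta <- sample(c(0, 0.02, 0.05), 1)
    pen <- unimodal_penalty(k, p, loss_config(delta = delta))
    c(dev = abs(pen - brute_penalty(p, k, delta)),
      agree = (pen == 0) == delta_unimodal_at(p, k, delta),
      zero = pen == 0)
  }, numeric(3))
  expect_lt(max(res["dev", ]), 1e-12)
  expect_true(all(res["agree", ] == 1))
  expect_gt(sum(res["zero", ]), 0)  # the zero set is actually exercised
})

test_that("as-printed boundary charges the peak pair from both sides", {
  set.seed(9)
  for (i in 1:300) {
    K <- sample(2:8, 1)
    k <- sample.int(max(K - 1, 1), 1)     # pair at k* exists when k* < K
    p <- random_simplex(K)
    cfg <- loss_config(delta = 0.05, boundary_mode = "as_printed")
    expect_gte(unimodal_penalty(k, p, cfg), 2 * 0.05)
  }
  # ...so even an ideal one-hot is charged more than in default mode
  p <- encode_one_hot(3, 7)
  expect_gt(unimodal_penalty(3, p, loss_config(delta = 0.05,
                                               boundary_mode = "as_printed")),
            unimodal_penalty(3, p, loss_config(delta = 0.05)))
})

test_that("ordinal-encoding loss is mean binary cross-entropy", {
  expect_equal(oe_loss(3, c(1, 1, 0))$total, 0, tolerance = 1e-9)
  expect_equal(oe_loss(2, c(0.5, 0.5))$total, log(2))
  expect_equal(oe_loss(4, c(0.9, 0.9, 0.9))$total, -log(0.9))
})

test_that("binomial and Poisson head losses evaluate the induced PMF", {
  expect_equal(bu_loss(2, q = 1, K = 2)$total, 0, tolerance = 1e-9)
  expect_equal(bu_loss(2, q = 0.5, K = 3)$total, -log(0.5))
  expect_equal(bu_loss(1, q = 0.5, K = 3)$total, -log(0.25))
  expect_equal(pu_loss(1, rate = 1, K = 3)$total, -log(0.4))
  expect_equal(pu_loss(3, rate = 1, K = 3)$total, -log(0.2))
})

test_that("all losses are non-negative and finite on degenerate inputs", {
  cfg <- loss_config(lambda = 3, delta = 0.05)
  set.seed(10)
  ok <- vapply(1:200, function(i) {
    K <- sample(2:8, 1)
    p <- random_simplex(K)
    p[sample.int(K, 1)] <- 0
    p <- p / sum(p)
    k <- sample.int(K, 1)
    all(vapply(list(cross_entropy(k, p), co_loss(k, p, cfg),
                    co2_loss(k, p, cfg), ho2_loss(k, p, cfg)),
               function(v) v$total >= 0 && is.finite(v$total) &&
                 v$penalty_term >= 0, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("evaluate_loss dispatches by name", {
  p <- c(0.1, 0.2, 0.6, 0.1)
  expect_equal(evaluate_loss("ce", 3, p)$total, cross_entropy(3, p)$total)
  expect_equal(evaluate_loss("bu", 2, 0.5, K = 3)$total,
               bu_loss(2, 0.5, 3)$total)
  expect_error(evaluate_loss("huber", 1, p))
})

test_that("analytic batch gradients match numerical differentiation", {
  cfg <- loss_config(lambda = 0.7, delta = 0.05)
  num_grad <- function(f, z, h = 1e-6)
    vapply(seq_along(z), function(i) {
      zp <- z; zm <- z
      zp[i] <- z[i] + h; zm[i] <- z[i] - h
      (f(zp) - f(zm)) / (2 * h)
    }, numeric(1))
  set.seed(42)
  for (loss in ordinal_loss_names()) {
    K <- 5L
    ow <- ordinalco:::output_width(loss, K)
    for (rep in 1:10) {
      z <- rnorm(ow)
      y <- sample.int(K, 1)
      g <- ordinalco:::batch_loss_grad(matrix(z, 1), y, loss, K, cfg)
      f <- function(zz)
        ordinalco:::batch_loss_grad(matrix(zz, 1), y, loss, K, cfg)$loss
      expect_equal(drop(g$dZ), num_grad(f, z), tolerance = 1e-5,
                   label = paste("gradient of", loss))
    }
  }
})
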