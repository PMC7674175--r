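test_that("instar update moves weights toward the presynaptic pattern", {
  expect_equal(instar_update(0.5, pre = 0.70711, post = 1, mu = 0.03),
               0.50621, tolerance = 1e-5)
  # full-rate update reaches the pattern in one step
  expect_equal(instar_update(c(0.1, 0.9), pre = c(0.4, 0.4), post = 1, mu = 1),
               c(0.4, 0.4))
  # no post-synaptic activity, no learning
  W <- runif(4)
  expect_equal(instar_update(W, pre = runif(4), post = 0, mu = 0.5), W)
  expect_error(instar_update(c(1, 2), pre = 1, post = 1, mu = 0.1),
               "dimension mismatch")
})

test_that("instar converges geometrically to a fixed pattern", {
  set.seed(11)
  mu <- 0.05
  W <- runif(4)
  pre <- runif(4, -0.7, 0.7)
  d0 <- sqrt(sum((W - pre)^2))
  bound <- ceiling(log(1e-6 / d0) / log(1 - mu))
  dist <- d0
  for (n in seq_len(bound)) {
    W <- instar_update(W, pre, post = 1, mu = mu)
    d1 <- sqrt(sum((W - pre)^2))
    expect_lt(d1, dist)
    dist <- d1
  }
  expect_lt(dist, 1e-6)
})

test_that("outstar update moves outgoing weights toward the target", {
  expect_equal(outstar_update(c(0.2, 0.2), pre = 1,
                              target_pattern = c(1, 0), mu = 0.03),
               c(0.224, 0.194))
  W <- runif(3)
  expect_equal(outstar_update(W, pre = 0, target_pattern = runif(3), mu = 0.5), W)
  expect_equal(outstar_update(W, pre = 1, target_pattern = W, mu = 0.5), W)
  # fixed-point convergence
  target <- c(0.9, 0.1, 0.5)
  W <- c(0, 0, 0)
  for (n in 1:400) W <- outstar_update(W, pre = 0.8, target, mu = 0.05)
  expect_equal(W, target, tolerance = 1e-6)
  expect_error(outstar_update(c(1, 2), pre = 1, target_pattern = 1, mu = 0.1),
               "dimension mismatch")
})

test_that("Widrow-Hoff descends the squared error below the stability bound", {
  expect_equal(widrow_hoff_update(0.1, pre = 0.5, error = 0.8, mu = 0.01), 0.104)
  W0 <- c(0.3, -0.2)
  expect_equal(widrow_hoff_update(W0, pre = c(1, 1), error = 0, mu = 0.5), W0)
  # linear single-output problem, mu below 2 / ||pre||^2
  set.seed(3)
  pre <- c(0.6, 0.3, 0.8)
  d <- 0.9
  mu <- 0.9 * 2 / sum(pre^2)
  W <- runif(3)
  err_prev <- (d - sum(W * pre))^2
  for (n in 1:50) {
    W <- widrow_hoff_update(W, pre, error = d - sum(W * pre), mu = mu)
    err <- (d - sum(W * pre))^2
    expect_lte(err, err_prev + 1e-12)
    err_prev <- err
  }
  expect_lt(err_prev, 1e-8)
})

test_that("quantum interval update follows the normalized gradient rule", {
  # hand-computed: theta + mu * delta * f(ybar - y) * (vbar - v), L2 norms
  y <- c(0.6, 0.8)          # ||y|| = 1: ybar = y
  v <- c(0.12, 0.2)
  vbar <- v / sqrt(sum(v^2))
  expected <- c(2, 2) + 0.03 * 1 * (1 / (1 + exp(0))) * (vbar - v)
  expect_equal(quantum_interval_update(c(2, 2), y, v, delta = 1, mu = 0.03),
               expected, tolerance = 1e-12)
  # unit-norm y and v: both difference factors vanish
  yu <- c(0.6, 0.8)
  vu <- c(1, 0)
  expect_equal(quantum_interval_update(c(2, 3), yu, vu, delta = 1, mu = 0.1),
               c(2, 3))
  # zero learning rate is a no-op
  expect_equal(quantum_interval_update(c(2, 3), c(0.1, 0.2), c(0.05, 0.1),
                                       delta = 1, mu = 0),
               c(2, 3))
  # zero-norm vectors fall back to the unmodified vector (no-op)
  expect_equal(quantum_interval_update(2, y = 0, v = 0, delta = 1, mu = 0.5), 2)
})

test_that("single-unit layers leave the interval unchanged", {
  # a normalized scalar is degenerate; the update must not drift one-way
  th <- 2
  for (n in 1:100) {
    th <- quantum_interval_update(th, y = 0.17, v = 0.14, delta = 1, mu = 0.03)
  }
  expect_equal(th, 2)
})

test_that("learning rules commute with coordinate permutations", {
  set.seed(21)
  perm <- sample(5)
  W <- runif(5); pre <- runif(5, -0.7, 0.7); tgt <- runif(5)
  expect_equal(instar_update(W, pre, post = 0.6, mu = 0.1)[perm],
               instar_update(W[perm], pre[perm], post = 0.6, mu = 0.1))
  expect_equal(outstar_update(W, pre = 0.7, tgt, mu = 0.1)[perm],
               outstar_update(W[perm], pre = 0.7, tgt[perm], mu = 0.1))
  expect_equal(widrow_hoff_update(W, pre, error = 0.3, mu = 0.1)[perm],
               widrow_hoff_update(W[perm], pre[perm], error = 0.3, mu = 0.1))
  y <- runif(5); v <- runif(5, 0, 0.25); th <- runif(5, 1, 3)
  expect_equal(quantum_interval_update(th, y, v, 1, 0.05)[perm],
               quantum_interval_update(th[perm], y[perm], v[perm], 1, 0.05))
})

test_that("error metrics report signed, half-sum, and absolute forms", {
  r <- error_metrics(c(1, 1), c(0, 0))
  expect_equal(r$half_sum, 1.0)
  expect_equal(r$mean_abs, 1.0)
  r2 <- error_metrics(0.8, 1)
  expect_equal(r2$half_sum, -0.1)
  expect_equal(r2$mean_abs, 0.2)
  r3 <- error_metrics(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(r3$half_sum, 0)
  expect_equal(r3$mean_abs, 0)
  expect_error(error_metrics(c(1, 2), 1), "dimension mismatch")
})

test_that("learning_config validates its domain", {
  expect_error(learning_config(mu_cortical = 0), "learning rates")
  expect_error(learning_config(epsilon = 0.6), "epsilon")
  expect_error(learning_config(max_trials = 0), "max_trials")
  cfg <- learning_config()
  expect_equal(cfg$mu_hippocampal, 0.03)
  expect_equal(cfg$mu_cortical, 0.01)
  expect_equal(cfg$theta_init, 2)
  expect_equal(cfg$hidden_aqinn, 1L)
  expect_equal(cfg$hidden_ffqinn, 16L)
})
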