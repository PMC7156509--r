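test_that("the dense epsilon-rule reproduces hand-evaluated redistributions", {
  l <- layer_dense(2, 1, weights = matrix(c(1, -1), 2, 1))
  # z = (2, -1), sum z = 1, denominator = 1 + 1*sign(1) = 2
  expect_equal(relprop_dense_epsilon(l, c(2, 1), 1, epsilon = 1), c(1, -0.5))
  # epsilon = 0 conserves: R = (2, -1), sum = R_out
  expect_equal(relprop_dense_epsilon(l, c(2, 1), 1, epsilon = 0), c(2, -1))
  # zero inputs receive zero relevance
  r <- relprop_dense_epsilon(layer_dense(2, 1, weights = matrix(c(3, 5), 2, 1)),
                             c(1, 0), 1, epsilon = 0)
  expect_equal(r, c(1, 0))
})

test_that("sign(0) is treated as +1 in the epsilon denominator", {
  # cancelling inputs: sum z = 0, denominator = 0 + eps*1
  l <- layer_dense(2, 1, weights = matrix(c(1, -1), 2, 1))
  r <- relprop_dense_epsilon(l, c(1, 1), 1, epsilon = 1)
  expect_equal(r, c(1, -1))
})

test_that("the conv alpha-beta-rule reproduces the hand-evaluated example", {
  # one unit with contributions z = (1, 2, -2): positives (1, 2, 0) share R = 3
  wk <- array(0, c(3, 3, 1, 1)); wk[1, 1, 1, 1] <- 1
  wk[1, 2, 1, 1] <- 1; wk[1, 3, 1, 1] <- 2
  lc <- layer_conv(1, 1, 3, weights = wk)
  xin <- array(0, c(3, 3, 1)); xin[1, 1:3, 1] <- c(1, 2, -1)
  R <- relprop_conv_alphabeta(lc, xin, array(3, c(1, 1, 1)), alpha = 1, beta = 0)
  expect_equal(R[1, 1:3, 1], c(1, 2, 0))
  expect_equal(sum(abs(R)), 3)
})

test_that("all-negative units absorb their relevance under alpha=1, beta=0", {
  wk <- array(-1, c(2, 2, 1, 1))
  lc <- layer_conv(1, 1, 2, weights = wk)
  xin <- array(1, c(2, 2, 1))
  R <- relprop_conv_alphabeta(lc, xin, array(5, c(1, 1, 1)), 1, 0)
  expect_equal(sum(abs(R)), 0)
})

test_that("max pooling routes relevance to the window argmax", {
  lp <- layer_maxpool(2)
  xp <- array(c(1, 2, 3, 0), c(2, 2, 1))
  Rp <- relprop_pool(lp, xp, array(5, c(1, 1, 1)))
  expect_equal(Rp[, , 1], matrix(c(0, 0, 5, 0), 2, 2))
  # first (lowest linear index) wins ties
  xt <- array(c(4, 4, 4, 4), c(2, 2, 1))
  Rt <- relprop_pool(lp, xt, array(8, c(1, 1, 1)))
  expect_equal(Rt[, , 1], matrix(c(8, 0, 0, 0), 2, 2))
})

test_that("global average pooling splits relevance proportional to value", {
  lg <- layer_global_avgpool()
  xg <- array(c(1, 2, 3, 4), c(2, 2, 1))
  Rg <- relprop_pool(lg, xg, 10)
  expect_equal(as.vector(Rg), c(1, 2, 3, 4))
  # zero channel absorbs
  expect_equal(sum(abs(relprop_pool(lg, array(0, c(2, 2, 1)), 10))), 0)
})

test_that("flatten reshapes relevance, preserving values and sum", {
  lf <- layer_flatten()
  x <- array(runif(12), c(2, 3, 2))
  R <- runif(12)
  out <- relprop_pool(lf, x, R)
  expect_equal(dim(out), dim(x))
  expect_equal(as.vector(out), R)
})

test_that("explain reproduces the single-dense-layer map", {
  net <- layered_network(
    list(layer_flatten(), layer_dense(2, 2, weights = matrix(c(1, -1, 0, 0), 2, 2))),
    c(1L, 2L, 1L), classes = c("a", "b"))
  m <- explain(net, array(c(2, 1), c(1, 2, 1)), target_class = "a",
               params = rule_params(epsilon = 1))
  expect_equal(as.vector(m$values), c(1, -0.5))
  expect_equal(m$seed_value, 1)
  expect_equal(m$normalisation, "raw")
})

test_that("all-positive networks conserve relevance through the full chain", {
  for (seed in 1:10) {
    net <- random_small_net(seed, positive = TRUE)
    set.seed(seed)
    x <- array(runif(24 * 24 * 3), c(24, 24, 3))
    m <- explain(net, x, "cancer", rule_params(epsilon = 0, alpha = 1, beta = 0),
                 seed = "logit")
    expect_gt(m$seed_value, 0)
    expect_equal(sum(m$values), m$seed_value, tolerance = 1e-6 * m$seed_value)
  }
})

test_that("margin seeding explains the logit difference and conserves it", {
  for (seed in 1:5) {
    net <- random_small_net(seed, positive = TRUE)
    set.seed(seed + 50)
    x <- array(runif(24 * 24 * 3), c(24, 24, 3))
    tr <- forward(net, x)
    m <- explain(net, x, "cancer", rule_params(epsilon = 0), seed = "margin",
                 trace = tr)
    expect_equal(m$seed_value,
                 unname(tr$scores["cancer"] - tr$scores["no_cancer"]))
    # the margin functional is linear in the head, so with epsilon = 0 and
    # no absorbed conv units the map still sums to the seeded quantity
    expect_equal(sum(m$values), m$seed_value,
                 tolerance = 1e-6 * max(abs(m$seed_value), 1))
  }
})

test_that("all-zero input with zero biases yields an all-zero map", {
  net <- random_small_net(4)
  m <- explain(net, array(0, c(24, 24, 3)), "cancer", rule_params())
  expect_equal(m$seed_value, 0)
  expect_true(all(m$values == 0))
})

test_that("epsilon=0 dense rule equals brute-force contribution decomposition", {
  set.seed(31)
  for (rep in 1:100) {
    n_in <- sample(2:8, 1); n_out <- sample(1:4, 1)
    w <- matrix(rnorm(n_in * n_out), n_in, n_out)
    x <- rnorm(n_in)
    R_up <- rnorm(n_out)
    l <- layer_dense(n_in, n_out, weights = w)
    got <- relprop_dense_epsilon(l, x, R_up, epsilon = 0)
    # oracle: explicit contribution shares per (i, j) pair
    want <- numeric(n_in)
    for (j in seq_len(n_out)) {
      z <- x * w[, j]
      s <- sum(z)
      if (s != 0) want <- want + z / s * R_up[j]
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("epsilon shrinks propagated relevance monotonically in magnitude", {
  set.seed(13)
  for (rep in 1:50) {
    n_in <- sample(2:6, 1)
    w <- matrix(rnorm(n_in), n_in, 1)
    x <- rnorm(n_in)
    l <- layer_dense(n_in, 1, weights = w)
    if (sum(x * w) == 0) next
    R_out <- 1
    sums <- vapply(c(0, 0.5, 1, 2), function(eps)
      abs(sum(relprop_dense_epsilon(l, x, R_out, eps))), numeric(1))
    expect_true(all(diff(sums) <= 1e-12))
    expect_true(all(sums <= abs(R_out) + 1e-12))
  }
})

test_that("conv relprop equals the explicit unrolled-matrix formulation", {
  set.seed(77)
  for (rep in 1:5) {
    h <- 5; w <- 6; cin <- 2; cout <- 3; k <- 3
    lc <- layer_conv(cin, cout, k,
                     weights = array(rnorm(k * k * cin * cout), c(k, k, cin, cout)),
                     bias = rnorm(cout) * 0.1)
    x <- array(runif(h * w * cin), c(h, w, cin))
    ho <- h - k + 1; wo <- w - k + 1
    R_up <- array(rnorm(ho * wo * cout), c(ho, wo, cout))
    got <- relprop_conv_alphabeta(lc, x, R_up, alpha = 1, beta = 0)
    # oracle: unroll the convolution into one big dense layer over flat input
    want <- array(0, c(h, w, cin))
    Wk <- array(lc$wmat, c(k, k, cin, cout))
    for (co in seq_len(cout)) for (oy in seq_len(ho)) for (ox in seq_len(wo)) {
      z <- array(0, c(h, w, cin))
      for (c in seq_len(cin))
        z[oy:(oy + k - 1), ox:(ox + k - 1), c] <-
          x[oy:(oy + k - 1), ox:(ox + k - 1), c] * Wk[, , c, co]
      zp <- pmax(z, 0)
      sp <- sum(zp) + max(lc$bias[co], 0)
      if (sp > 0) want <- want + zp / sp * R_up[oy, ox, co]
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("relevance conservation holds per layer without absorbed units", {
  # alpha=1/beta=0 with positive weights, non-negative inputs, zero biases:
  # no unit can absorb, so each layer must conserve to 1e-6 relative
  for (seed in 1:100) {
    set.seed(seed)
    n_in <- sample(3:10, 1); n_out <- sample(2:5, 1)
    w <- matrix(runif(n_in * n_out, 0.1, 1), n_in, n_out)
    x <- runif(n_in, 0.1, 1)
    R_up <- runif(n_out)
    l <- layer_dense(n_in, n_out, weights = w)
    R <- relprop_dense_epsilon(l, x, R_up, epsilon = 0)
    expect_equal(sum(R), sum(R_up), tolerance = 1e-6)
    k <- 2
    lc <- layer_conv(1, 1, k, weights = array(runif(k * k, 0.1, 1), c(k, k, 1, 1)))
    xc <- array(runif(9, 0.1, 1), c(3, 3, 1))
    Rc_up <- array(runif(4), c(2, 2, 1))
    Rc <- relprop_conv_alphabeta(lc, xc, Rc_up, 1, 0)
    expect_equal(sum(Rc), sum(Rc_up), tolerance = 1e-6)
  }
})

test_that("a non-zero beta is flagged to the user", {
  expect_message(rule_params(beta = 0.5), "beta != 0")
  expect_silent(rule_params())
})
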