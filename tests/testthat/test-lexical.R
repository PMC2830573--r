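test_that("lexical sigmoid has the stated midpoint, slope and limits", {
  expect_equal(lexical_sigmoid(2.5, theta = 2.5, p = 2), 0.5)
  expect_equal(lexical_sigmoid(0.7, theta = 0.7, p = 13), 0.5)
  expect_equal(lexical_sigmoid(1e4, 0, 1), 1)
  expect_equal(lexical_sigmoid(-1e4, 0, 1), 0)
  # closed form
  expect_equal(lexical_sigmoid(1, 0, 2), 1 / (1 + exp(-2)))
  expect_true(all(diff(lexical_sigmoid(seq(-5, 5, 0.1), 0, 1)) > 0))
  expect_error(lexical_sigmoid(0, 0, -1), "positive")
})

test_that("feature drive is the weighted sum over oscillator activities", {
  expect_equal(feature_drive(matrix(0, 3, 5), runif(5)), rep(0, 3))
  W <- matrix(0, 2, 4); W[1, 3] <- 0.7
  expect_equal(feature_drive(W, c(0, 0, 0.5, 0)), c(0.35, 0))
  expect_error(feature_drive(W, 1:3), "match")
  # brute-force oracle on a dense case
  set.seed(42)
  W <- matrix(runif(12), 3, 4); x <- runif(4)
  brute <- vapply(1:3, function(i) sum(W[i, ] * x), numeric(1))
  expect_equal(feature_drive(W, x), brute)
})

test_that("competitive inhibition excludes self and rejects bad weights", {
  W <- matrix(c(0, 2, 3, 0), 2, 2)
  expect_equal(competition_drive(W, c(0, 0)), c(0, 0))
  expect_equal(competition_drive(W, c(1, 0.5)), as.numeric(W %*% c(1, 0.5)))
  expect_error(competition_drive(matrix(c(1, 0, 0, 0), 2, 2), c(1, 1)),
               "self")
  expect_error(competition_drive(matrix(c(0, -1, 0, 0), 2, 2), c(1, 1)),
               "nonnegative")
})

test_that("net lexical input is the exact signed sum with gating", {
  expect_equal(lexical_input(0, 0, 1, 0, 0, G = 16), 0)
  expect_equal(lexical_input(rep(0, 4), rep(0, 4), 0, rep(0, 4), rep(0, 4),
                             G = 16), rep(-16, 4))
  expect_equal(lexical_input(17, 3, 0, 2, 1, G = 16), 17 + 3 - 16 - 2 - 1)
  expect_error(lexical_input(0, 0, 0.5, 0, 0, 16), "0 or 1")
  expect_error(lexical_input(0, 0, 1, 0, -1, 16), "nonnegative")
  # an external word input built by word_input overcomes full gating
  net <- mini_network()
  u <- lexical_input(max(word_input(net, "L1")), 0, 0, 0, 0,
                     net$lex$gate_strength)
  expect_gt(u, net$lex$theta)
})

test_that("lexical dynamics follow the first-order closed form", {
  par <- lexical_params()
  # fixed point: x = H(u) is unchanged
  u <- 3
  xstar <- lexical_sigmoid(u, par$theta, par$slope)
  expect_equal(step_lexical(xstar, u, par, 0.05), xstar)
  # analytic solution of the linear ODE: x(tau) = (1 - e^-1) H(u), x(0)=0
  dt <- 0.002
  x <- 0
  for (i in seq_len(round(par$tau / dt))) x <- step_lexical(x, u, par, dt)
  expect_equal(x, (1 - exp(-1)) * xstar, tolerance = 1e-3)
  # removing the input decays back with the same time constant
  for (i in seq_len(round(5 * par$tau / dt)))
    x <- step_lexical(x, -1e3, par, dt)
  expect_lt(x, 1e-2)
  expect_error(step_lexical(0, NaN, par, 0.05), "finite")
  expect_error(step_lexical(0, 1, par, par$tau), "dt")
})

test_that("interneurons track their paired word unit only", {
  par <- lexical_params()
  x <- 0.5
  for (i in 1:20000) x <- step_interneuron(x, 0, par, 0.05)
  expect_equal(x, lexical_sigmoid(0, par$theta_int, par$slope_int),
               tolerance = 1e-6)
  expect_lt(x, 0.05)
  x <- 0
  for (i in 1:20000) x <- step_interneuron(x, 1, par, 0.05)
  expect_gt(x, 0.94)
  # an interneuron much slower than the gamma period tracks the mean of
  # an oscillating word with ripple bounded by the low-pass prediction
  par <- lexical_params(tau_int = 50)
  dt <- 0.05; f <- 40
  t <- seq(dt, 500, by = dt)
  word <- 0.5 + 0.5 * sin(2 * pi * f * t / 1000)
  x <- 0
  xs <- numeric(length(t))
  for (i in seq_along(t)) {
    x <- step_interneuron(x, word[i], par, dt)
    xs[i] <- x
  }
  tail_x <- xs[t > 300]
  ripple <- (max(tail_x) - min(tail_x)) / 2
  # input to the low-pass is H(word(t)), a sharpened (square-ish) wave:
  # its fundamental can reach 4/pi times the half-swing, and higher
  # harmonics are attenuated even more by the first-order filter
  h <- lexical_sigmoid(word[t > 300], par$theta_int, par$slope_int)
  atten <- 1 / sqrt(1 + (2 * pi * f / 1000 * par$tau_int)^2)
  expect_lt(ripple, (4 / pi) * 1.1 * atten * (max(h) - min(h)) / 2)
  expect_lt(ripple, 0.15)  # competition integrates, it does not chop
})

test_that("engine lexical update equals the explicit Euler discretization", {
  # drive one word with a constant external input, no trained weights: the
  # engine trajectory must match the R-side Euler recursion to machine
  # precision
  net <- mini_network()
  wdrv <- word_input(net, "L2")
  sim <- simulate_network(net, word_drive = wdrv, duration_ms = 20,
                          record_ms = 0.05, record_features = FALSE)
  par <- net$lex
  x <- 0; z <- 0  # gate stays closed (no bubbles)
  ref <- numeric(length(sim$time_ms))
  for (i in seq_along(ref)) {
    u <- lexical_input(max(wdrv), 0, z, 0, 0, par$gate_strength)
    x <- step_lexical(x, u, par, 0.05)
    ref[i] <- x
  }
  expect_equal(as.numeric(sim$word_act[, "L2"]), ref, tolerance = 1e-12)
})

test_that("gating keeps feature-driven words silent while the gate is closed", {
  # trained network, object input, persistence long enough that the gate
  # never opens within the simulation: all word activity stays < 0.05
  net <- mini_phase2()
  net$dec <- decision_params(persistence_ms = 1e5)
  sim <- simulate_network(net, feature_drive = object_stimulus(net, 1),
                          duration_ms = 400)
  expect_true(all(sim$gate == 0))
  expect_lt(max(sim$word_act), 0.05)
  expect_lt(max(sim$lex_background), 0.05)
})

test_that("a strong bias silences a word regardless of other drive", {
  net <- mini_phase2()
  sim <- simulate_network(net, feature_drive = object_stimulus(net, 1),
                          bias_drive = bias_input(net, "L1", amplitude = 50),
                          duration_ms = 400)
  expect_lt(max(sim$word_act[, "L1"]), 0.05)
})
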