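test_that("default oscillator has a silent rest state and a gamma limit cycle", {
  p <- oscillator_params()          # construction itself runs the regime gate
  chk <- check_gamma_regime(p)
  expect_true(chk$rest_silent)
  expect_lt(chk$rest_max, 0.01)
  expect_true(chk$gamma)
  expect_gte(chk$period_ms, 20)
  expect_lte(chk$period_ms, 30)
})

test_that("a driven oscillator oscillates across the drives the network stacks", {
  p <- oscillator_params()
  # gamma period near the reference drive
  for (drive in c(1.5, 2, 2.5)) {
    tr <- bilexnet:::.engine_single_oscillator(p, drive, 600, 0.05)
    xs <- tr[tr[, "time_ms"] > 150, "x"]
    est <- dominant_frequency(xs, 0.05)
    expect_gt(est$freq_hz, 1000 / 30)
    expect_lt(est$freq_hz, 1000 / 20)
    expect_true(all(xs >= 0 & xs <= 1))
  }
  # no amplitude death up to the largest summed synaptic drive a unit sees
  for (drive in c(4, 8, 12)) {
    tr <- bilexnet:::.engine_single_oscillator(p, drive, 600, 0.05)
    xs <- tr[tr[, "time_ms"] > 150, "x"]
    expect_gt(max(xs) - min(xs), 0.3)
    expect_gt(dominant_frequency(xs, 0.05)$freq_hz, 30)
  }
})

test_that("parameter sets violating the regime are rejected at construction", {
  # no inhibition: cannot oscillate
  expect_error(oscillator_params(g_ie = 0, g_ei = 0), "limit cycle")
  expect_error(oscillator_params(tau_ex = -1), "positive")
})

test_that("network at rest stays silent and bounded under bounded drive", {
  net <- mini_network()
  sim <- simulate_network(net, duration_ms = 1000)
  expect_lt(max(sim$feature_ex), 0.01)
  expect_true(all(sim$bubble_counts == 0))
  expect_true(is.na(sim$gate_open_ms))
  # arbitrary bounded stimulus: activities stay in [0,1]
  drv <- object_stimulus(net, 1, amplitude = 8, spread = 2)
  sim2 <- simulate_network(net, feature_drive = drv, duration_ms = 300)
  expect_true(all(sim2$feature_ex >= 0 & sim2$feature_ex <= 1))
  expect_true(all(sim2$word_act >= 0 & sim2$word_act <= 1))
})

test_that("invalid integration inputs are rejected", {
  net <- mini_network()
  expect_error(simulate_network(net, duration_ms = 100, dt = 1), "dt")
  bad <- object_stimulus(net, 1); bad[1] <- NaN
  expect_error(simulate_network(net, feature_drive = bad), "finite")
})

test_that("object stimulus concentrates drive on the specified features", {
  net <- mini_network()
  d0 <- object_stimulus(net, 1, amplitude = 3, spread = 0)
  expect_equal(sum(d0 != 0), net$geometry$n_areas)
  expect_equal(unique(d0[d0 != 0]), 3)
  expect_equal(sum(object_stimulus(net, 1, amplitude = 0)), 0)
  # coordinate outside the grid is a fixture error
  bad_obj <- object_spec(rep(list(c(30, 30)), 2))
  expect_error(
    bilex_network(geometry = net$geometry, objects = list(bad_obj),
                  words = net$words,
                  lex = lexical_params(m1 = 12, m2 = 12)),
    "outside")
})

test_that("trained object features form one bubble per area and bind", {
  net1 <- mini_phase1()
  simf <- simulate_network(net1, feature_drive = object_stimulus(net1, 1),
                           duration_ms = 400)
  counts <- vapply(seq_len(2), function(a)
    length(detect_bubbles(feature_window_max(simf, a), 0.5)), integer(1))
  expect_equal(counts, c(1L, 1L))
  expect_false(is.na(simf$gate_open_ms))
  # binding: the two areas oscillate with near-zero lag
  geom <- net1$geometry; M <- geom$side
  win <- simf$time_ms > 150
  tr <- lapply(1:2, function(a) {
    wm <- feature_window_max(simf, a)
    idx <- (a - 1) * M * M + which(t(wm) >= 0.5)
    rowMeans(simf$feature_ex[win, idx, drop = FALSE])
  })
  expect_lt(abs(phase_lag(tr[[1]], tr[[2]], 0.5)), 2)
  # an untrained network does not complete a partial pattern
  sim0 <- simulate_network(mini_network(), feature_drive =
                             object_stimulus(net1, 1, areas = 1),
                           duration_ms = 300)
  wm2 <- feature_window_max(sim0, 2)
  expect_equal(length(detect_bubbles(wm2, 0.5)), 0L)
})

test_that("partial cues of a trained object retrieve the remaining bubbles", {
  # reference-scale network (shared trained curriculum): 3-of-4 and even
  # 1-of-4 feature cues must re-create all four bubbles
  net <- paper_checkpoints()$untrained
  for (cue in list(1:3, 1)) {
    sim <- simulate_network(net, feature_drive =
                              object_stimulus(net, 1, areas = cue),
                            duration_ms = 600)
    counts <- vapply(seq_len(4), function(a)
      length(detect_bubbles(feature_window_max(sim, a), 0.5)), integer(1))
    expect_equal(counts, rep(1L, 4),
                 label = paste("bubble census with cue areas",
                               paste(cue, collapse = ",")))
    # the completed area is phase-locked to a cued one
    geom <- net$geometry; M <- geom$side
    win <- sim$time_ms > 350
    tr <- lapply(c(1, 4), function(a) {
      wm <- feature_window_max(sim, a)
      idx <- (a - 1) * M * M + which(t(wm) >= 0.5)
      rowMeans(sim$feature_ex[win, idx, drop = FALSE])
    })
    expect_lt(abs(phase_lag(tr[[1]], tr[[2]], 0.5)), 2)
  }
})

test_that("inter-area weights become near-symmetric under symmetric co-activation", {
  WA <- mini_phase1()$weights$inter_area
  nz <- WA > 0.01
  expect_gt(sum(nz), 0)
  expect_lt(max(abs(WA - t(WA))[nz]), 0.01 * max(WA))
})
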