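test_that("soft-bounded Hebbian rule matches its closed-form recurrence", {
  # zero pre or post activity leaves weights unchanged
  W <- matrix(0.2, 2, 2)
  expect_equal(hebbian_update(W, c(0, 0), c(1, 1), 0.1, 1), W)
  expect_equal(hebbian_update(W, c(1, 1), c(0, 0), 0.1, 1), W)
  # direct increment at full co-activation from zero
  expect_equal(hebbian_update(matrix(0, 1, 1), 1, 1, 0.3, 5)[1, 1], 0.3)
  # repeated co-activation approaches the ceiling monotonically; oracle is
  # the closed-form geometric solution W_n = wmax (1 - (1 - beta/wmax)^n)
  beta <- 0.07; wmax <- 2
  W <- matrix(0, 1, 1)
  for (n in 1:200) {
    W <- hebbian_update(W, 1, 1, beta, wmax)
    expect_equal(W[1, 1], wmax * (1 - (1 - beta / wmax)^n),
                 tolerance = 1e-12)
  }
  expect_lt(W[1, 1], wmax)
  expect_error(hebbian_update(W, 1, 1, -0.1, 1), "nonnegative")
})

test_that("weights never exceed the ceiling over many updates", {
  beta <- 0.5; wmax <- 1.3
  W <- matrix(0, 1, 1)
  top <- 0
  for (n in 1:1e5) {
    W <- hebbian_update(W, 1, 1, beta, wmax)
    top <- max(top, W[1, 1])
  }
  expect_lte(top, wmax)
  expect_equal(W[1, 1], wmax, tolerance = 1e-10)
})

test_that("masked entries stay frozen", {
  mask <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- hebbian_update(matrix(0, 2, 2), c(1, 1), c(1, 1), 0.2, 1, mask = mask)
  expect_equal(diag(W), c(0, 0))
  expect_true(all(W[mask == 1] > 0))
})

test_that("zero training leaves all synapse groups at zero", {
  net <- mini_network()
  net0 <- train_phase1(net, presentations = 0)
  expect_true(all(net0$weights$inter_area == 0))
  net0 <- train_phase3(net0, epochs = 0)
  expect_true(all(net0$weights$feature_to_word == 0))
  expect_true(all(net0$weights$competition == 0))
})

test_that("training conserves structural zeros and stays within bounds", {
  ck <- mini_checkpoints()
  tr <- ck$strong$train
  W <- ck$strong$weights
  expect_true(all(W$inter_area >= 0 & W$inter_area <= tr$wmax_inter_area))
  expect_true(all(W$feature_to_word <= tr$wmax_feature_to_word))
  expect_true(all(W$word_to_feature <= tr$wmax_word_to_feature))
  expect_true(all(W$competition <= tr$wmax_competition))
  # no within-area inter-area entries
  M2 <- ck$strong$geometry$side^2
  blk <- W$inter_area[seq_len(M2), seq_len(M2)]
  expect_true(all(blk == 0))
  # a word never learns inhibition from its own interneuron
  expect_equal(diag(W$competition), rep(0, 2))
  # units never co-active with a word keep exactly zero weight: the
  # object bubble occupies a corner of area 1; far-away units must be 0
  geom <- ck$strong$geometry
  far <- feature_index(geom, 1, geom$side, geom$side)
  expect_equal(W$feature_to_word[, far], c(0, 0))
  expect_equal(W$word_to_feature[far, ], c(0, 0))
})

test_that("after the L1 phase the word and the object evoke each other", {
  net2 <- mini_phase2()
  # word -> object: one bubble per area
  sc <- run_scenario(net2, "l1_word", duration_ms = 500)
  expect_equal(sc$n_bubbles, rep(1L, 2))
  expect_true(sc$recognized)
  # object -> word
  sc2 <- run_scenario(net2, "object", duration_ms = 500)
  expect_equal(sc2$words$classification[sc2$words$label == "L1"], "active")
  # untrained distractor word evokes nothing
  sc3 <- run_scenario(net2, "l2_word", duration_ms = 500)
  expect_equal(sum(sc3$n_bubbles), 0L)
})

test_that("L2 acquisition is monotone and crosses weak before strong", {
  ck <- mini_checkpoints()
  h <- ck$history
  expect_true(all(diff(h$ratio) > -1e-9))
  expect_lt(min(which(h$ratio >= 0.3)), min(which(h$ratio >= 0.9)))
  expect_gte(l2_weight_ratio(ck$weak), 0.3)
  expect_lt(l2_weight_ratio(ck$weak), 0.7)
  expect_gte(l2_weight_ratio(ck$strong), 0.9)
  # retrieval quality (bubble count, then mean bubble activity) is
  # non-decreasing across untrained -> weak -> strong
  quality <- lapply(list(ck$untrained, ck$weak, ck$strong), function(net) {
    sc <- run_scenario(net, "l2_word", duration_ms = 500)
    obj <- object_activity_trace(sc$sim)
    list(nb = sum(sc$n_bubbles), act = mean(obj$trace))
  })
  expect_equal(quality[[1]]$nb, 0L)
  expect_gte(quality[[2]]$nb, quality[[1]]$nb)
  expect_gte(quality[[3]]$nb, quality[[2]]$nb)
  expect_gte(quality[[3]]$act, quality[[2]]$act - 1e-9)
})

test_that("two words trained identically acquire near-identical weights", {
  # symmetric curriculum: object plus both words presented together from
  # scratch; permutation symmetry of the rule must give equal matrices
  net <- mini_phase1()
  for (k in 1:6) {
    sim <- simulate_network(net,
                            feature_drive = object_stimulus(net, 1),
                            word_drive = word_input(net, c("L1", "L2")),
                            duration_ms = 300,
                            learn = c("feature_to_word", "word_to_feature",
                                      "competition"),
                            record_features = FALSE)
    net <- sim$network
  }
  WF <- net$weights$feature_to_word
  expect_gt(sum(WF[1, ]), 0)
  expect_equal(WF[1, ], WF[2, ], tolerance = 0.01)
  WL <- net$weights$word_to_feature
  expect_equal(WL[, 1], WL[, 2], tolerance = 0.01)
  WI <- net$weights$competition
  expect_equal(WI[1, 2], WI[2, 1], tolerance = 0.01)
})
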