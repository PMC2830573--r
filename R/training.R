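#' Soft-bounded Hebbian update
#'
#' One sampling-instant update of a weight matrix: each weight grows by
#' `beta_eff * post * pre` with the effective rate
#' `beta_eff = beta * (1 - W / w_max)`, so growth tapers to zero as a
#' weight approaches its ceiling. The result is clipped to
#' `[0, w_max]`. A weight whose pre- or post-activity is zero is
#' unchanged.
#'
#' @param W weight matrix (`n_post` x `n_pre`), entries in `[0, w_max]`.
#' @param pre presynaptic activity vector (length `n_pre`), in `[0, 1]`.
#' @param post postsynaptic activity vector (length `n_post`).
#' @param beta learning rate (>= 0).
#' @param w_max saturation ceiling (> 0).
#' @param mask optional logical/0-1 matrix; entries with `mask == FALSE`
#'   are frozen (used to keep within-area and self-competition entries
#'   structurally absent).
#' @return the updated weight matrix.
#' @export
hebbian_update <- function(W, pre, post, beta, w_max, mask = NULL) {
  if (beta < 0) stop("learning rate must be nonnegative")
  if (w_max <= 0) stop("w_max must be positive")
  dW <- beta * (1 - W / w_max) * outer(post, pre)
  if (!is.null(mask)) dW <- dW * mask
  pmin(pmax(W + dW, 0), w_max)
}

weight_norm <- function(v) sqrt(sum(v^2))

#' Trained-weight ratio of L2 relative to L1
#'
#' Euclidean norm of the L2 word's feature-to-word weights divided by the
#' L1 word's. Defines the proficiency checkpoints: `weak` when the ratio
#' first reaches `weak_ratio` (default 0.3), `strong` at `strong_ratio`
#' (default 0.9).
#'
#' @param net a trained [bilex_network()].
#' @param l1,l2 word labels.
#' @return a single number (0 for an untrained L2).
#' @export
l2_weight_ratio <- function(net, l1 = "L1", l2 = "L2") {
  i1 <- word_index(net, l1)
  i2 <- word_index(net, l2)
  n1 <- weight_norm(net$weights$feature_to_word[i1, ])
  if (n1 == 0) return(NA_real_)
  weight_norm(net$weights$feature_to_word[i2, ]) / n1
}

#' Phase (i): object learning
#'
#' Presents each object individually with all its features and trains the
#' inter-area feature synapses with the soft-bounded Hebbian rule. After
#' this phase an object can be retrieved from incomplete cues: any
#' single-feature cue re-creates all bubbles.
#'
#' @param net a [bilex_network()].
#' @param presentations number of presentations per object (default from
#'   the training parameters).
#' @param amplitude,spread object stimulus shape, see [object_stimulus()].
#' @param dt Euler step (ms).
#' @return the network with trained inter-area weights and
#'   `phase = "phase1"`.
#' @export
train_phase1 <- function(net, presentations = NULL, amplitude = 3,
                         spread = 1, dt = 0.05) {
  presentations <- presentations %||% net$train$phase1_presentations
  if (presentations == 0) return(net)
  for (k in seq_len(presentations)) {
    for (ob in seq_along(net$objects)) {
      drive <- object_stimulus(net, ob, amplitude = amplitude,
                               spread = spread)
      sim <- simulate_network(net, feature_drive = drive,
                              duration_ms = net$train$presentation_ms,
                              dt = dt, learn = "inter_area",
                              record_features = FALSE)
      net <- sim$network
    }
  }
  net$phase <- "phase1"
  net
}

#' Phase (ii): L1 word-object association
#'
#' Presents an object together with its L1 word and trains the
#' feature-to-word and word-to-feature synapses in both directions. After
#' this phase the object evokes the word and the word evokes the object.
#'
#' @param net a network after [train_phase1()].
#' @param l1 label of the word to associate.
#' @param object object to present (index or label).
#' @param presentations number of joint presentations.
#' @param amplitude,spread object stimulus shape.
#' @param dt Euler step (ms).
#' @return the network with trained word synapses and `phase = "phase2"`.
#' @export
train_phase2 <- function(net, l1 = "L1", object = 1, presentations = NULL,
                         amplitude = 3, spread = 1, dt = 0.05) {
  presentations <- presentations %||% net$train$phase2_presentations
  for (k in seq_len(presentations)) {
    fdrive <- object_stimulus(net, object, amplitude = amplitude,
                              spread = spread)
    wdrive <- word_input(net, l1)
    sim <- simulate_network(net, feature_drive = fdrive,
                            word_drive = wdrive,
                            duration_ms = net$train$presentation_ms,
                            dt = dt,
                            learn = c("feature_to_word", "word_to_feature"),
                            record_features = FALSE)
    net <- sim$network
  }
  net$phase <- "phase2"
  net
}

#' Phase (iii): L2 acquisition with competitive synapses
#'
#' Each epoch presents the L1 word together with the new L2 word. The L1
#' word retrieves the object in the feature areas; the synapses linking
#' the feature areas to the L2 word (and back) grow by the Hebbian rule,
#' and the inhibitory synapses from each word's interneuron onto the
#' other word grow as well, because both words -- and hence both
#' interneurons -- are active during the presentation.
#'
#' @param net a network after [train_phase2()].
#' @param l1,l2 word labels.
#' @param epochs number of paired presentations (0 leaves L2 untrained).
#' @param dt Euler step (ms).
#' @return the network with `phase = "phase3"`.
#' @export
train_phase3 <- function(net, l1 = "L1", l2 = "L2", epochs = 1, dt = 0.05) {
  if (identical(word_index(net, l1), word_index(net, l2)))
    stop("L1 and L2 must be distinct words")
  if (epochs == 0) return(net)
  for (k in seq_len(epochs)) {
    wdrive <- word_input(net, c(l1, l2))
    sim <- simulate_network(net, word_drive = wdrive,
                            duration_ms = net$train$presentation_ms,
                            dt = dt,
                            learn = c("feature_to_word", "word_to_feature",
                                      "competition"),
                            record_features = FALSE)
    net <- sim$network
  }
  net$phase <- "phase3"
  net
}

#' Run the full curriculum and collect proficiency checkpoints
#'
#' Trains phases (i) and (ii), then runs phase-(iii) epochs until the
#' L2-to-L1 weight ratio crosses the `weak` and `strong` thresholds,
#' saving a checkpoint network at each stage.
#'
#' @param net a freshly constructed [bilex_network()].
#' @param max_epochs safety cap on phase-(iii) epochs.
#' @param dt Euler step (ms).
#' @param verbose print phase transitions and checkpoint ratios.
#' @return a list with networks `untrained`, `weak`, `strong`, and a
#'   data.frame `history` (epoch, ratio).
#' @export
train_curriculum <- function(net, max_epochs = 60, dt = 0.05,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("phase i: object learning (%d presentations)",
      net$train$phase1_presentations)
  net <- train_phase1(net, dt = dt)
  say("phase ii: L1 association (%d presentations)",
      net$train$phase2_presentations)
  net <- train_phase2(net, dt = dt)
  ck <- list(untrained = net, weak = NULL, strong = NULL)
  hist <- data.frame(epoch = integer(), ratio = numeric())
  for (ep in seq_len(max_epochs)) {
    net <- train_phase3(net, epochs = 1, dt = dt)
    r <- l2_weight_ratio(net)
    hist <- rbind(hist, data.frame(epoch = ep, ratio = r))
    if (is.null(ck$weak) && r >= net$train$weak_ratio) {
      say("phase iii: weak checkpoint at epoch %d (ratio %.3f)", ep, r)
      ck$weak <- net
    }
    if (r >= net$train$strong_ratio) {
      say("phase iii: strong checkpoint at epoch %d (ratio %.3f)", ep, r)
      ck$strong <- net
      break
    }
  }
  if (is.null(ck$weak) || is.null(ck$strong))
    stop("phase iii did not reach the requested proficiency within ",
         max_epochs, " epochs")
  ck$history <- hist
  ck
}
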