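#' Simulate the full network
#'
#' Advances the feature maps, the lexical sheet, its interneurons and the
#' decision gate from rest (or a supplied state) under constant external
#' drives, by explicit Euler integration at step `dt`. Optionally applies
#' soft-bounded Hebbian updates to selected weight groups every
#' `sample_ms` of simulated time, returning the updated network.
#'
#' The model is fully deterministic: two calls with the same arguments
#' produce identical results.
#'
#' @param net a [bilex_network()].
#' @param feature_drive external drive per feature unit (default none),
#'   e.g. from [object_stimulus()].
#' @param word_drive external linguistic input per word (default none),
#'   e.g. from [word_input()].
#' @param bias_drive top-down inhibitory input per word (default none),
#'   e.g. from [bias_input()].
#' @param duration_ms simulated time.
#' @param dt Euler step (ms); must not exceed one tenth of the smallest
#'   time constant.
#' @param learn character vector of weight groups to train during this
#'   simulation: any of `"inter_area"`, `"feature_to_word"`,
#'   `"word_to_feature"`, `"competition"`.
#' @param record_ms sampling interval of the recorded traces.
#' @param record_features whether to record the full feature-map
#'   excitatory state at every sample (needed for bubble censuses and
#'   spectral metrics).
#' @param state optional initial state (list `x`, `y`, `xl`, `xi`,
#'   `xl_bg`, `xi_bg`) to continue a previous simulation.
#' @return an object of class `bilex_sim`: recorded traces, the gate
#'   opening time (`NA` if the gate never opened), the final state, and
#'   `network` -- the input network carrying the (possibly updated)
#'   weights.
#' @export
simulate_network <- function(net, feature_drive = NULL, word_drive = NULL,
                             bias_drive = NULL, duration_ms = 500,
                             dt = 0.05, learn = character(),
                             record_ms = 0.5, record_features = TRUE,
                             state = NULL) {
  geom <- net$geometry
  nf <- geom$n_units
  nw <- length(net$words)
  feature_drive <- feature_drive %||% numeric(nf)
  word_drive <- word_drive %||% numeric(nw)
  bias_drive <- bias_drive %||% numeric(nw)
  stopifnot(length(feature_drive) == nf, length(word_drive) == nw,
            length(bias_drive) == nw)
  if (any(!is.finite(c(feature_drive, word_drive, bias_drive))))
    stop("non-finite external drive")
  if (any(bias_drive < 0)) stop("bias input must be nonnegative")
  tau_min <- min(net$osc$tau_ex, net$osc$tau_inh, net$lex$tau, net$lex$tau_int)
  if (dt > tau_min / 10)
    stop("dt must be <= ", tau_min / 10, " ms (one tenth of the smallest ",
         "time constant)")
  bad <- setdiff(learn, c("inter_area", "feature_to_word",
                          "word_to_feature", "competition"))
  if (length(bad)) stop("unknown weight group(s): ", paste(bad, collapse = ", "))

  tr <- net$train
  lrn <- list(
    learn_inter_area = "inter_area" %in% learn,
    learn_feature_to_word = "feature_to_word" %in% learn,
    learn_word_to_feature = "word_to_feature" %in% learn,
    learn_competition = "competition" %in% learn,
    beta_inter_area = tr$beta_inter_area,
    beta_feature_to_word = tr$beta_feature_to_word,
    beta_word_to_feature = tr$beta_word_to_feature,
    beta_competition = tr$beta_competition,
    wmax_inter_area = tr$wmax_inter_area,
    wmax_feature_to_word = tr$wmax_feature_to_word,
    wmax_word_to_feature = tr$wmax_word_to_feature,
    wmax_competition = tr$wmax_competition,
    sample_ms = tr$sample_ms,
    activity_floor = tr$activity_floor
  )
  state <- state %||% list(x = numeric(nf), y = numeric(nf),
                           xl = numeric(nw), xi = numeric(nw),
                           xl_bg = 0, xi_bg = 0)
  lexpar <- unclass(net$lex)
  lexpar$feature_output_mode <-
    if (identical(net$feature_output, "mean_pair")) 1L else 0L

  raw <- .engine_simulate(
    geom = list(n_areas = geom$n_areas, side = geom$side, n_words = nw),
    osc = unclass(net$osc), lex = lexpar, dec = unclass(net$dec), lrn = lrn,
    lat = net$kernel,
    WA = net$weights$inter_area, WF = net$weights$feature_to_word,
    WL = net$weights$word_to_feature, WI = net$weights$competition,
    ext_feature = as.numeric(feature_drive),
    word_input = as.numeric(word_drive),
    word_bias = as.numeric(bias_drive),
    x0 = state$x, y0 = state$y, xl0 = state$xl, xi0 = state$xi,
    xlbg0 = state$xl_bg, xibg0 = state$xi_bg,
    dt = dt, duration_ms = duration_ms, record_ms = record_ms,
    record_features = record_features)

  net$weights <- list(inter_area = raw$WA, feature_to_word = raw$WF,
                      word_to_feature = raw$WL, competition = raw$WI)
  wl <- word_labels(net)
  colnames(raw$word_act) <- wl
  colnames(raw$word_int) <- wl

  structure(list(
    time_ms = raw$time_ms,
    feature_ex = raw$feature_ex,
    word_act = raw$word_act,
    word_int = raw$word_int,
    lex_background = raw$lex_background,
    gate = raw$gate,
    bubble_counts = raw$bubble_counts,
    gate_open_ms = if (raw$gate_open_ms < 0) NA_real_ else raw$gate_open_ms,
    dt = dt, record_ms = record_ms,
    final_state = list(x = raw$x_final, y = raw$y_final,
                       xl = raw$xl_final, xi = raw$xi_final,
                       xl_bg = raw$xl_background_final,
                       xi_bg = raw$xi_background_final),
    network = net
  ), class = "bilex_sim")
}

#' Extract one feature area from a recorded snapshot
#'
#' @param sim a `bilex_sim` from [simulate_network()].
#' @param area 1-based area index.
#' @param sample 1-based recorded-sample index (default: last).
#' @return a `side` x `side` activity matrix.
#' @export
feature_snapshot <- function(sim, area, sample = nrow(sim$feature_ex)) {
  geom <- sim$network$geometry
  M <- geom$side
  idx <- (area - 1) * M * M + seq_len(M * M)
  matrix(sim$feature_ex[sample, idx], M, M, byrow = TRUE)
}

#' Per-area sliding-window-maximum map at the end of a simulation
#'
#' Computes, for every unit of one area, the maximum activity over the
#' trailing `window_ms` of the recording; this is the map the decision
#' network effectively sees.
#'
#' @param sim a `bilex_sim`.
#' @param area 1-based area index.
#' @param window_ms trailing window (default: the decision window).
#' @return a `side` x `side` matrix.
#' @export
feature_window_max <- function(sim, area,
                               window_ms = sim$network$dec$window_ms) {
  geom <- sim$network$geometry
  M <- geom$side
  nrec <- nrow(sim$feature_ex)
  k <- max(1L, round(window_ms / sim$record_ms))
  rows <- seq(max(1L, nrec - k + 1L), nrec)
  idx <- (area - 1) * M * M + seq_len(M * M)
  vals <- apply(sim$feature_ex[rows, idx, drop = FALSE], 2, max)
  matrix(vals, M, M, byrow = TRUE)
}
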