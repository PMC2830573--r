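#' Run one recognition/production scenario
#'
#' Simulates the network from rest at a given proficiency checkpoint
#' under one of the reference stimuli -- the L2 word, the L1 word, or the
#' object's features -- optionally with a top-down bias suppressing all
#' words of one language, and derives the outcome metrics: per-area
#' bubble census, dominant frequency of the retrieved object
#' representation, per-word activity and its classification.
#'
#' Word activity is summarized as the mean, over the measurement window,
#' of a sliding-window maximum of the word trace (window = one decision
#' window, covering a gamma period), so that an oscillating word is rated
#' by the level its bursts reach. The measurement window runs from gate
#' opening (or stimulus onset + the gate persistence interval, if the
#' gate never opens) to the end of the simulation. Classification:
#' `active` above 0.5, `negligible` below 0.1, anything between is
#' reported as `indeterminate` -- a deliberate forbidden band.
#'
#' @param net a checkpoint network.
#' @param stimulus one of `"l1_word"`, `"l2_word"`, `"object"`.
#' @param bias language tag whose words receive the top-down inhibitory
#'   bias (`"none"` for no bias).
#' @param duration_ms simulated time.
#' @param dt Euler step (ms).
#' @param checkpoint optional label stored in the result.
#' @return an object of class `bilex_scenario`: the underlying
#'   `bilex_sim`, `n_bubbles` (per-area census at the end), `freq_hz`,
#'   `gate_open_ms` (`NA` if the gate never opened -- outcome
#'   "no-recognition"), `words` (data.frame label, mean_activity,
#'   classification), and `recognized`.
#' @export
run_scenario <- function(net, stimulus = c("l1_word", "l2_word", "object"),
                         bias = "none", duration_ms = 600, dt = 0.05,
                         checkpoint = net$phase) {
  stimulus <- match.arg(stimulus)
  fdrive <- NULL
  wdrive <- NULL
  if (stimulus == "object") {
    fdrive <- object_stimulus(net, 1)
  } else {
    wdrive <- word_input(net, if (stimulus == "l1_word") "L1" else "L2")
  }
  bdrive <- bias_input(net, bias)
  if (duration_ms < net$dec$persistence_ms + 200)
    stop("duration must be at least persistence + 200 ms")
  sim <- simulate_network(net, feature_drive = fdrive, word_drive = wdrive,
                          bias_drive = bdrive, duration_ms = duration_ms,
                          dt = dt)

  # bubble census on the trailing window-maximum maps
  counts <- vapply(seq_len(net$geometry$n_areas), function(a) {
    length(detect_bubbles(feature_window_max(sim, a),
                          net$dec$bubble_threshold))
  }, integer(1))

  obj <- object_activity_trace(sim)
  t0 <- if (!is.na(sim$gate_open_ms)) sim$gate_open_ms
        else net$dec$persistence_ms
  win <- sim$time_ms >= t0
  freq <- if (sum(counts) > 0 && sum(win) * sim$record_ms >= 100) {
    dominant_frequency(obj$trace[win], sim$record_ms)$freq_hz
  } else 0

  k <- max(1L, round(net$dec$window_ms / sim$record_ms))
  words <- do.call(rbind, lapply(seq_along(net$words), function(i) {
    wm <- sliding_window_max(sim$word_act[, i], k)
    m <- mean(wm[win])
    data.frame(label = net$words[[i]]$label,
               language = net$words[[i]]$language,
               mean_activity = m,
               classification = classify_activity(m),
               stringsAsFactors = FALSE)
  }))

  structure(list(sim = sim, checkpoint = checkpoint, stimulus = stimulus,
                 bias = bias, n_bubbles = counts, freq_hz = freq,
                 gate_open_ms = sim$gate_open_ms,
                 recognized = !is.na(sim$gate_open_ms),
                 words = words, measure_from_ms = t0),
            class = "bilex_scenario")
}

#' Classify a summarized word activity
#'
#' @param m mean windowed activity in `[0, 1]`.
#' @param active_above,negligible_below class boundaries; the band between
#'   them is reported as `"indeterminate"` rather than silently rounded
#'   to the nearer class.
#' @return `"active"`, `"negligible"` or `"indeterminate"`.
#' @export
classify_activity <- function(m, active_above = 0.5,
                              negligible_below = 0.1) {
  if (m > active_above) "active"
  else if (m < negligible_below) "negligible"
  else "indeterminate"
}

#' Run the full experiment grid
#'
#' Nine base scenarios (three stimuli x three proficiency checkpoints)
#' plus two word-production scenarios with a top-down bias on all L1
#' words, as a tidy outcome table.
#'
#' @param checkpoints list with networks `untrained`, `weak`, `strong`
#'   (from [train_curriculum()]).
#' @param duration_ms,dt simulation settings passed to [run_scenario()].
#' @param keep_scenarios if `TRUE`, attach the individual
#'   `bilex_scenario` objects as an attribute.
#' @return a data.frame with one row per scenario x word: `scenario_id`,
#'   `checkpoint`, `stimulus`, `bias`, `n_bubbles` (total across areas),
#'   `freq_hz`, `word`, `mean_activity`, `classification`.
#' @export
scenario_matrix <- function(checkpoints, duration_ms = 600, dt = 0.05,
                            keep_scenarios = FALSE) {
  need <- c("untrained", "weak", "strong")
  if (!all(need %in% names(checkpoints)) ||
      any(vapply(checkpoints[need], is.null, logical(1))))
    stop("checkpoints must contain networks 'untrained', 'weak', 'strong'")
  grid <- rbind(
    expand.grid(checkpoint = need,
                stimulus = c("l2_word", "l1_word", "object"),
                bias = "none", stringsAsFactors = FALSE),
    data.frame(checkpoint = c("weak", "strong"), stimulus = "object",
               bias = "L1", stringsAsFactors = FALSE))
  scens <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sc <- run_scenario(checkpoints[[g$checkpoint]], stimulus = g$stimulus,
                       bias = g$bias, duration_ms = duration_ms, dt = dt,
                       checkpoint = g$checkpoint)
    scens[[i]] <- sc
    rows[[i]] <- data.frame(
      scenario_id = sprintf("%s_%s%s", g$checkpoint, g$stimulus,
                            if (g$bias == "none") "" else "_biasL1"),
      checkpoint = g$checkpoint, stimulus = g$stimulus, bias = g$bias,
      n_bubbles = sum(sc$n_bubbles), freq_hz = sc$freq_hz,
      word = sc$words$label, mean_activity = sc$words$mean_activity,
      classification = sc$words$classification,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_scenarios) attr(out, "scenarios") <- scens
  out
}
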