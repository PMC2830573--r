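#' Detect activation bubbles in one feature map
#'
#' A bubble is a maximal 4-connected set of units whose activity is at or
#' above `threshold`. For oscillating maps pass a sliding-window maximum
#' of the raw activity (see [sliding_window_max()]); the raw activity of a
#' gamma bubble dips below threshold every cycle.
#'
#' @param grid activity matrix (rows x cols).
#' @param threshold detection threshold in (0, 1).
#' @return a list of bubbles, each with fields `members` (2-column matrix
#'   of 1-based row/col coordinates), `centroid`, and `peak`; an empty
#'   list if no unit is suprathreshold.
#' @export
detect_bubbles <- function(grid, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  out <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (grid[r0, c0] < threshold || lab[r0, c0] > 0L) next
    nlab <- nlab + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nlab
    members <- matrix(0L, 0, 2)
    while (length(stack) > 0) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members <- rbind(members, q)
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- q[1] + d[1]; cc <- q[2] + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (grid[rr, cc] >= threshold && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nlab
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    dimnames(members) <- NULL
    out[[nlab]] <- list(
      members = members,
      centroid = colMeans(members),
      peak = max(grid[members])
    )
  }
  out
}

#' Decision-gate state
#'
#' @param timer_ms elapsed continuous-validity time.
#' @param z binary gate output.
#' @return a list with fields `timer_ms` and `z`.
#' @export
decision_state <- function(timer_ms = 0, z = 0L) {
  list(timer_ms = timer_ms, z = as.integer(z))
}

#' Advance the decision gate by one evaluation interval
#'
#' The validity timer advances by `dt` if and only if every feature area
#' shows exactly one bubble; the gate opens (`z = 1`) once the timer
#' reaches `persistence_ms`. Any violation resets the timer and closes
#' the gate immediately.
#'
#' @param state a [decision_state()].
#' @param counts integer vector of per-area bubble counts.
#' @param dt evaluation interval (ms).
#' @param persistence_ms required continuous validity (ms).
#' @return the updated state.
#' @export
decision_update <- function(state, counts, dt, persistence_ms) {
  if (persistence_ms <= 0) stop("persistence_ms must be positive")
  if (all(counts == 1L)) {
    state$timer_ms <- state$timer_ms + dt
    if (state$timer_ms >= persistence_ms) state$z <- 1L
  } else {
    state$timer_ms <- 0
    state$z <- 0L
  }
  state
}

#' Sliding-window maximum of a time series
#'
#' Running maximum over the trailing `width` samples (shorter at the start
#' of the series). Used to make oscillating activity visible to the
#' bubble detector and to summarize oscillating word activity.
#'
#' @param x numeric vector.
#' @param width window length in samples (>= 1).
#' @return vector of the same length as `x`.
#' @export
sliding_window_max <- function(x, width) {
  width <- as.integer(width)
  if (width < 1) stop("width must be >= 1")
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- max(x[max(1L, i - width + 1L):i])
  out
}
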