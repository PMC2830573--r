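#' Mexican-hat lateral kernel profile
#'
#' Difference-of-Gaussians weight as a function of inter-unit grid
#' distance: short-range excitation minus broader inhibition. With
#' `exc_sigma < inh_sigma` and both amplitudes positive the profile is
#' positive near zero, crosses into inhibition at intermediate distance
#' and decays to zero at long range.
#'
#' @param d distance in grid units (vectorized).
#' @param exc_amp,exc_sigma amplitude and radius of the excitatory
#'   Gaussian.
#' @param inh_amp,inh_sigma amplitude and radius of the inhibitory
#'   Gaussian.
#' @return kernel weights, same length as `d`.
#' @export
lateral_kernel_profile <- function(d, exc_amp = 1.6, exc_sigma = 1,
                                   inh_amp = 0.5, inh_sigma = 3) {
  if (exc_sigma <= 0 || inh_sigma <= 0) stop("kernel radii must be positive")
  if (exc_amp < 0 || inh_amp < 0) stop("kernel amplitudes must be nonnegative")
  exc_amp * exp(-d^2 / (2 * exc_sigma^2)) -
    inh_amp * exp(-d^2 / (2 * inh_sigma^2))
}

#' Within-area lateral weight matrix
#'
#' Builds the full `side^2` x `side^2` within-area weight matrix from the
#' Mexican-hat profile. The kernel depends on Euclidean grid distance only
#' (translation invariant up to the hard, non-periodic boundary), is
#' truncated at `3 * inh_sigma`, and has no self-connection.
#'
#' @param geometry a [feature_geometry()] object.
#' @param exc_amp,exc_sigma,inh_amp,inh_sigma profile parameters, see
#'   [lateral_kernel_profile()].
#' @return a matrix `W` with `W[i, j]` the weight from unit `j` to unit
#'   `i` (row-major unit order within the area); `diag(W) == 0`.
#' @export
build_lateral_kernel <- function(geometry, exc_amp = 1.6, exc_sigma = 1,
                                 inh_amp = 0.5, inh_sigma = 3) {
  M <- geometry$side
  rc <- expand.grid(col = seq_len(M), row = seq_len(M))  # row-major order
  dr <- outer(rc$row, rc$row, "-")
  dc <- outer(rc$col, rc$col, "-")
  d <- sqrt(dr^2 + dc^2)
  W <- lateral_kernel_profile(d, exc_amp, exc_sigma, inh_amp, inh_sigma)
  W[d > 3 * inh_sigma] <- 0
  diag(W) <- 0
  W
}
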