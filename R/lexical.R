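#' Sigmoidal activation of lexical units
#'
#' Logistic function with central point `theta` (input at which output is
#' half maximal) and slope `p`; the maximum activity is 1.
#'
#' @param u net input (vectorized).
#' @param theta central point.
#' @param p slope at the central point; must be positive.
#' @return values in (0, 1).
#' @export
lexical_sigmoid <- function(u, theta, p) {
  if (p <= 0) stop("sigmoid slope must be positive")
  1 / (1 + exp(-(u - theta) * p))
}

#' Feature-to-word synaptic drive
#'
#' The drive each word unit receives from the feature network: the
#' weighted sum of oscillator activities through the learned
#' feature-to-word synapses.
#'
#' @param W_fw weight matrix, `n_words` x `n_feature_units`.
#' @param x feature activity vector.
#' @return drive per word unit.
#' @export
feature_drive <- function(W_fw, x) {
  if (ncol(W_fw) != length(x))
    stop("feature-to-word weight matrix does not match feature vector")
  as.numeric(W_fw %*% x)
}

#' Competitive inhibition between words
#'
#' The inhibition each word unit receives from the interneurons paired
#' with other words. A word's own interneuron never inhibits it: the
#' diagonal of `W_comp` must be zero.
#'
#' @param W_comp nonnegative weight matrix, `n_words` x `n_words`,
#'   `W_comp[i, j]` the synapse from word `j`'s interneuron onto word `i`.
#' @param x_int interneuron activity vector.
#' @return inhibition per word unit (nonnegative).
#' @export
competition_drive <- function(W_comp, x_int) {
  if (any(W_comp < 0)) stop("competitive weights must be nonnegative")
  if (any(diag(W_comp) != 0)) stop("self-competition entries must be zero")
  as.numeric(W_comp %*% x_int)
}

#' Net input to lexical units
#'
#' Signed sum of external linguistic input, feature drive, decision-gate
#' inhibition, learned competition and top-down bias:
#' `u = I_word + V_feat - G * (1 - z) - C - I_bias`.
#'
#' @param I_word external linguistic input per word.
#' @param V_feat feature drive per word (see [feature_drive()]).
#' @param z binary decision-gate output (0 closed, 1 open).
#' @param C competitive inhibition per word (see [competition_drive()]).
#' @param I_bias top-down inhibitory bias per word (nonnegative).
#' @param G gating inhibition strength.
#' @return net input per word.
#' @export
lexical_input <- function(I_word, V_feat, z, C, I_bias, G) {
  if (!(length(z) == 1 && z %in% c(0, 1))) stop("z must be 0 or 1")
  if (any(I_bias < 0)) stop("bias input must be nonnegative")
  I_word + V_feat - G * (1 - z) - C - I_bias
}

#' One Euler step of the lexical unit dynamics
#'
#' First-order relaxation of each word unit toward the sigmoid of its net
#' input: `tau * dx/dt = -x + H(u)`.
#'
#' @param x current word activities.
#' @param u net input per word (see [lexical_input()]).
#' @param params a [lexical_params()] object.
#' @param dt Euler step (ms); must satisfy `dt <= tau / 10`.
#' @return updated activities.
#' @export
step_lexical <- function(x, u, params, dt) {
  if (dt > params$tau / 10) stop("dt must be <= tau/10")
  if (any(!is.finite(u))) stop("non-finite lexical input")
  x + dt / params$tau * (-x + lexical_sigmoid(u, params$theta, params$slope))
}

#' One Euler step of the interneuron dynamics
#'
#' Each interneuron receives excitation only from the word unit at its own
#' sheet position: `tau_int * dx/dt = -x + H(x_word)`.
#'
#' @param x_int current interneuron activities.
#' @param x_word paired word-unit activities (sole input).
#' @param params a [lexical_params()] object.
#' @param dt Euler step (ms); must satisfy `dt <= tau_int / 10`.
#' @return updated interneuron activities.
#' @export
step_interneuron <- function(x_int, x_word, params, dt) {
  if (dt > params$tau_int / 10) stop("dt must be <= tau_int/10")
  if (any(!is.finite(x_word))) stop("non-finite interneuron input")
  x_int + dt / params$tau_int *
    (-x_int + lexical_sigmoid(x_word, params$theta_int, params$slope_int))
}
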