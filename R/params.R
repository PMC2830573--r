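#' Wilson-Cowan oscillator parameters
#'
#' Each unit of a feature map is a coupled excitatory/inhibitory pair with
#' first-order dynamics and a sigmoidal activation. The activation is a
#' logistic rescaled so that zero net input maps to exactly zero output
#' (silent rest) and the supremum is 1; activities therefore stay in
#' \eqn{[0,1]}. The default gains place the pair in a regime with a stable
#' silent rest state at zero input and a gamma-band limit cycle (period
#' 20--30 ms) under suprathreshold constant drive.
#'
#' @param tau_ex,tau_inh time constants of the excitatory and inhibitory
#'   sub-units (ms).
#' @param g_ee,g_ie,g_ei,g_ii coupling gains within one oscillator:
#'   excitatory self-excitation, inhibitory-to-excitatory, excitatory-to-
#'   inhibitory, inhibitory self-inhibition.
#' @param theta_ex,slope_ex,theta_inh,slope_inh sigmoid central points and
#'   slopes for the two sub-units.
#' @param rest_input constant external input applied to every excitatory
#'   sub-unit (default 0: true rest).
#' @param validate if `TRUE` (default), simulate a single oscillator at
#'   construction and require (a) silence at zero input and (b) a limit
#'   cycle with period in 20--30 ms at a suprathreshold reference drive.
#' @param ref_drive drive used for the limit-cycle check.
#'
#' @return an object of class `oscillator_params`.
#' @export
oscillator_params <- function(tau_ex = 2.6, tau_inh = 5.3,
                              g_ee = 20, g_ie = 32.5, g_ei = 25, g_ii = 0,
                              theta_ex = 2.5, slope_ex = 2,
                              theta_inh = 4, slope_inh = 2,
                              rest_input = 0,
                              validate = TRUE, ref_drive = 2) {
  if (tau_ex <= 0 || tau_inh <= 0)
    stop("oscillator time constants must be positive")
  if (slope_ex <= 0 || slope_inh <= 0)
    stop("sigmoid slopes must be positive")
  p <- structure(list(
    tau_ex = tau_ex, tau_inh = tau_inh,
    g_ee = g_ee, g_ie = g_ie, g_ei = g_ei, g_ii = g_ii,
    theta_ex = theta_ex, slope_ex = slope_ex,
    theta_inh = theta_inh, slope_inh = slope_inh,
    rest_input = rest_input
  ), class = "oscillator_params")
  if (validate) {
    chk <- check_gamma_regime(p, ref_drive = ref_drive)
    if (!chk$rest_silent)
      stop("oscillator parameters do not admit a silent rest state ",
           "(max rest activity ", signif(chk$rest_max, 3), ")")
    if (!chk$gamma)
      stop("oscillator parameters do not produce a gamma limit cycle at ",
           "drive ", ref_drive, " (period ", signif(chk$period_ms, 4), " ms)")
  }
  p
}

#' Verify the dynamical regime of an oscillator parameter set
#'
#' Simulates one free-running oscillator and reports whether the rest state
#' is silent at zero input and whether a suprathreshold constant drive
#' produces a limit cycle with period in the gamma range (20--30 ms).
#'
#' @param params an [oscillator_params()] object (or plain list with the
#'   same fields).
#' @param ref_drive suprathreshold drive for the limit-cycle test.
#' @param dt Euler step (ms).
#' @return a list with fields `rest_silent`, `rest_max`, `gamma`,
#'   `period_ms`, `freq_hz`, `amplitude`.
#' @export
check_gamma_regime <- function(params, ref_drive = 2, dt = 0.05) {
  rest <- .engine_single_oscillator(params, 0, 1000, dt)
  rest_max <- max(rest[, "x"])
  drv <- .engine_single_oscillator(params, ref_drive, 600, dt)
  xs <- drv[drv[, "time_ms"] > 150, "x"]
  amp <- max(xs) - min(xs)
  freq <- if (amp > 0.2) {
    est <- dominant_frequency(xs, dt)
    est$freq_hz
  } else 0
  period <- if (freq > 0) 1000 / freq else Inf
  list(rest_silent = rest_max < 0.01, rest_max = rest_max,
       gamma = is.finite(period) && period >= 20 && period <= 30,
       period_ms = period, freq_hz = freq, amplitude = amp)
}

#' Lexical-area parameters
#'
#' Word units are first-order sigmoidal units on an `m1` x `m2` sheet, each
#' paired with one inhibitory interneuron that receives input only from its
#' own word unit. The decision gate subtracts `gate_strength` from every
#' word unit while closed. The interneuron time constant defaults to five
#' lexical time constants so that competition integrates over gamma cycles
#' instead of chopping them.
#'
#' @param tau time constant of word units (ms).
#' @param theta,slope sigmoid central point and slope of word units.
#' @param gate_strength inhibition applied while the decision gate is
#'   closed; must be large enough that feature drive alone cannot activate
#'   any word while the gate is closed.
#' @param tau_int,theta_int,slope_int interneuron counterparts.
#' @param m1,m2 sheet dimensions.
#' @return an object of class `lexical_params`.
#' @export
lexical_params <- function(tau = 2, theta = 2.5, slope = 2,
                           gate_strength = 16,
                           tau_int = 5 * tau, theta_int = 0.5,
                           slope_int = 6,
                           m1 = 40, m2 = 40) {
  if (tau <= 0 || tau_int <= 0) stop("lexical time constants must be positive")
  if (slope <= 0 || slope_int <= 0) stop("sigmoid slopes must be positive")
  if (gate_strength < 0) stop("gate_strength must be nonnegative")
  structure(list(tau = tau, theta = theta, slope = slope,
                 gate_strength = gate_strength,
                 tau_int = tau_int, theta_int = theta_int,
                 slope_int = slope_int, m1 = m1, m2 = m2),
            class = "lexical_params")
}

#' Decision-gate parameters
#'
#' The decision network opens the gate (`z = 1`) only when every feature
#' area contains exactly one activation bubble continuously for
#' `persistence_ms`. Because a gamma-oscillating bubble dips below
#' threshold every cycle, bubble detection operates on a sliding-window
#' maximum of each unit's activity; the window must cover at least one
#' gamma period.
#'
#' @param bubble_threshold activity level above which a unit belongs to a
#'   bubble; in (0,1).
#' @param window_ms sliding-maximum window (ms).
#' @param persistence_ms continuous validity required before the gate
#'   opens (ms).
#' @param eval_ms interval between gate evaluations (ms).
#' @return an object of class `decision_params`.
#' @export
decision_params <- function(bubble_threshold = 0.5, window_ms = 30,
                            persistence_ms = 75, eval_ms = 1) {
  if (bubble_threshold <= 0 || bubble_threshold >= 1)
    stop("bubble_threshold must be in (0,1)")
  if (persistence_ms <= 0) stop("persistence_ms must be positive")
  if (window_ms <= 0 || eval_ms <= 0) stop("window and eval must be positive")
  structure(list(bubble_threshold = bubble_threshold, window_ms = window_ms,
                 persistence_ms = persistence_ms, eval_ms = eval_ms),
            class = "decision_params")
}

#' Hebbian training parameters
#'
#' All four trainable weight groups use the same soft-bounded Hebbian rule
#' applied every `sample_ms` of simulated co-activity: the increment is
#' `beta * (1 - W/wmax) * post * pre`, so the effective learning rate
#' tapers to zero as a weight approaches its ceiling `wmax`.
#'
#' @param beta_inter_area,beta_feature_to_word,beta_word_to_feature,beta_competition
#'   learning rates of the four weight groups.
#' @param wmax_inter_area,wmax_feature_to_word,wmax_word_to_feature,wmax_competition
#'   saturation ceilings.
#' @param sample_ms interval between Hebbian updates (ms).
#' @param activity_floor activities below this level do not drive
#'   learning, so pairs that are never co-active above the floor keep
#'   exactly zero weight despite the lexical sigmoid's nonzero baseline.
#' @param presentation_ms duration of one stimulus presentation (ms).
#' @param phase1_presentations,phase2_presentations number of presentations
#'   in the object-learning and L1-association phases.
#' @param weak_ratio,strong_ratio trained-to-L1 weight-norm ratios defining
#'   the weak and strong L2 proficiency checkpoints.
#' @return an object of class `training_params`.
#' @export
training_params <- function(beta_inter_area = 0.012,
                            beta_feature_to_word = 0.0028,
                            beta_word_to_feature = 0.046,
                            beta_competition = 0.105,
                            wmax_inter_area = 0.32,
                            wmax_feature_to_word = 0.4,
                            wmax_word_to_feature = 5,
                            wmax_competition = 16,
                            sample_ms = 5,
                            activity_floor = 0.05,
                            presentation_ms = 350,
                            phase1_presentations = 8,
                            phase2_presentations = 12,
                            weak_ratio = 0.3, strong_ratio = 0.9) {
  betas <- c(beta_inter_area, beta_feature_to_word, beta_word_to_feature,
             beta_competition)
  if (any(betas < 0)) stop("learning rates must be nonnegative")
  wmaxs <- c(wmax_inter_area, wmax_feature_to_word, wmax_word_to_feature,
             wmax_competition)
  if (any(wmaxs <= 0)) stop("saturation ceilings must be positive")
  if (sample_ms <= 0) stop("sample_ms must be positive")
  if (activity_floor < 0 || activity_floor >= 1)
    stop("activity_floor must be in [0, 1)")
  if (!(weak_ratio > 0 && weak_ratio < strong_ratio && strong_ratio <= 1))
    stop("need 0 < weak_ratio < strong_ratio <= 1")
  structure(list(
    beta_inter_area = beta_inter_area,
    beta_feature_to_word = beta_feature_to_word,
    beta_word_to_feature = beta_word_to_feature,
    beta_competition = beta_competition,
    wmax_inter_area = wmax_inter_area,
    wmax_feature_to_word = wmax_feature_to_word,
    wmax_word_to_feature = wmax_word_to_feature,
    wmax_competition = wmax_competition,
    sample_ms = sample_ms, activity_floor = activity_floor,
    presentation_ms = presentation_ms,
    phase1_presentations = phase1_presentations,
    phase2_presentations = phase2_presentations,
    weak_ratio = weak_ratio, strong_ratio = strong_ratio
  ), class = "training_params")
}
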