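#' Construct a bilingual lexical-semantic network
#'
#' Bundles geometry, parameters, fixed lateral connectivity, object and
#' word specifications, and the four trainable synapse groups (all zero at
#' construction): inter-area feature synapses (object memory),
#' feature-to-word, word-to-feature, and interneuron-to-word competition.
#'
#' @param fixture a fixture set from [generate_fixture()], or `NULL` to
#'   assemble from the remaining arguments.
#' @param geometry a [feature_geometry()].
#' @param objects list of [object_spec()]s.
#' @param words list of [word_spec()]s; distinct words must occupy
#'   distinct lexical coordinates.
#' @param osc,lex,dec,train parameter objects (defaults used if `NULL`).
#' @param kernel_params named list overriding [build_lateral_kernel()]
#'   arguments.
#' @param feature_output which oscillator signal the lexical layer reads:
#'   the excitatory sub-unit (default) or the mean of both sub-units.
#' @return an object of class `bilex_network`.
#' @export
bilex_network <- function(fixture = NULL, geometry = NULL, objects = NULL,
                          words = NULL, osc = NULL, lex = NULL, dec = NULL,
                          train = NULL, kernel_params = list(),
                          feature_output = c("excitatory", "mean_pair")) {
  feature_output <- match.arg(feature_output)
  if (!is.null(fixture)) {
    geometry <- fixture$geometry
    objects <- fixture$objects
    words <- fixture$words
    lex <- lex %||% do.call(lexical_params, fixture$lexical %||% list())
    train <- train %||% do.call(training_params, fixture$training %||% list())
    kernel_params <- fixture$kernel %||% kernel_params
  }
  if (is.null(geometry)) stop("geometry is required")
  osc <- osc %||% oscillator_params()
  lex <- lex %||% lexical_params()
  dec <- dec %||% decision_params()
  train <- train %||% training_params()

  validate_objects(objects, geometry)
  validate_words(words, lex)

  nf <- geometry$n_units
  nw <- length(words)
  kernel <- do.call(build_lateral_kernel, c(list(geometry), kernel_params))

  net <- structure(list(
    geometry = geometry, objects = objects, words = words,
    osc = osc, lex = lex, dec = dec, train = train,
    kernel = kernel, kernel_params = kernel_params,
    feature_output = feature_output,
    weights = list(
      inter_area = matrix(0, nf, nf),
      feature_to_word = matrix(0, nw, nf),
      word_to_feature = matrix(0, nf, nw),
      competition = matrix(0, nw, nw)
    ),
    phase = "untrained"
  ), class = "bilex_network")
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_objects <- function(objects, geometry) {
  for (ob in objects) {
    if (length(ob$coords) != geometry$n_areas)
      stop("object '", ob$label, "' needs one feature per area")
    for (p in ob$coords)
      if (any(p < 1) || any(p > geometry$side))
        stop("object '", ob$label, "' has a feature outside the grid")
  }
  invisible(TRUE)
}

validate_words <- function(words, lex) {
  seen <- character()
  for (w in words) {
    if (any(w$coord < 1) || w$coord[1] > lex$m1 || w$coord[2] > lex$m2)
      stop("word '", w$label, "' is outside the lexical sheet")
    key <- paste(w$coord, collapse = ",")
    if (key %in% seen)
      stop("two words occupy lexical coordinate (", key, ")")
    seen <- c(seen, key)
  }
  invisible(TRUE)
}

word_labels <- function(net) vapply(net$words, `[[`, "", "label")

word_index <- function(net, label) {
  i <- match(label, word_labels(net))
  if (is.na(i)) stop("unknown word '", label, "'")
  i
}

#' External drive implementing an object stimulus
#'
#' Concentrates drive on the object's feature coordinates, optionally with
#' a small Gaussian neighborhood (truncated at three spreads).
#'
#' @param net a [bilex_network()].
#' @param object an [object_spec()] or the label of one of the network's
#'   objects.
#' @param amplitude peak drive per feature.
#' @param spread Gaussian spatial spread in grid units (0 = single unit).
#' @param areas which areas receive their feature (default all); use a
#'   subset for partial-cue experiments.
#' @return drive vector over all feature units.
#' @export
object_stimulus <- function(net, object = 1, amplitude = 3, spread = 1,
                            areas = NULL) {
  if (is.character(object)) {
    i <- match(object, vapply(net$objects, `[[`, "", "label"))
    if (is.na(i)) stop("unknown object '", object, "'")
    object <- net$objects[[i]]
  } else if (is.numeric(object)) object <- net$objects[[object]]
  geom <- net$geometry
  M <- geom$side
  areas <- areas %||% seq_len(geom$n_areas)
  drive <- numeric(geom$n_units)
  for (a in areas) {
    p <- object$coords[[a]]
    if (spread <= 0) {
      drive[feature_index(geom, a, p[1], p[2])] <- amplitude
    } else {
      for (r in seq_len(M)) for (cc in seq_len(M)) {
        d2 <- (r - p[1])^2 + (cc - p[2])^2
        if (d2 <= (3 * spread)^2) {
          g <- feature_index(geom, a, r, cc)
          drive[g] <- drive[g] + amplitude * exp(-d2 / (2 * spread^2))
        }
      }
    }
  }
  drive
}

#' External linguistic input for a word
#'
#' The input is set high enough to overcome the gating inhibition that
#' reaches the lexical sheet while the decision gate is closed:
#' `gate_strength + theta + 5/slope` at the stimulated word, zero
#' elsewhere.
#'
#' @param net a [bilex_network()].
#' @param label word label to stimulate (or several).
#' @param amplitude drive at the stimulated word; default as above.
#' @return drive vector over the network's words.
#' @export
word_input <- function(net, label, amplitude = NULL) {
  lx <- net$lex
  amplitude <- amplitude %||% (lx$gate_strength + lx$theta + 5 / lx$slope)
  drive <- numeric(length(net$words))
  for (lb in label) drive[word_index(net, lb)] <- amplitude
  drive
}

#' Top-down inhibitory bias targeting one language
#'
#' Applies a nonnegative inhibitory input (same magnitude as the gating
#' inhibition by default) to every word of the given language, emulating a
#' higher control center suppressing the non-target language.
#'
#' @param net a [bilex_network()].
#' @param language language tag whose words are suppressed, or `"none"`.
#' @param amplitude bias strength.
#' @return bias vector over the network's words.
#' @export
bias_input <- function(net, language = "none",
                       amplitude = net$lex$gate_strength) {
  drive <- numeric(length(net$words))
  if (identical(language, "none")) return(drive)
  tags <- vapply(net$words, `[[`, "", "language")
  hit <- tags == language
  if (!any(hit)) stop("no words with language tag '", language, "'")
  drive[hit] <- amplitude
  drive
}
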