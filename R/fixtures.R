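#' Generate a complete fixture set
#'
#' A fixture set defines everything needed to build and train a network:
#' geometry, lexical sheet dimensions, objects, words, kernel parameters
#' and the training schedule. Two profiles are built in:
#'
#' * `"paper2010"` -- the reference configuration: 4 feature areas of
#'   20 x 20 oscillators, a 40 x 40 lexical sheet, one object with its
#'   feature at position (10, 10) of every area, an L1 word at lexical
#'   position (5, 5) and an L2 word at (20, 30).
#' * `"mini"` -- a scaled-down configuration for fast tests: 2 areas of
#'   8 x 8 oscillators, a 12 x 12 sheet, features at (4, 4), words at
#'   (2, 2) and (9, 10).
#'
#' @param profile profile name.
#' @param overrides named list of fields to replace after profile
#'   construction; the result is re-validated, and an override that breaks
#'   an invariant is rejected with the offending field named.
#' @return an object of class `bilex_fixture`.
#' @export
generate_fixture <- function(profile = c("paper2010", "mini"),
                             overrides = list()) {
  profile <- match.arg(profile)
  fx <- switch(profile,
    paper2010 = list(
      profile = "paper2010",
      geometry = feature_geometry(n_areas = 4, side = 20),
      lexical = list(m1 = 40, m2 = 40),
      objects = list(object_spec(
        coords = rep(list(c(10L, 10L)), 4), label = "object")),
      words = list(word_spec("L1", c(5, 5), language = "L1"),
                   word_spec("L2", c(20, 30), language = "L2")),
      kernel = list(),
      training = list(),
      stimulus = list(amplitude = 3, spread = 1),
      scenario = list(duration_ms = 600, dt = 0.05)
    ),
    mini = list(
      profile = "mini",
      geometry = feature_geometry(n_areas = 2, side = 8),
      lexical = list(m1 = 12, m2 = 12),
      objects = list(object_spec(
        coords = rep(list(c(4L, 4L)), 2), label = "object")),
      words = list(word_spec("L1", c(2, 2), language = "L1"),
                   word_spec("L2", c(9, 10), language = "L2")),
      kernel = list(),
      training = list(phase1_presentations = 6, phase2_presentations = 8,
                      presentation_ms = 300,
                      wmax_inter_area = 0.5,
                      beta_inter_area = 0.019,
                      wmax_feature_to_word = 1.15,
                      beta_feature_to_word = 0.019,
                      beta_word_to_feature = 0.12),
      stimulus = list(amplitude = 3, spread = 1),
      scenario = list(duration_ms = 500, dt = 0.05)
    ))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(fx))
    if (length(bad))
      stop("unknown fixture field(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) fx[[nm]] <- overrides[[nm]]
  }
  fx <- structure(fx, class = "bilex_fixture")
  validate_fixture(fx)
  fx
}

validate_fixture <- function(fx) {
  if (!inherits(fx$geometry, "feature_geometry"))
    fx$geometry <- do.call(feature_geometry, fx$geometry)
  lexp <- do.call(lexical_params, fx$lexical)
  validate_objects(fx$objects, fx$geometry)
  validate_words(fx$words, lexp)
  for (ob in fx$objects) for (p in ob$coords)
    if (any(p < 3) || any(p > fx$geometry$side - 2))
      stop("fixture field 'objects': feature at (", paste(p, collapse = ","),
           ") is closer than 3 units to the area boundary")
  invisible(TRUE)
}

#' Write a fixture set to a YAML config file
#'
#' @param fx a fixture from [generate_fixture()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fx, path) {
  ser <- list(
    profile = fx$profile,
    geometry = list(n_areas = fx$geometry$n_areas, side = fx$geometry$side),
    lexical = fx$lexical,
    objects = lapply(fx$objects, function(ob)
      list(label = ob$label, coords = lapply(ob$coords, as.integer))),
    words = lapply(fx$words, function(w)
      list(label = w$label, coord = as.integer(w$coord),
           language = w$language)),
    kernel = fx$kernel,
    training = fx$training,
    stimulus = fx$stimulus,
    scenario = fx$scenario
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a fixture set from a YAML config file
#'
#' @param path file written by [write_fixture()].
#' @return a validated `bilex_fixture`.
#' @export
read_fixture <- function(path) {
  raw <- yaml::read_yaml(path)
  fx <- structure(list(
    profile = raw$profile,
    geometry = feature_geometry(raw$geometry$n_areas, raw$geometry$side),
    lexical = lapply(raw$lexical, identity),
    objects = lapply(raw$objects, function(ob)
      object_spec(coords = ob$coords, label = ob$label)),
    words = lapply(raw$words, function(w)
      word_spec(w$label, w$coord, language = w$language)),
    kernel = raw$kernel %||% list(),
    training = raw$training %||% list(),
    stimulus = raw$stimulus,
    scenario = raw$scenario
  ), class = "bilex_fixture")
  validate_fixture(fx)
  fx
}
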