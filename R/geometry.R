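#' Feature-network geometry
#'
#' The feature network consists of `n_areas` square topographic maps, each
#' `side` x `side` Wilson-Cowan oscillators. One object is represented by
#' one feature (one map position) per area.
#'
#' @param n_areas number of feature areas (>= 1).
#' @param side units per side of each square area (>= 3).
#' @return an object of class `feature_geometry` with fields `n_areas`,
#'   `side` and `n_units` (total oscillator count).
#' @export
feature_geometry <- function(n_areas = 4, side = 20) {
  if (n_areas < 1) stop("n_areas must be >= 1")
  if (side < 3) stop("side must be >= 3")
  structure(list(n_areas = as.integer(n_areas), side = as.integer(side),
                 n_units = as.integer(n_areas * side * side)),
            class = "feature_geometry")
}

# 1-based (area, row, col) -> 1-based global feature index
feature_index <- function(geometry, area, row, col) {
  M <- geometry$side
  stopifnot(area >= 1, area <= geometry$n_areas,
            row >= 1, row <= M, col >= 1, col <= M)
  (area - 1L) * M * M + (row - 1L) * M + col
}

# 1-based (row, col) -> 1-based lexical sheet index (row-major)
lexical_index <- function(m1, m2, row, col) {
  stopifnot(row >= 1, row <= m1, col >= 1, col <= m2)
  (row - 1L) * m2 + col
}

#' Object specification
#'
#' One feature coordinate (1-based row, col) per feature area.
#'
#' @param coords a list with one `c(row, col)` pair per area, or a 2-column
#'   matrix with one row per area.
#' @param label object name.
#' @return an object of class `object_spec`.
#' @export
object_spec <- function(coords, label = "object") {
  if (is.matrix(coords))
    coords <- lapply(seq_len(nrow(coords)), function(i) coords[i, ])
  coords <- lapply(coords, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L) stop("each feature coordinate must be (row, col)")
    p
  })
  structure(list(label = label, coords = coords), class = "object_spec")
}

#' Word specification
#'
#' @param label word label, e.g. `"L1"` or `"L2"`.
#' @param coord 1-based `c(row, col)` position on the lexical sheet.
#' @param language language tag, e.g. `"L1"`.
#' @return an object of class `word_spec`.
#' @export
word_spec <- function(label, coord, language = label) {
  coord <- as.integer(coord)
  if (length(coord) != 2L) stop("word coordinate must be (row, col)")
  structure(list(label = label, coord = coord, language = language),
            class = "word_spec")
}
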