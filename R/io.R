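#' Export probe-unit activity traces to CSV
#'
#' Long format, one row per sample and probe unit: `time_ms, area, row,
#' col, activity`.
#'
#' @param sim a `bilex_sim` with recorded features.
#' @param probes 3-column matrix (area, row, col), 1-based.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_trace_csv <- function(sim, probes, path) {
  geom <- sim$network$geometry
  probes <- matrix(as.integer(probes), ncol = 3)
  rows <- lapply(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    g <- feature_index(geom, p[1], p[2], p[3])
    data.frame(time_ms = sim$time_ms, area = p[1], row = p[2], col = p[3],
               activity = sim$feature_ex[, g])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export word and interneuron traces to CSV
#'
#' One row per sample and word: `time_ms, word_label, x_word, x_int`.
#'
#' @param sim a `bilex_sim`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_word_trace_csv <- function(sim, path) {
  wl <- colnames(sim$word_act)
  rows <- lapply(seq_along(wl), function(i)
    data.frame(time_ms = sim$time_ms, word_label = wl[i],
               x_word = sim$word_act[, i], x_int = sim$word_int[, i]))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export the decision-gate trace to CSV
#'
#' One row per sample: `time_ms, z, count_area1..count_areaF`.
#'
#' @param sim a `bilex_sim`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gate_trace_csv <- function(sim, path) {
  cc <- sim$bubble_counts
  colnames(cc) <- paste0("count_area", seq_len(ncol(cc)))
  write.csv(data.frame(time_ms = sim$time_ms, z = sim$gate, cc),
            path, row.names = FALSE)
  invisible(path)
}

#' Dump all trainable weight groups to plain-text files
#'
#' Writes each group as a dense CSV (`<group>.csv`) plus a `manifest.csv`
#' recording the phase, the L2-to-L1 weight ratio and the matrix shapes.
#'
#' @param net a [bilex_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_weights <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(net$weights))
    write.csv(net$weights[[g]], file.path(dir, paste0(g, ".csv")),
              row.names = FALSE)
  shapes <- vapply(net$weights, function(W)
    paste(dim(W), collapse = "x"), "")
  write.csv(data.frame(group = names(net$weights), shape = shapes,
                       phase = net$phase,
                       l2_ratio = tryCatch(l2_weight_ratio(net),
                                           error = function(e) NA_real_)),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
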