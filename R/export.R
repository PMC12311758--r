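#' Export a criticality profile as long-format CSV
#'
#' One row per channel x wavelet frequency with the subject/visit keys
#' prepended, matching the layout the cohort statistics layer joins on.
#'
#' @param profile a [criticality_profile()] tibble.
#' @param path output CSV path.
#' @param subject_id,visit identifiers prepended to every row.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, subject_id = "S001",
                          visit = "baseline") {
  out <- dplyr::mutate(profile, subject_id = subject_id, visit = visit,
                       .before = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export band synchrony graphs as edge-list and nodal CSVs
#'
#' Writes `<stem>_edges.csv` (subject, visit, band, ch_a, ch_b, wpli) and
#' `<stem>_nodes.csv` (subject, visit, band, channel, strength, clustering,
#' eigencentrality).
#'
#' @param graphs result of [band_graphs()].
#' @param stem output path stem (without extension).
#' @param subject_id,visit identifiers prepended to every row.
#' @return the two paths, invisibly.
#' @export
write_graphs <- function(graphs, stem, subject_id = "S001",
                         visit = "baseline") {
  edges <- dplyr::bind_rows(lapply(names(graphs), function(b) {
    W <- graphs[[b]]$wpli
    idx <- which(upper.tri(W), arr.ind = TRUE)
    tibble::tibble(subject_id = subject_id, visit = visit, band = b,
                   ch_a = rownames(W)[idx[, 1]], ch_b = colnames(W)[idx[, 2]],
                   wpli = W[idx])
  }))
  nodes <- dplyr::mutate(nodal_table(graphs), subject_id = subject_id,
                         visit = visit, .before = 1)
  pe <- paste0(stem, "_edges.csv"); pn <- paste0(stem, "_nodes.csv")
  utils::write.csv(edges, pe, row.names = FALSE)
  utils::write.csv(nodes, pn, row.names = FALSE)
  invisible(c(pe, pn))
}
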