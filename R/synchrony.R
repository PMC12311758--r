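#' Weighted phase lag index between two channels
#'
#' With cross-spectrum `X_t = c_a(t) * Conj(c_b(t))` over jointly valid
#' samples, `wPLI = |mean(Im X_t)| / mean(|Im X_t|)`. The index lies in
#' \[0, 1\], is insensitive to zero-lag (volume-conduction) coupling, and is
#' returned as missing when the denominator vanishes (identical or exactly
#' zero-lag signals) or when fewer than `min_samples` valid samples exist.
#'
#' @param decomp an [nb_transform()] decomposition.
#' @param ch_a,ch_b channel indices or labels.
#' @param freq_index index into `decomp$freqs`.
#' @param min_samples minimum number of valid joint samples (default 100).
#' @return scalar in \[0, 1\], or NA with attribute `"reason"` set to
#'   `"zero_denominator"` or `"insufficient_samples"`.
#' @export
wpli <- function(decomp, ch_a, ch_b, freq_index, min_samples = 100L) {
  stopifnot(inherits(decomp, "nb_decomposition"))
  if (is.character(ch_a)) ch_a <- match(ch_a, decomp$labels)
  if (is.character(ch_b)) ch_b <- match(ch_b, decomp$labels)
  v <- decomp$valid[freq_index, ]
  ca <- decomp$coeffs[ch_a, freq_index, v]
  cb <- decomp$coeffs[ch_b, freq_index, v]
  if (length(ca) < min_samples) {
    return(structure(NA_real_, reason = "insufficient_samples"))
  }
  imx <- Im(ca * Conj(cb))
  den <- mean(abs(imx))
  scale_ref <- mean(Mod(ca) * Mod(cb))
  if (den == 0 || den < 1e-10 * scale_ref) {
    return(structure(NA_real_, reason = "zero_denominator"))
  }
  abs(mean(imx)) / den
}

#' Full wPLI matrix at one wavelet frequency
#'
#' @inheritParams wpli
#' @return symmetric channels x channels matrix with NA diagonal; off-
#'   diagonal NAs mark undefined (zero-denominator) pairs.
#' @export
wpli_matrix <- function(decomp, freq_index, min_samples = 100L) {
  n_ch <- dim(decomp$coeffs)[1]
  v <- decomp$valid[freq_index, ]
  C <- decomp$coeffs[, freq_index, v, drop = FALSE]
  dim(C) <- c(n_ch, sum(v))
  W <- matrix(NA_real_, n_ch, n_ch, dimnames = list(decomp$labels, decomp$labels))
  if (ncol(C) < min_samples) return(W)
  for (a in seq_len(n_ch - 1L)) {
    for (b in (a + 1L):n_ch) {
      imx <- Im(C[a, ] * Conj(C[b, ]))
      den <- mean(abs(imx))
      scale_ref <- mean(Mod(C[a, ]) * Mod(C[b, ]))
      w <- if (den == 0 || den < 1e-10 * scale_ref) NA_real_ else abs(mean(imx)) / den
      W[a, b] <- W[b, a] <- w
    }
  }
  W
}

#' Nodal graph measures of a synchrony matrix
#'
#' From a symmetric nonnegative weight matrix computes, per node: strength
#' (sum of incident weights), the Onnela weighted local clustering
#' coefficient (geometric-mean triangle intensity over realized neighbor
#' triplets, with weights normalized by the matrix maximum), and eigenvector
#' centrality (principal eigenvector by power iteration, normalized to unit
#' maximum; nonnegative by Perron-Frobenius). Missing entries are treated as
#' 0 and their count reported.
#'
#' @param W symmetric channels x channels weight matrix (NAs allowed).
#' @param clustering_variant `"onnela"` (default) or `"barrat"`.
#' @param tol power-iteration convergence tolerance (default 1e-10).
#' @return object of class `synchrony_graph`: list with the zero-filled
#'   matrix `wpli`, tibble `nodes` (`channel`, `strength`, `clustering`,
#'   `eigencentrality`), and `n_missing`.
#' @export
nodal_metrics <- function(W, clustering_variant = c("onnela", "barrat"),
                          tol = 1e-10) {
  clustering_variant <- match.arg(clustering_variant)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(W)))
  diag(W) <- 0
  n_missing <- sum(is.na(W)) / 2
  W[is.na(W)] <- 0
  if (any(W < 0)) stop("synchrony weights must be nonnegative")
  n <- nrow(W)

  strength <- rowSums(W)
  deg <- rowSums(W > 0)

  if (max(W) == 0) {
    nodes <- tibble::tibble(channel = labels, strength = 0, clustering = 0,
                            eigencentrality = NA_real_)
    return(structure(list(wpli = W, nodes = nodes, n_missing = n_missing),
                     class = "synchrony_graph"))
  }

  if (clustering_variant == "onnela") {
    A <- (W / max(W))^(1 / 3)
    cyc <- diag(A %*% A %*% A)           # 2x triangle intensity per node
    clustering <- ifelse(deg > 1, cyc / (deg * (deg - 1)), 0)
  } else {
    B <- (W > 0) + 0
    num <- diag((W %*% B %*% B + B %*% W %*% B + B %*% B %*% W)) / 2
    clustering <- ifelse(deg > 1 & strength > 0,
                         num / (strength * (deg - 1)), 0)
  }

  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(10000L)) {
    v_new <- W %*% v
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) { v <- rep(NA_real_, n); break }
    v_new <- as.numeric(v_new) / nv
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  eig <- abs(v)
  if (all(is.finite(eig)) && max(eig) > 0) eig <- eig / max(eig)

  nodes <- tibble::tibble(channel = labels, strength = strength,
                          clustering = clustering, eigencentrality = eig)
  structure(list(wpli = W, nodes = nodes, n_missing = n_missing),
            class = "synchrony_graph")
}

#' @export
print.synchrony_graph <- function(x, ...) {
  cat(sprintf("<synchrony_graph> %d nodes, mean weight %.3f (%d missing pair(s) zero-filled)\n",
              nrow(x$wpli), mean(x$wpli[upper.tri(x$wpli)]), x$n_missing))
  invisible(x)
}

#' @rdname nodal_metrics
#' @param x a `synchrony_graph`.
#' @param ... unused.
#' @export
tidy.synchrony_graph <- function(x, ...) x$nodes

#' Plot a synchrony graph as a weight-matrix heatmap
#'
#' @param object a `synchrony_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.synchrony_graph <- function(object, ...) {
  W <- object$wpli
  df <- tidyr::expand_grid(a = rownames(W), b = colnames(W))
  df$wpli <- as.vector(t(W))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$wpli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "wPLI") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Band-aggregated synchrony graphs
#'
#' Averages the per-frequency wPLI matrices over the wavelet frequencies
#' inside each canonical band (matrix-first aggregation), then computes the
#' nodal measures on the band-average matrix. Bank frequencies falling in
#' no band are excluded.
#'
#' @param decomp an [nb_transform()] decomposition.
#' @param bands band table as from [canonical_bands()].
#' @param ... passed to [nodal_metrics()].
#' @return named list of `synchrony_graph`, one per band.
#' @export
band_graphs <- function(decomp, bands = canonical_bands(), ...) {
  assignment <- band_of(decomp$freqs, bands)
  out <- list()
  for (b in levels(bands$band)) {
    idx <- which(!is.na(assignment) & assignment == b)
    if (length(idx) == 0L) {
      stop(sprintf("no wavelet frequency falls inside band '%s'", b))
    }
    mats <- lapply(idx, function(fi) wpli_matrix(decomp, fi))
    stack <- simplify2array(mats)
    Wb <- apply(stack, c(1, 2), mean, na.rm = TRUE)
    Wb[is.nan(Wb)] <- NA_real_
    out[[b]] <- nodal_metrics(Wb, ...)
  }
  out
}

#' Long-format nodal table for a set of band graphs
#'
#' @param graphs result of [band_graphs()].
#' @return tibble with columns `band`, `channel`, `strength`, `clustering`,
#'   `eigencentrality`.
#' @export
nodal_table <- function(graphs) {
  dplyr::bind_rows(lapply(names(graphs), function(b) {
    dplyr::mutate(graphs[[b]]$nodes, band = b, .before = 1)
  }))
}
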