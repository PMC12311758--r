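#' Idealized 10-10 electrode montage on the unit sphere
#'
#' Constructs standard 10-10 electrode coordinates geometrically: the outer
#' ring (Fp, F7/8, T7/8, P7/8, O positions and their neighbors) lies at 72
#' degrees of polar angle from the vertex with azimuths every 18 degrees;
#' midline electrodes are spaced every 18 degrees along the sagittal arc;
#' each transverse row is filled by spherical (great-circle) interpolation
#' between its outer-ring edges and its midline electrode. Coordinates are
#' x = right, y = anterior, z = superior, unit norm.
#'
#' @param labels optional subset of labels to return (error if unknown).
#' @return tibble with columns `label`, `x`, `y`, `z` (64 rows by default).
#' @export
montage_1010 <- function(labels = NULL) {
  deg <- pi / 180
  ring_pt <- function(az) c(cos(az * deg) * sin(72 * deg),
                            sin(az * deg) * sin(72 * deg), cos(72 * deg))
  mid_pt <- function(polar_front) c(0, sin(polar_front * deg), cos(polar_front * deg))
  slerp <- function(u, v, t) {
    om <- acos(max(-1, min(1, sum(u * v))))
    if (om < 1e-12) return(u)
    (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
  }

  pts <- list()
  ring <- c(Fpz = 90, Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
            TP8 = -18, P8 = -36, PO8 = -54, O2 = -72, Oz = -90, O1 = -108,
            PO7 = -126, P7 = -144, TP7 = -162, T7 = 180, FT7 = 162,
            F7 = 144, AF7 = 126, Fp1 = 108)
  for (nm in names(ring)) pts[[nm]] <- ring_pt(ring[[nm]])
  mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0, CPz = -18, Pz = -36, POz = -54)
  for (nm in names(mid)) pts[[nm]] <- mid_pt(mid[[nm]])
  pts[["Iz"]] <- c(0, sin(-90 * deg), cos(90 * deg))

  rows <- list(
    AF = list(left = "AF7", mid = "AFz", right = "AF8",
              members = c(`AF3` = -0.5, `AF4` = 0.5)),
    F  = list(left = "F7", mid = "Fz", right = "F8",
              members = c(`F5` = -0.75, `F3` = -0.5, `F1` = -0.25,
                          `F2` = 0.25, `F4` = 0.5, `F6` = 0.75)),
    FC = list(left = "FT7", mid = "FCz", right = "FT8",
              members = c(`FC5` = -0.75, `FC3` = -0.5, `FC1` = -0.25,
                          `FC2` = 0.25, `FC4` = 0.5, `FC6` = 0.75)),
    C  = list(left = "T7", mid = "Cz", right = "T8",
              members = c(`C5` = -0.75, `C3` = -0.5, `C1` = -0.25,
                          `C2` = 0.25, `C4` = 0.5, `C6` = 0.75)),
    CP = list(left = "TP7", mid = "CPz", right = "TP8",
              members = c(`CP5` = -0.75, `CP3` = -0.5, `CP1` = -0.25,
                          `CP2` = 0.25, `CP4` = 0.5, `CP6` = 0.75)),
    P  = list(left = "P7", mid = "Pz", right = "P8",
              members = c(`P5` = -0.75, `P3` = -0.5, `P1` = -0.25,
                          `P2` = 0.25, `P4` = 0.5, `P6` = 0.75)),
    PO = list(left = "PO7", mid = "POz", right = "PO8",
              members = c(`PO5` = -0.75, `PO3` = -0.5,
                          `PO4` = 0.5, `PO6` = 0.75)))
  for (row in rows) {
    for (nm in names(row$members)) {
      f <- row$members[[nm]]
      pts[[nm]] <- if (f < 0) slerp(pts[[row$mid]], pts[[row$left]], -f)
                   else slerp(pts[[row$mid]], pts[[row$right]], f)
    }
  }

  M <- do.call(rbind, pts)
  out <- tibble::tibble(label = rownames(M),
                        x = unname(M[, 1]), y = unname(M[, 2]),
                        z = unname(M[, 3]))
  nrm <- sqrt(out$x^2 + out$y^2 + out$z^2)
  out$x <- out$x / nrm; out$y <- out$y / nrm; out$z <- out$z / nrm
  if (!is.null(labels)) {
    idx <- match(labels, out$label)
    if (anyNA(idx)) {
      stop("unknown electrode label(s): ", paste(labels[is.na(idx)], collapse = ", "))
    }
    out <- out[idx, ]
  }
  out
}
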