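#' Electrode montage
#'
#' A montage couples an ordered set of channel labels to 3D electrode
#' positions on the unit sphere (head-centered, dimensionless). Positions
#' drive spherical-spline interpolation and the distance-dependent spatial
#' correlation of the synthetic generator.
#'
#' @param labels Character vector of channel names.
#' @param positions Numeric matrix, one row per channel, columns x/y/z
#'   (x to the right ear, y to the nasion, z to the vertex). Every row must
#'   have Euclidean norm 1 within 1e-9 and rows must be pairwise distinct.
#' @return An object of class `eeg_montage` with elements `labels` and
#'   `positions`.
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 3L) {
    stop_relbeta("positions must be a length(labels) x 3 matrix", "montage_error")
  }
  norms <- sqrt(rowSums(positions^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop_relbeta("electrode positions must lie on the unit sphere (norm 1 +/- 1e-9)",
                 "montage_error")
  }
  if (anyDuplicated(round(positions, 9L))) {
    stop_relbeta("electrode positions must be pairwise distinct", "montage_error")
  }
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions), class = "eeg_montage")
}

#' Standard 19-channel 10-20 montage
#'
#' Returns the 19 electrodes of the international 10-20 system in the
#' conventional order Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2, F7, F8, T3,
#' T4, T5, T6, Fz, Cz, Pz, with idealized unit-sphere coordinates derived
#' from the 10-20 arc construction: the vertex Cz at (0,0,1), the outer
#' circumferential ring at 90 degrees inclination with azimuths in 36-degree
#' steps (Fp1/Fp2 at +/-18 degrees from the nasion), midline Fz/Pz and
#' central C3/C4 at 45 degrees inclination, and F3/F4/P3/P4 as great-circle
#' midpoints of their flanking midline and ring electrodes.
#'
#' @return An `eeg_montage` with 19 channels.
#' @export
standard_montage_1020 <- function() {
  sph <- function(incl, az) {
    ir <- incl * pi / 180
    ar <- az * pi / 180
    c(sin(ir) * sin(ar), sin(ir) * cos(ar), cos(ir))
  }
  gc_mid <- function(a, b) {
    v <- a + b
    v / sqrt(sum(v^2))
  }
  pos <- list(
    Fp1 = sph(90, -18), Fp2 = sph(90, 18),
    F7  = sph(90, -54), F8  = sph(90, 54),
    T3  = sph(90, -90), T4  = sph(90, 90),
    T5  = sph(90, -126), T6 = sph(90, 126),
    O1  = sph(90, -162), O2 = sph(90, 162),
    Fz  = sph(45, 0), Cz = c(0, 0, 1), Pz = sph(45, 180),
    C3  = sph(45, -90), C4 = sph(45, 90)
  )
  pos$F3 <- gc_mid(pos$Fz, pos$F7)
  pos$F4 <- gc_mid(pos$Fz, pos$F8)
  pos$P3 <- gc_mid(pos$Pz, pos$T5)
  pos$P4 <- gc_mid(pos$Pz, pos$T6)
  labels <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
              "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
  montage(labels, t(vapply(labels, function(l) pos[[l]], numeric(3))))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# chord distances between electrodes, used for spatial mixing
montage_distances <- function(mon) {
  as.matrix(stats::dist(mon$positions))
}
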