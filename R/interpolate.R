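# Spherical-spline scalp interpolation (Perrin-style): surface potentials are
# modeled as c0 + sum_i c_i g(cos(angle to electrode i)) with
# g(x) = (1/4pi) sum_n (2n+1) / (n^m (n+1)^m) P_n(x),
# stiffness m = 4, the Legendre series truncated at 50 terms, and a small
# ridge (1e-5) on the fitted system for numerical stability.

legendre_poly_matrix <- function(x, n_terms) {
  # P_n(x) for n = 1..n_terms via the Bonnet recursion, rows follow x
  P <- matrix(0, length(x), n_terms)
  P[, 1] <- x
  if (n_terms >= 2) P[, 2] <- 0.5 * (3 * x^2 - 1)
  for (n in 2:(n_terms - 1)) {
    if (n + 1 > n_terms) break
    P[, n + 1] <- ((2 * n + 1) * x * P[, n] - n * P[, n - 1]) / (n + 1)
  }
  P
}

spline_g <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_poly_matrix(as.vector(cosang), n_terms)
  out <- (P %*% coef) / (4 * pi)
  if (is.matrix(cosang)) matrix(out, nrow(cosang), ncol(cosang)) else as.vector(out)
}

# Linear operator mapping potentials at `good` electrodes to interpolated
# potentials at `bad` electrodes (rows: bad, cols: good).
spherical_interp_operator <- function(positions, good, bad,
                                      m = 4, n_terms = 50, lambda = 1e-5) {
  G <- spline_g(tcrossprod(positions[good, , drop = FALSE]), m, n_terms)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  Gb <- spline_g(positions[bad, , drop = FALSE] %*% t(positions[good, , drop = FALSE]),
                 m, n_terms)
  W <- solve(A, rbind(diag(ng), matrix(0, 1, ng)))  # (ng+1) x ng: data -> (c, c0)
  cbind(Gb, rep(1, length(bad))) %*% W
}

#' Spherical-spline interpolation of channels
#'
#' Replaces the listed channels, sample by sample, with the spherical-spline
#' estimate fitted to the remaining channels; all other channels are
#' untouched. The spline is calibrated on retained electrodes only.
#'
#' @param rec An `eeg_recording` with a montage.
#' @param channels Channel labels (or indices) to replace; empty set is the
#'   identity.
#' @param m Spline stiffness order.
#' @param n_terms Number of Legendre terms.
#' @param lambda Ridge regularization on the fitted system.
#' @return The recording with the listed channels replaced.
#' @export
spherical_interpolate <- function(rec, channels, m = 4, n_terms = 50,
                                  lambda = 1e-5) {
  if (is.character(channels)) channels <- match(channels, rec$labels)
  channels <- sort(unique(as.integer(channels)))
  if (!length(channels)) return(rec)
  n_ch <- nrow(rec$data)
  if (length(channels) >= n_ch - 3L) {
    stop_relbeta("too few good channels left to fit the spherical spline",
                 "interpolation_error")
  }
  if (is.null(rec$montage)) {
    stop_relbeta("recording has no montage; cannot interpolate", "interpolation_error")
  }
  pos <- rec$montage$positions[match(rec$labels, rec$montage$labels), , drop = FALSE]
  good <- setdiff(seq_len(n_ch), channels)
  Wop <- spherical_interp_operator(pos, good, channels, m, n_terms, lambda)
  data <- rec$data
  data[channels, ] <- Wop %*% data[good, , drop = FALSE]
  rec_with_data(rec, data)
}
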