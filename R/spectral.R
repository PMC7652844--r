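# Welch power spectra and relative band-power features.

#' Frequency band scheme
#'
#' The four canonical bands: delta 0.5-4, theta 4-8, alpha 8-12 and beta
#' 12-25 Hz. Bands are half-open `[lo, hi)` so shared edges are counted
#' once and the four relative fractions sum exactly to one.
#'
#' @param delta,theta,alpha,beta Two-element `c(lo, hi)` vectors in Hz.
#' @return Named list of class `band_scheme`.
#' @export
band_scheme <- function(delta = c(0.5, 4), theta = c(4, 8),
                        alpha = c(8, 12), beta = c(12, 25)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha, beta = beta)
  edges <- unlist(bands)
  if (any(vapply(bands, function(b) b[1] >= b[2], logical(1)))) {
    stop_relbeta("each band needs lo < hi", "config_error")
  }
  for (i in 1:3) {
    if (bands[[i]][2] != bands[[i + 1]][1]) {
      stop_relbeta("bands must be contiguous and ordered", "config_error")
    }
  }
  structure(bands, class = "band_scheme")
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: 2 s Hann segments with 50% overlap,
#' density scaling (microvolt^2 / Hz), one-sided. Retained-segment
#' annotations are respected: segments never bridge a window-rejection
#' deletion, and each Welch segment is tapered independently.
#'
#' @param rec An `eeg_recording`.
#' @param segment_s Welch segment length in seconds (default 2, giving
#'   0.5 Hz resolution).
#' @param overlap Fractional overlap between Welch segments.
#' @return A list of class `psd_estimate` with `freqs` (Hz), `power`
#'   (channels x freqs), `labels` and estimator metadata.
#' @export
compute_psd <- function(rec, segment_s = 2, overlap = 0.5) {
  nper <- round(segment_s * rec$fs)
  if (ncol(rec$data) < 2L * nper) {
    stop_relbeta("recording shorter than two Welch segments", "estimation_error")
  }
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1L) / nper)  # Hann
  u <- sum(win^2)
  step <- max(1L, round(nper * (1 - overlap)))
  segs <- rec_segments(rec)
  starts <- unlist(lapply(segs, function(sg) {
    if (sg[2] - sg[1] + 1L < nper) return(integer(0))
    seq(sg[1], sg[2] - nper + 1L, by = step)
  }))
  count <- length(starts)
  if (count == 0L) {
    stop_relbeta("no retained segment is long enough for the Welch window",
                 "estimation_error")
  }
  n_ch <- nrow(rec$data)
  # all (segment x channel) snippets as columns of one matrix: a single FFT
  idx <- outer(0L:(nper - 1L), starts, "+")
  td <- t(rec$data)
  big <- matrix(td[as.vector(idx), ], nper, count * n_ch)
  big <- (big - rep(colMeans(big), each = nper)) * win
  p3 <- array(Mod(stats::mvfft(big))^2, c(nper, count, n_ch))
  p <- matrix(0, nper, n_ch)
  for (k in seq_len(count)) p <- p + p3[, k, ]
  p <- p / count / (rec$fs * u)
  half <- nper %/% 2L
  onesided <- p[1:(half + 1L), , drop = FALSE]
  if (half >= 2L) onesided[2:half, ] <- 2 * onesided[2:half, ]
  structure(list(freqs = (0:half) * rec$fs / nper, power = t(onesided),
                 labels = rec$labels,
                 meta = list(segment_s = segment_s, overlap = overlap,
                             taper = "hann", n_segments = count)),
            class = "psd_estimate")
}

#' Integrated band power
#'
#' Riemann integration of the density over the half-open band `[lo, hi)`.
#'
#' @param psd A `psd_estimate`.
#' @param band Two-element `c(lo, hi)` in Hz, within the frequency grid.
#' @return Named per-channel power vector (microvolt^2).
#' @export
band_power <- function(psd, band) {
  if (band[1] < psd$freqs[1] || band[2] > psd$freqs[length(psd$freqs)] + 1e-9) {
    stop_relbeta("band lies outside the PSD frequency grid", "range_error")
  }
  df <- psd$freqs[2] - psd$freqs[1]
  sel <- psd$freqs >= band[1] - 1e-12 & psd$freqs < band[2] - 1e-12
  out <- rowSums(psd$power[, sel, drop = FALSE]) * df
  names(out) <- psd$labels
  out
}

#' Relative beta-band power
#'
#' Beta-band power divided by the summed power of the four bands, per
#' channel. Values lie in [0, 1] and the four band fractions sum to one.
#'
#' @param psd A `psd_estimate`.
#' @param scheme A [band_scheme()].
#' @return Named per-channel relative beta vector.
#' @export
relative_beta <- function(psd, scheme = band_scheme()) {
  bp <- vapply(scheme, function(b) band_power(psd, b), numeric(length(psd$labels)))
  if (length(psd$labels) == 1L) {
    bp <- matrix(bp, 1L, dimnames = list(NULL, names(scheme)))
  }
  denom <- rowSums(bp)
  if (any(denom <= 0)) {
    stop_relbeta(paste("zero total band power (silent channel):",
                       paste(psd$labels[denom <= 0], collapse = ", ")),
                 "undefined_feature")
  }
  out <- bp[, "beta"] / denom
  names(out) <- psd$labels
  out
}

#' Build the subjects x features table
#'
#' One row per (subject, session) with the 19 per-channel relative beta
#' powers, their channel mean, optional absolute beta powers, and the
#' sex/age metadata joined in. Subjects missing a session get a row of NA
#' features so that paired analyses can exclude them explicitly.
#'
#' @param recordings Named list: for each session name, a list of cleaned
#'   `eeg_recording`s aligned with the metadata rows of that session.
#' @param metadata Data frame with `subject_id`, `sex`, `age`, `session`.
#' @param scheme A [band_scheme()].
#' @param absolute_beta Also emit per-channel absolute beta power columns
#'   (`abs_` prefix) and their mean.
#' @param psd_args List of extra arguments for [compute_psd()].
#' @return Data frame of class `feature_table`; channel columns carry the
#'   channel label as name, plus `mean_relative_beta`.
#' @export
build_feature_table <- function(recordings, metadata, scheme = band_scheme(),
                                absolute_beta = FALSE, psd_args = list()) {
  sessions <- names(recordings)
  rows <- list()
  for (ses in sessions) {
    meta_s <- metadata[metadata$session == ses, , drop = FALSE]
    recs <- recordings[[ses]]
    if (nrow(meta_s) != length(recs)) {
      stop_relbeta(sprintf("session %s: %d metadata rows but %d recordings",
                           ses, nrow(meta_s), length(recs)), "feature_error")
    }
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      if (is.null(rec)) {
        labs <- recordings[[sessions[1]]][[1]]$labels
        feat <- stats::setNames(rep(NA_real_, length(labs)), labs)
        absb <- feat
      } else {
        psd <- do.call(compute_psd, c(list(rec), psd_args))
        feat <- relative_beta(psd, scheme)
        absb <- band_power(psd, scheme$beta)
      }
      row <- data.frame(subject_id = meta_s$subject_id[i], session = ses,
                        sex = meta_s$sex[i], age = meta_s$age[i],
                        stringsAsFactors = FALSE)
      row <- cbind(row, as.data.frame(as.list(feat)))
      row$mean_relative_beta <- mean(feat)
      if (absolute_beta) {
        ab <- as.data.frame(as.list(absb))
        names(ab) <- paste0("abs_", names(absb))
        row <- cbind(row, ab)
        row$mean_absolute_beta <- mean(absb)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

# channel feature columns of a feature table (everything between the
# metadata block and mean_relative_beta)
feature_channels <- function(table) {
  nm <- names(table)
  nm[!(nm %in% c("subject_id", "session", "sex", "age", "mean_relative_beta",
                 "mean_absolute_beta")) & !startsWith(nm, "abs_")]
}
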