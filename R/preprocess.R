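# PREP-inspired cleaning chain. Stages are exported individually and
# orchestrated by preprocess() in the fixed order: resample, edge trim,
# flat-channel detection, high-pass, low-correlation channel detection,
# artifact subspace reconstruction, bad-window rejection, spherical
# interpolation of all removed channels, average re-reference, low-pass FIR.

# MAD-based robust standard deviation (1.4826 * MAD); long inputs are
# subsampled evenly (the scale estimate, not the data, tolerates this).
robust_scale <- function(x, max_n = 8000L) {
  if (length(x) > max_n) x <- x[seq(1L, length(x), length.out = max_n)]
  1.4826 * stats::mad(x, constant = 1)
}

#' Cleaning configuration
#'
#' Defaults follow the published cleaning recipe: resampling to 250 Hz,
#' 30 s edge trims, flat threshold 5 s, a 0.5 Hz high-pass with 0.25/0.75 Hz
#' stop/pass edges, channel correlation threshold 0.75, ASR standard
#' deviation threshold 5, 1 s rejection windows with 66% overlap and a
#' more-than-four bad-channel rule, and a 40 Hz low-pass FIR.
#'
#' @param target_fs Resampling target (Hz).
#' @param trim_s Seconds removed from each end of the recording.
#' @param flat_max_s Longest tolerated flat stretch (seconds).
#' @param hp_stop,hp_pass High-pass stopband and passband edges (Hz).
#' @param corr_threshold Minimum median window correlation between a channel
#'   and its spherical-spline prediction from the other channels.
#' @param asr_std_threshold Component rejection threshold, in multiples of
#'   the calibration scale.
#' @param asr_window_s ASR sliding-window length (seconds, 50% overlap).
#' @param reject_window_s,reject_overlap,reject_max_bad Window-rejection
#'   parameters: window length, fractional overlap, and the strict
#'   "more than `reject_max_bad` bad channels" deletion rule.
#' @param lp_cutoff Low-pass FIR passband edge (Hz); stopband edge is 5 Hz above.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(target_fs = 250, trim_s = 30, flat_max_s = 5,
                            hp_stop = 0.25, hp_pass = 0.75,
                            corr_threshold = 0.75, asr_std_threshold = 5,
                            asr_window_s = 0.5, reject_window_s = 1,
                            reject_overlap = 0.66, reject_max_bad = 4,
                            lp_cutoff = 40) {
  cfg <- as.list(environment())
  if (cfg$hp_stop >= cfg$hp_pass) {
    stop_relbeta("hp_stop must be below hp_pass", "config_error")
  }
  if (cfg$reject_overlap <= 0 || cfg$reject_overlap >= 1) {
    stop_relbeta("reject_overlap must lie in (0, 1)", "config_error")
  }
  if (any(unlist(cfg[c("target_fs", "trim_s", "flat_max_s", "asr_std_threshold",
                       "asr_window_s", "reject_window_s", "lp_cutoff")]) < 0)) {
    stop_relbeta("cleaning thresholds must be non-negative", "config_error")
  }
  class(cfg) <- "cleaning_config"
  cfg
}

#' Resample a recording
#'
#' Fourier-method resampling: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-alias filter) and inverted on the new grid, so
#' the duration is preserved to within one sample period.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate in Hz; upsampling is not supported.
#' @return The resampled recording.
#' @export
resample <- function(rec, target_fs) {
  if (target_fs > rec$fs) {
    stop_relbeta("upsampling is not supported (target_fs > fs)", "resample_error")
  }
  if (target_fs == rec$fs) return(rec)
  n_out <- round(ncol(rec$data) * target_fs / rec$fs)
  rec_with_data(rec, resample_fourier(rec$data, n_out), fs = target_fs)
}

#' Trim recording edges
#'
#' Removes `trim_s` seconds from each end; interior samples are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param trim_s Seconds to remove from each end.
#' @return The trimmed recording.
#' @export
trim_edges <- function(rec, trim_s) {
  if (trim_s == 0) return(rec)
  n <- ncol(rec$data)
  k <- round(trim_s * rec$fs)
  if (n <= 2L * k) {
    stop_relbeta(sprintf("recording too short (%.1f s) for a 2 x %g s edge trim",
                         n / rec$fs, trim_s), "too_short_recording")
  }
  rec_with_data(rec, rec$data[, (k + 1L):(n - k), drop = FALSE])
}

#' Detect flat channels
#'
#' A channel is flat when it contains a contiguous run longer than
#' `flat_max_s` in which successive differences stay below a flatness
#' epsilon of `1e-8` times the channel's robust scale (MAD-based), with an
#' absolute floor of `1e-10` microvolts.
#'
#' @param rec An `eeg_recording`.
#' @param flat_max_s Longest tolerated flat stretch (seconds).
#' @return Character vector of flat channel labels.
#' @export
detect_flat_channels <- function(rec, flat_max_s = 5) {
  min_run <- flat_max_s * rec$fs
  flat <- vapply(seq_len(nrow(rec$data)), function(i) {
    x <- rec$data[i, ]
    eps <- max(1e-8 * robust_scale(x), 1e-10)
    small <- abs(diff(x)) < eps
    if (sum(small) < min_run) return(FALSE)  # cannot contain a long enough run
    r <- rle(small)
    runs <- r$lengths[r$values]
    length(runs) > 0 && (max(runs) + 1L) / rec$fs > flat_max_s
  }, logical(1))
  rec$labels[flat]
}

#' Zero-phase high-pass filter
#'
#' Applies the squared-magnitude response of an order-4 Butterworth
#' high-pass (the zero-phase forward-backward equivalent) whose -6 dB point
#' sits at the center of the `hp_stop`/`hp_pass` transition band. With the
#' default 0.25/0.75 Hz edges this is a 0.5 Hz high-pass with > 40 dB
#' attenuation at the stop edge and < 0.2 dB ripple at the pass edge.
#'
#' @param rec An `eeg_recording`.
#' @param hp_stop,hp_pass Stopband and passband edges in Hz.
#' @return The filtered recording.
#' @export
highpass <- function(rec, hp_stop = 0.25, hp_pass = 0.75) {
  if (hp_stop <= 0 || hp_stop >= hp_pass || hp_pass >= rec$fs / 2) {
    stop_relbeta("invalid high-pass band edges", "config_error")
  }
  fc <- (hp_stop + hp_pass) / 2
  rec_with_data(rec, apply_mag_response(rec$data, rec$fs, butter_hp_gain(fc)))
}

#' Zero-phase low-pass FIR filter
#'
#' Windowed-sinc (Hamming) kernel with passband edge `cutoff` and stopband
#' edge `cutoff + 5` Hz, applied with centered (zero-phase) convolution and
#' reflection padding.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff Passband edge in Hz; must be below Nyquist.
#' @return The filtered recording.
#' @export
lowpass_fir <- function(rec, cutoff = 40) {
  if (cutoff + 5 >= rec$fs / 2) {
    stop_relbeta("low-pass cutoff too close to Nyquist", "config_error")
  }
  h <- fir_lowpass_kernel(rec$fs, cutoff, cutoff + 5)
  rec_with_data(rec, apply_fir(rec$data, h))
}

#' Detect channels poorly correlated with their neighbors
#'
#' For every 1 s window, each channel is correlated with its
#' spherical-spline prediction from all other channels; a channel's score is
#' the median correlation over windows. Channels are flagged iteratively,
#' worst first: after a channel falls below `corr_threshold` it is removed
#' from the predictor set and the remaining scores are recomputed, so one
#' corrupted channel cannot drag its neighbors' predictions down with it.
#' Scores are clamped at zero so a threshold of 0 never flags anything.
#'
#' @param rec An `eeg_recording` with montage (at least 3 channels).
#' @param corr_threshold Rejection threshold on the median window correlation.
#' @param window_s Window length in seconds.
#' @return Character vector of flagged channel labels.
#' @export
reject_low_correlation_channels <- function(rec, corr_threshold = 0.75,
                                            window_s = 1) {
  n_ch <- nrow(rec$data)
  if (n_ch < 3L) stop_relbeta("need at least 3 channels", "config_error")
  pos <- rec$montage$positions[match(rec$labels, rec$montage$labels), , drop = FALSE]
  wlen <- max(2L, round(window_s * rec$fs))
  score_channels <- function(rows) {
    k <- length(rows)
    P <- matrix(0, k, k)
    for (i in seq_len(k)) {
      P[i, -i] <- spherical_interp_operator(pos[rows, , drop = FALSE],
                                            setdiff(seq_len(k), i), i)
    }
    x <- rec$data[rows, , drop = FALSE]
    pred <- P %*% x
    nw <- floor(ncol(x) / wlen)
    scores <- matrix(NA_real_, k, nw)
    for (w in seq_len(nw)) {
      idx <- ((w - 1L) * wlen + 1L):(w * wlen)
      a <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
      b <- pred[, idx, drop = FALSE] - rowMeans(pred[, idx, drop = FALSE])
      denom <- sqrt(rowSums(a^2) * rowSums(b^2))
      scores[, w] <- ifelse(denom > 0, rowSums(a * b) / denom, 0)
    }
    pmax(apply(scores, 1, stats::median), 0)
  }
  remaining <- seq_len(n_ch)
  flagged <- integer(0)
  while (length(remaining) >= 4L) {
    med <- score_channels(remaining)
    if (min(med) >= corr_threshold) break
    worst <- remaining[which.min(med)]
    flagged <- c(flagged, worst)
    remaining <- setdiff(remaining, worst)
  }
  rec$labels[sort(flagged)]
}

#' Calibrate an artifact-subspace-reconstruction model
#'
#' The "most representative part" of the recording is taken as the 1 s
#' windows whose total RMS lies within the 5th-67th percentile. The model
#' holds the principal axes of the calibration data and, per component, a
#' robust (MAD-based) scale of the component scores.
#'
#' @param rec An `eeg_recording` with at least 30 s of data.
#' @param window_s Calibration window length (seconds).
#' @param rms_quantiles Lower/upper quantiles of the per-window RMS kept for
#'   calibration.
#' @return A list of class `asr_model` with `axes` (orthonormal columns),
#'   `scales` and `labels`.
#' @export
asr_calibrate <- function(rec, window_s = 1, rms_quantiles = c(0.05, 0.67)) {
  n <- ncol(rec$data)
  if (n / rec$fs < 30) {
    stop_relbeta("at least 30 s of data are required for ASR calibration",
                 "calibration_error")
  }
  wlen <- round(window_s * rec$fs)
  nw <- floor(n / wlen)
  wrms <- vapply(seq_len(nw), function(w) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    sqrt(mean(rec$data[, idx]^2))
  }, numeric(1))
  qs <- stats::quantile(wrms, rms_quantiles, names = FALSE)
  keep <- which(wrms >= qs[1] & wrms <= qs[2])
  if (!length(keep)) stop_relbeta("no calibration windows survive", "calibration_error")
  idx <- unlist(lapply(keep, function(w) ((w - 1L) * wlen + 1L):(w * wlen)))
  calib <- rec$data[, idx, drop = FALSE]
  eg <- eigen(stats::cov(t(calib)), symmetric = TRUE)
  axes <- eg$vectors
  scores <- t(axes) %*% calib
  scales <- apply(scores, 1, robust_scale)
  structure(list(axes = axes, scales = scales, labels = rec$labels,
                 # robust calibration covariance, used to derive the scale of
                 # an arbitrary component direction during cleaning
                 cov = axes %*% (scales^2 * t(axes))),
            class = "asr_model")
}

#' Apply artifact subspace reconstruction
#'
#' Slides a window (50% overlap, raised-cosine cross-fade) over the
#' recording and PCA-decomposes each window. A window component is rejected
#' when its standard deviation exceeds `std_threshold` times the calibration
#' scale of that component direction (the direction's standard deviation
#' under the robust calibration covariance); the window is then
#' reconstructed from the retained components only. Windows with no
#' exceeding component pass through unchanged; windows in which every
#' component exceeds are left untouched and reported as unreconstructable so
#' that window rejection can delete them.
#'
#' @param rec An `eeg_recording` whose channels match the model.
#' @param model An `asr_model` from [asr_calibrate()].
#' @param std_threshold Rejection threshold (multiples of calibration scale).
#' @param window_s Sliding-window length in seconds.
#' @return List with `recording`, `modified_spans` and `unreconstructable`
#'   (data frames with `start_s`, `end_s`).
#' @export
asr_clean <- function(rec, model, std_threshold = 5, window_s = 0.5) {
  if (!identical(model$labels, rec$labels)) {
    stop_relbeta("ASR model channels do not match the recording", "asr_error")
  }
  data <- rec$data
  n <- ncol(data)
  L <- round(window_s * rec$fs)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, max(1L, n - L + 1L), by = step)
  if (starts[length(starts)] + L - 1L < n) starts <- c(starts, n - L + 1L)
  Ccal <- model$cov
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 0.5) / L)
  out <- matrix(0, nrow(data), n)
  wsum <- numeric(n)
  mod_spans <- list()
  bad_spans <- list()
  for (s in starts) {
    idx <- s:(s + L - 1L)
    X <- data[, idx, drop = FALSE]
    eg <- eigen(tcrossprod(X) / L, symmetric = TRUE)
    comp_sd <- sqrt(pmax(eg$values, 0))
    cal_sd <- sqrt(pmax(colSums(eg$vectors * (Ccal %*% eg$vectors)), 0))
    exceed <- comp_sd > std_threshold * cal_sd
    if (all(exceed)) {
      bad_spans[[length(bad_spans) + 1L]] <- c(s, s + L - 1L)
      Xr <- X
    } else if (any(exceed)) {
      V <- eg$vectors
      S <- crossprod(V, X)
      S[exceed, ] <- 0
      Xr <- V %*% S
      mod_spans[[length(mod_spans) + 1L]] <- c(s, s + L - 1L)
    } else {
      Xr <- X
    }
    out[, idx] <- out[, idx] + sweep(Xr, 2, w, "*")
    wsum[idx] <- wsum[idx] + w
  }
  out <- sweep(out, 2, pmax(wsum, .Machine$double.eps), "/")
  span_df <- function(spans) {
    if (!length(spans)) {
      return(data.frame(start_s = numeric(0), end_s = numeric(0)))
    }
    m <- do.call(rbind, spans)
    merge_spans(data.frame(start_s = (m[, 1] - 1) / rec$fs,
                           end_s = m[, 2] / rec$fs))
  }
  list(recording = rec_with_data(rec, out),
       modified_spans = span_df(mod_spans),
       unreconstructable = span_df(bad_spans))
}

# merge overlapping/adjacent [start_s, end_s] spans
merge_spans <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start_s), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$start_s[i] <= out$end_s[j] + 1e-9) {
      out$end_s[j] <- max(out$end_s[j], df$end_s[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Reject windows with too many bad channels
#'
#' Slides a window over the recording; a channel is bad within a window when
#' its RMS exceeds 5 times its robust (MAD-based) channel scale, or when the
#' window overlaps an ASR-unreconstructable span. Windows with strictly more
#' than `max_bad` bad channels are deleted; surviving segments are
#' concatenated, with the retained segment boundaries and the rejected spans
#' recorded in the annotations.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds.
#' @param overlap Fractional window overlap in (0, 1).
#' @param max_bad Strict bad-channel count threshold ("more than" rule).
#' @param bad_spans Optional data frame (`start_s`, `end_s`) of
#'   unreconstructable spans.
#' @param badness_channels Optional subset of channel labels on which
#'   badness is evaluated (removed channels carry no information).
#' @return List with `recording`, `rejected_spans` and `retained_fraction`.
#' @export
reject_bad_windows <- function(rec, window_s = 1, overlap = 0.66, max_bad = 4,
                               bad_spans = NULL, badness_channels = NULL) {
  n <- ncol(rec$data)
  L <- round(window_s * rec$fs)
  if (n <= L) stop_relbeta("recording shorter than the rejection window",
                           "too_short_recording")
  rows <- if (is.null(badness_channels)) seq_len(nrow(rec$data)) else
    match(badness_channels, rec$labels)
  x <- rec$data[rows, , drop = FALSE]
  scales <- apply(x, 1, robust_scale)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  if (starts[length(starts)] + L - 1L < n) starts <- c(starts, n - L + 1L)
  drop <- logical(n)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    rms <- sqrt(rowMeans(x[, idx, drop = FALSE]^2))
    nbad <- sum(rms > 5 * scales)
    if (!is.null(bad_spans) && nrow(bad_spans)) {
      t0 <- (s - 1) / rec$fs
      t1 <- (s + L - 1) / rec$fs
      if (any(bad_spans$start_s < t1 & bad_spans$end_s > t0)) nbad <- length(rows)
    }
    if (nbad > max_bad) drop[idx] <- TRUE
  }
  retained_fraction <- mean(!drop)
  if (retained_fraction == 0) {
    stop_relbeta("every window was rejected (retained_fraction = 0)",
                 "empty_recording")
  }
  r <- rle(drop)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  rejected <- data.frame(start_s = (starts_r[r$values] - 1) / rec$fs,
                         end_s = ends[r$values] / rec$fs)
  keep_runs <- which(!r$values)
  new_data <- rec$data[, !drop, drop = FALSE]
  out <- rec_with_data(rec, new_data)
  # retained segments in the post-deletion timeline
  lens <- r$lengths[keep_runs]
  seg_end <- cumsum(lens)
  seg_start <- seg_end - lens + 1L
  out$annotations <- out$annotations[out$annotations$tag != "retained_segment", ]
  out <- add_annotation(out, (seg_start - 1) / rec$fs, seg_end / rec$fs,
                        "retained_segment")
  if (nrow(rejected)) {
    out <- add_annotation(out, rejected$start_s, rejected$end_s, "rejected_window")
  }
  list(recording = out, rejected_spans = rejected,
       retained_fraction = retained_fraction)
}

#' Re-reference to the average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  rec_with_data(rec, sweep(rec$data, 2, colMeans(rec$data), "-"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, relbeta_error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = c(class(e)[1], "pipeline_error", "relbeta_error",
                                  "error", "condition")))
  })
}

#' Run the full cleaning chain
#'
#' Applies, in order: resample, trim_edges, detect_flat_channels, highpass,
#' reject_low_correlation_channels, asr_calibrate + asr_clean,
#' reject_bad_windows, spherical_interpolate of all removed channels,
#' rereference_average, lowpass_fir. Channel count and order are preserved
#' end to end; removed channels are interpolated back.
#'
#' @param rec An `eeg_recording`.
#' @param config A [cleaning_config()].
#' @return List with `recording` and `report` (class `cleaning_report`): the
#'   removed/interpolated channels, ASR-modified spans, rejected spans and
#'   the retained-data fraction.
#' @export
preprocess <- function(rec, config = cleaning_config()) {
  rec <- with_stage("resample", resample(rec, config$target_fs))
  rec <- with_stage("trim_edges", trim_edges(rec, config$trim_s))
  flat <- with_stage("detect_flat_channels",
                     detect_flat_channels(rec, config$flat_max_s))
  rec <- with_stage("highpass", highpass(rec, config$hp_stop, config$hp_pass))
  good <- setdiff(rec$labels, flat)
  sub <- subset_channels(rec, good)
  low_corr <- with_stage("reject_low_correlation_channels",
                         reject_low_correlation_channels(sub, config$corr_threshold))
  good <- setdiff(good, low_corr)
  if (length(good) < 4L) {
    stop_relbeta("fewer than 4 channels survive channel rejection", "pipeline_error")
  }
  sub <- subset_channels(rec, good)
  model <- with_stage("asr_calibrate", asr_calibrate(sub, window_s = 1))
  asr <- with_stage("asr_clean",
                    asr_clean(sub, model, config$asr_std_threshold,
                              config$asr_window_s))
  rec$data[match(good, rec$labels), ] <- asr$recording$data
  rj <- with_stage("reject_bad_windows",
                   reject_bad_windows(rec, config$reject_window_s,
                                      config$reject_overlap, config$reject_max_bad,
                                      bad_spans = asr$unreconstructable,
                                      badness_channels = good))
  rec <- rj$recording
  removed <- c(flat, low_corr)
  rec <- with_stage("spherical_interpolate", spherical_interpolate(rec, removed))
  rec <- with_stage("rereference_average", rereference_average(rec))
  rec <- with_stage("lowpass_fir", lowpass_fir(rec, config$lp_cutoff))
  report <- structure(list(
    flat_channels = flat,
    low_correlation_channels = low_corr,
    interpolated_channels = removed,
    asr_windows_modified = list(count = nrow(asr$modified_spans),
                                spans = asr$modified_spans),
    asr_unreconstructable = asr$unreconstructable,
    rejected_windows = rj$rejected_spans,
    retained_fraction = rj$retained_fraction
  ), class = "cleaning_report")
  list(recording = rec, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat("  flat channels:", if (length(x$flat_channels)) paste(x$flat_channels, collapse = ", ") else "none", "\n")
  cat("  low-correlation channels:",
      if (length(x$low_correlation_channels)) paste(x$low_correlation_channels, collapse = ", ") else "none", "\n")
  cat(sprintf("  ASR windows modified: %d\n", x$asr_windows_modified$count))
  cat(sprintf("  rejected windows: %d, retained fraction %.3f\n",
              nrow(x$rejected_windows), x$retained_fraction))
  invisible(x)
}

# recording restricted to the given channel labels (order preserved)
subset_channels <- function(rec, labels) {
  idx <- match(labels, rec$labels)
  out <- rec
  out$data <- rec$data[idx, , drop = FALSE]
  out$labels <- rec$labels[idx]
  out
}
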