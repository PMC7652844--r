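#' Multichannel EEG recording
#'
#' The central signal container: a channels x samples matrix in microvolts,
#' its sampling rate, channel labels, the electrode montage and a table of
#' time annotations. Annotations with tag `"retained_segment"` mark the
#' contiguous stretches that survived window rejection; spectral estimation
#' never bridges a segment boundary.
#'
#' @param data Numeric matrix, channels x samples (microvolts). All values
#'   must be finite.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names, one per row of `data`.
#' @param montage An [montage()] covering `labels` (may hold extra channels).
#' @param annotations Data frame with columns `start_s`, `end_s`, `tag`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, labels, montage = NULL, annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop_relbeta("recording data must be a finite numeric matrix", "recording_error")
  }
  labels <- as.character(labels)
  if (nrow(data) != length(labels)) {
    stop_relbeta("rows of data must correspond 1:1 to labels", "recording_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_relbeta("fs must be a positive scalar", "recording_error")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(start_s = numeric(0), end_s = numeric(0),
                              tag = character(0), stringsAsFactors = FALSE)
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, montage = montage,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, rec_duration(x)))
  if (nrow(x$annotations)) {
    cat(sprintf("  annotations: %d (%s)\n", nrow(x$annotations),
                paste(unique(x$annotations$tag), collapse = ", ")))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

# replace the data matrix, keeping metadata
rec_with_data <- function(rec, data, fs = rec$fs, annotations = rec$annotations) {
  rec$data <- data
  rec$fs <- fs
  rec$annotations <- annotations
  rownames(rec$data) <- rec$labels
  rec
}

# contiguous retained segments as a list of column index ranges.
# If no retained_segment annotations exist the whole recording is one segment.
rec_segments <- function(rec) {
  ann <- rec$annotations
  seg <- ann[ann$tag == "retained_segment", , drop = FALSE]
  if (!nrow(seg)) {
    return(list(c(1L, ncol(rec$data))))
  }
  lapply(seq_len(nrow(seg)), function(i) {
    c(floor(seg$start_s[i] * rec$fs) + 1L,
      min(ncol(rec$data), round(seg$end_s[i] * rec$fs)))
  })
}

add_annotation <- function(rec, start_s, end_s, tag) {
  if (length(start_s)) {
    rec$annotations <- rbind(
      rec$annotations,
      data.frame(start_s = start_s, end_s = end_s, tag = tag,
                 stringsAsFactors = FALSE)
    )
  }
  rec
}
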