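# Frequency-domain signal primitives shared by the generator and the cleaning
# chain. All filters here are zero-phase by construction: either a real,
# non-negative magnitude response applied to the DFT, or a symmetric FIR
# kernel applied with centered convolution.

# Apply a magnitude response to every channel of a channels x samples matrix.
# `gain` is a function of absolute frequency in Hz returning values in [0, 1].
apply_mag_response <- function(x, fs, gain) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) * fs / n
  fa <- pmin(f, fs - f)          # fold to absolute frequency
  g <- gain(fa)
  X <- stats::mvfft(t(x))
  y <- Re(stats::mvfft(X * g, inverse = TRUE)) / n
  t(y)
}

# squared-magnitude response of an order-4 Butterworth high-pass: equivalent
# to forward-backward (zero-phase) IIR filtering with that filter.
butter_hp_gain <- function(fc, order = 4L) {
  function(f) {
    r <- (f / fc)^(2L * order)
    g <- r / (1 + r)
    g[f == 0] <- 0
    g
  }
}

# windowed-sinc (Hamming) low-pass FIR kernel; cutoff at the transition-band
# center, length from the 3.3/width Hamming rule, normalized to unit DC gain.
fir_lowpass_kernel <- function(fs, f_pass, f_stop) {
  stopifnot(f_stop > f_pass)
  fc <- (f_pass + f_stop) / 2
  width <- (f_stop - f_pass) / fs
  ntaps <- ceiling(3.3 / width)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- seq_len(ntaps) - 1L - (ntaps - 1L) / 2
  h <- ifelse(m == 0, 2 * fc / fs, sin(2 * pi * fc * m / fs) / (pi * m))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(ntaps) - 1L) / (ntaps - 1L))
  h <- h * w
  h / sum(h)
}

# zero-phase FIR filtering of a channels x samples matrix with a symmetric
# kernel; edges handled by reflection padding.
apply_fir <- function(x, h) {
  ntaps <- length(h)
  half <- (ntaps - 1L) / 2L
  n <- ncol(x)
  if (half >= n) stop_relbeta("recording too short for FIR kernel", "filter_error")
  pad_l <- x[, half:1, drop = FALSE]
  pad_r <- x[, n:(n - half + 1L), drop = FALSE]
  xp <- cbind(pad_l, x, pad_r)
  np <- ncol(xp)
  nfft <- stats::nextn(np + ntaps - 1L, 2L)
  H <- stats::fft(c(h, numeric(nfft - ntaps)))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  # centered part: convolution delay is `half` + the left padding
  t(y[(2L * half + 1L):(2L * half + n), , drop = FALSE])
}

# Fourier-method resampling of a channels x samples matrix to n_out samples:
# spectrum truncation is an ideal anti-alias filter, duration is preserved.
resample_fourier <- function(x, n_out) {
  n <- ncol(x)
  if (n_out == n) return(x)
  X <- stats::mvfft(t(x))
  Y <- matrix(0 + 0i, n_out, nrow(x))
  h <- min(n, n_out) %/% 2L
  Y[1L, ] <- X[1L, ]                                   # DC
  if (h >= 1L) {
    Y[2L:(h + 1L), ] <- X[2L:(h + 1L), ]               # positive freqs
    k <- seq_len(max(h - 1L, 0L))
    if (length(k)) Y[n_out - k + 1L, ] <- X[n - k + 1L, ]  # negative freqs
  }
  # IDFT with the forward transform's 1/n keeps amplitudes unchanged
  t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
}
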