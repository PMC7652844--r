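fs <- 250

test_that("resample halves the rate, preserves duration and spectral peaks", {
  t <- seq_len(10 * 500) / 500
  rec <- recording(rbind(sin(2 * pi * 10 * t)), 500, "a")
  out <- resample(rec, 250)
  expect_equal(out$fs, 250)
  expect_lte(abs(ncol(out$data) - 2500), 1)
  spec <- Mod(fft(out$data[1, ]))[1:1250]
  peak_hz <- (which.max(spec) - 1) * 250 / ncol(out$data)
  expect_lt(abs(peak_hz - 10), 250 / ncol(out$data) + 1e-9)  # within one bin
  # identity and error branches
  expect_identical(resample(rec, 500), rec)
  expect_error(resample(rec, 1000), class = "resample_error")
})

test_that("trim_edges removes exactly the edges", {
  n <- 60 * fs
  rec <- recording(rbind(seq_len(n) - 1), fs, "ramp")
  out <- trim_edges(rec, 5)
  expect_equal(ncol(out$data), n - 2 * 5 * fs)
  expect_equal(unname(out$data[1, 1]), 5 * fs)  # index shift by trim_s * fs
  expect_identical(trim_edges(rec, 0), rec)
  expect_error(trim_edges(rec, 31), class = "too_short_recording")
})

test_that("flat channels are detected by run length with the epsilon rule", {
  n <- 20 * fs
  set.seed(1)
  base <- function(t) rnorm(length(t))
  mk <- function(flat_s, jitter = 0) {
    x <- rnorm(n)
    idx <- (5 * fs):(5 * fs + flat_s * fs)
    x[idx] <- 1 + jitter * rnorm(length(idx))
    x
  }
  rec <- recording(rbind(a = mk(6), b = mk(4), c = rnorm(n),
                         d = c(rep(0, 10 * fs) + 1e-12 * rnorm(10 * fs),
                               rnorm(n - 10 * fs))),
                   fs, c("a", "b", "c", "d"))
  flags <- detect_flat_channels(rec, 5)
  expect_true("a" %in% flags)   # 6 s > 5 s
  expect_false("b" %in% flags)  # 4 s below threshold
  expect_false("c" %in% flags)
  expect_true("d" %in% flags)   # sub-epsilon jitter counts as flat
})

test_that("high-pass meets the stop/pass specification", {
  t <- seq_len(120 * fs) / fs
  rec <- recording(rbind(sin(2 * pi * 0.1 * t), sin(2 * pi * 2 * t),
                         rep(100, length(t))),
                   fs, c("slow", "fast", "dc"))
  out <- highpass(rec, 0.25, 0.75)
  expect_lte(rms(out$data[1, ]) / rms(rec$data[1, ]), 0.1)
  expect_gt(rms(out$data[2, ]) / rms(rec$data[2, ]), 10^(-1 / 20))  # within 1 dB
  expect_lt(abs(mean(out$data[3, ])), 1)
  expect_error(highpass(rec, 0.75, 0.25), class = "config_error")
})

test_that("low-pass FIR meets the stop/pass specification", {
  t <- seq_len(60 * fs) / fs
  rec <- recording(rbind(sin(2 * pi * 45 * t), sin(2 * pi * 10 * t),
                         rep(5, length(t))),
                   fs, c("hf", "mid", "dc"))
  out <- lowpass_fir(rec, 40)
  expect_lte(rms(out$data[1, ]) / rms(rec$data[1, ]), 0.1)
  expect_gt(rms(out$data[2, ]) / rms(rec$data[2, ]), 10^(-1 / 20))
  expect_gt(mean(out$data[3, ]) / 5, 10^(-1 / 20))
  expect_error(lowpass_fir(recording(rbind(rnorm(1000)), 80, "a"), 40),
               class = "config_error")
})

test_that("low-correlation rejection flags decorrelated channels only", {
  rec <- highpass(cohort_recording(seed = 21))
  expect_length(reject_low_correlation_channels(rec), 0)
  # replace one channel with independent noise
  bad <- rec
  set.seed(9)
  bad$data[7, ] <- rnorm(ncol(bad$data), sd = sd(bad$data[7, ]))
  expect_identical(reject_low_correlation_channels(bad), bad$labels[7])
  # identical copies correlate perfectly; threshold 0 flags nothing
  t <- seq_len(40 * fs) / fs
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 11 * t)
  same <- recording(matrix(rep(x, 19), nrow = 19, byrow = TRUE), fs,
                    standard_montage_1020()$labels,
                    montage = standard_montage_1020())
  expect_length(reject_low_correlation_channels(same), 0)
  expect_length(reject_low_correlation_channels(bad, corr_threshold = 0), 0)
})

test_that("ASR calibration recovers component scales of stationary input", {
  set.seed(10)
  n <- 40 * fs
  mix <- matrix(rnorm(25), 5, 5)
  data <- mix %*% matrix(rnorm(5 * n), 5, n)
  rec <- recording(data, fs, letters[1:5])
  model <- asr_calibrate(rec)
  eg <- eigen(cov(t(data)), symmetric = TRUE)
  direct_sd <- sqrt(eg$values)
  expect_lt(max(abs(model$scales / direct_sd - 1)), 0.10)
  # deterministic
  model2 <- asr_calibrate(rec)
  expect_identical(model$scales, model2$scales)
  expect_error(asr_calibrate(recording(rbind(rnorm(fs)), fs, "a")),
               class = "calibration_error")
})

test_that("ASR calibration tolerates a small fraction of burst windows", {
  set.seed(11)
  n <- 60 * fs
  mix <- matrix(rnorm(25), 5, 5)
  clean <- mix %*% matrix(rnorm(5 * n), 5, n)
  corrupted <- clean
  burst_w <- sample(0:59, 3)  # 5% of the 1 s windows
  for (w in burst_w) {
    idx <- (w * fs + 1):((w + 1) * fs)
    corrupted[, idx] <- corrupted[, idx] + 40 * matrix(rnorm(5 * fs), 5)
  }
  m_corrupt <- asr_calibrate(recording(corrupted, fs, letters[1:5]))
  keep <- setdiff(0:59, burst_w)
  idx_clean <- unlist(lapply(keep, function(w) (w * fs + 1):((w + 1) * fs)))
  m_clean <- asr_calibrate(recording(clean[, idx_clean], fs, letters[1:5]))
  expect_lt(max(abs(m_corrupt$scales / m_clean$scales - 1)), 0.15)
})

test_that("ASR reconstructs bursts and leaves clean data alone", {
  rec <- highpass(cohort_recording(seed = 22))
  model <- asr_calibrate(rec)
  # burst-free input passes through nearly unchanged
  out <- asr_clean(rec, model, 5)
  cors <- vapply(seq_len(19), function(i)
    cor(out$recording$data[i, ], rec$data[i, ]), numeric(1))
  expect_true(all(cors >= 0.99))
  # infinite threshold: exact identity
  out_inf <- asr_clean(rec, model, Inf)
  expect_equal(out_inf$recording$data, rec$data, tolerance = 1e-12)
  expect_equal(nrow(out_inf$modified_spans), 0)
  # a 0.5 s burst at 50x background on 3 channels
  corrupted <- rec
  bidx <- (20 * fs + 1):(20.5 * fs)
  set.seed(12)
  for (ch in c(3, 8, 15)) {
    corrupted$data[ch, bidx] <- corrupted$data[ch, bidx] +
      50 * sd(rec$data[ch, ]) * rnorm(length(bidx))
  }
  cleaned <- asr_clean(corrupted, model, 5)
  expect_gte(rms(corrupted$data[c(3, 8, 15), bidx]) /
               rms(cleaned$recording$data[c(3, 8, 15), bidx]), 10)
  # distortion outside the modified spans stays below 5%
  mask <- rep(TRUE, ncol(rec$data))
  ms <- cleaned$modified_spans
  for (k in seq_len(nrow(ms))) {
    mask[(round(ms$start_s[k] * fs) + 1):round(ms$end_s[k] * fs)] <- FALSE
  }
  expect_lt(abs(rms(cleaned$recording$data[, mask]) /
                  rms(corrupted$data[, mask]) - 1), 0.05)
})

test_that("window rejection applies the strict more-than-four rule", {
  rec <- highpass(cohort_recording(seed = 23))
  clean <- reject_bad_windows(rec)
  expect_equal(clean$retained_fraction, 1)
  expect_equal(nrow(clean$rejected_spans), 0)
  saturate <- function(rec, n_ch) {
    out <- rec
    idx <- (10 * fs + 1):(11 * fs)
    for (ch in seq_len(n_ch)) out$data[ch, idx] <- 500 + out$data[ch, idx]
    out
  }
  r5 <- reject_bad_windows(saturate(rec, 5))
  expect_gt(nrow(r5$rejected_spans), 0)
  expect_true(any(r5$rejected_spans$start_s < 11 & r5$rejected_spans$end_s > 10))
  expect_lt(r5$retained_fraction, 1)
  r4 <- reject_bad_windows(saturate(rec, 4))  # exactly four: kept
  expect_equal(r4$retained_fraction, 1)
})

test_that("spherical interpolation reproduces smooth fields", {
  mon <- standard_montage_1020()
  n <- 100
  # constant potential field
  rec_c <- recording(matrix(7, 19, n), 1, mon$labels, montage = mon)
  out_c <- spherical_interpolate(rec_c, "Cz")
  expect_lt(max(abs(out_c$data[match("Cz", mon$labels), ] - 7)), 1e-6)
  # first-order spherical harmonic: potential = x-coordinate
  vx <- mon$positions[, 1]
  rec_h <- recording(matrix(vx, 19, n), 1, mon$labels, montage = mon)
  for (ch in c("C3", "Fz", "T4")) {
    out_h <- spherical_interpolate(rec_h, ch)
    i <- match(ch, mon$labels)
    expect_lt(abs(out_h$data[i, 1] - vx[i]) / max(abs(vx)), 0.05)
  }
  # empty set is the identity; too many channels errors
  expect_identical(spherical_interpolate(rec_h, character(0)), rec_h)
  expect_error(spherical_interpolate(rec_h, mon$labels[1:16]),
               class = "interpolation_error")
})

test_that("average reference zeroes the cross-channel mean", {
  set.seed(13)
  rec <- recording(matrix(rnorm(5 * 100, sd = 10), 5), 10, letters[1:5])
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotent
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  # two channels: closed form
  two <- rereference_average(recording(rbind(c(3, 5), c(1, 1)), 1, c("a", "b")))
  expect_equal(two$data, rbind(a = c(1, 2), b = c(-1, -2)))
})

test_that("preprocess leaves an artifact-free recording intact", {
  cfg <- sim_config(n_subjects = 2, n_female = 1, duration_s = 90, seed = 24)
  rec <- simulate_cohort(cfg)$pre[[1]]
  out <- preprocess(rec)
  expect_length(out$report$interpolated_channels, 0)
  expect_equal(out$report$retained_fraction, 1)
  expect_identical(out$recording$labels, rec$labels)
  # compare against the passband content of the raw input on the same span
  ref <- lowpass_fir(rereference_average(highpass(trim_edges(rec, 30))))
  cors <- vapply(seq_len(19), function(i)
    cor(out$recording$data[i, ], ref$data[i, ]), numeric(1))
  expect_true(all(cors >= 0.95))
})

test_that("preprocess recovers planted channel flaws and burst spans", {
  cfg <- sim_config(n_subjects = 2, n_female = 1, duration_s = 100, seed = 25)
  rec <- simulate_cohort(cfg)$pre[[1]]
  spec <- artifact_spec(n_flat = 1, n_decorrelated = 1, n_bursts = 2,
                        burst_amplitude = 50, edge_margin_s = 32)
  inj <- inject_artifacts(rec, spec, seed = 5)
  out <- preprocess(inj$recording)
  flat_truth <- inj$log$channels[inj$log$type == "flat"]
  dec_truth <- inj$log$channels[inj$log$type == "decorrelated"]
  expect_setequal(out$report$flat_channels, flat_truth)
  expect_setequal(out$report$low_correlation_channels, dec_truth)
  expect_setequal(out$report$interpolated_channels, c(flat_truth, dec_truth))
  # burst spans (shifted by the 30 s trim) overlap ASR-modified or rejected spans
  bursts <- inj$log[inj$log$type == "burst", ]
  spans <- rbind(out$report$asr_windows_modified$spans,
                 out$report$asr_unreconstructable)
  hits <- vapply(seq_len(nrow(bursts)), function(k) {
    s0 <- bursts$start_s[k] - 30
    s1 <- bursts$end_s[k] - 30
    any(spans$start_s < s1 & spans$end_s > s0)
  }, logical(1))
  expect_gte(sum(hits), 2)
  # channel order preserved, average reference holds
  expect_identical(out$recording$labels, rec$labels)
  expect_lt(max(abs(colMeans(out$recording$data))), 1e-9)
})

test_that("preprocess propagates stage errors with the stage name", {
  rec <- cohort_recording(seed = 26, duration_s = 62)
  err <- tryCatch(preprocess(rec, cleaning_config(trim_s = 31)),
                  relbeta_error = identity)
  expect_s3_class(err, "too_short_recording")
  expect_match(conditionMessage(err), "trim_edges")
})
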