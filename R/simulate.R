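# Synthetic EEG cohort generator.
#
# Each recording is a spatially mixed sum of three stationary components:
# a 1/f^gamma background, band-limited alpha (8-12 Hz) and band-limited beta
# (12-25 Hz), plus a small amount of independent sensor noise. The beta
# component's amplitude is the configured baseline times a per-subject,
# per-session multiplicative factor; the factor is log-normal with a
# sex-specific location so that the analytic AUC of any monotone beta
# feature against sex is pnorm(effect_size / sqrt(2)).

#' Artifact specification for the synthetic generator
#'
#' @param n_flat Number of flat-channel artifacts to plant.
#' @param flat_duration_s Duration of each flat stretch (seconds).
#' @param n_decorrelated Number of channels replaced wholesale by independent
#'   white noise (breaking spatial correlation).
#' @param n_bursts Number of high-amplitude burst events.
#' @param burst_amplitude Burst amplitude as a multiple of the channel's
#'   background standard deviation.
#' @param burst_duration_s Duration of each burst (seconds).
#' @param burst_channels Number of channels each burst touches.
#' @param edge_margin_s Keep timed artifacts at least this far from either
#'   end of the recording (so they survive edge trimming).
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(n_flat = 0L, flat_duration_s = 6, n_decorrelated = 0L,
                          n_bursts = 0L, burst_amplitude = 50,
                          burst_duration_s = 0.5, burst_channels = 3L,
                          edge_margin_s = 0) {
  spec <- list(n_flat = as.integer(n_flat), flat_duration_s = flat_duration_s,
               n_decorrelated = as.integer(n_decorrelated),
               n_bursts = as.integer(n_bursts), burst_amplitude = burst_amplitude,
               burst_duration_s = burst_duration_s,
               burst_channels = as.integer(burst_channels),
               edge_margin_s = edge_margin_s)
  if (any(unlist(spec) < 0)) {
    stop_relbeta("artifact rates must be non-negative", "config_error")
  }
  class(spec) <- "artifact_spec"
  spec
}

#' Cohort simulation configuration
#'
#' Defaults are the documented recovery scenario: 134 subjects (93 women)
#' recorded twice at 250 Hz, an effect size on the log beta-amplitude factor
#' chosen so the analytic feature AUC is 0.75 (`sqrt(2) * qnorm(0.75)`), and
#' a pre/post factor correlation of 0.88.
#'
#' @param n_subjects Total number of subjects.
#' @param n_female Number of female subjects (0 < n_female < n_subjects).
#' @param fs Sampling rate in Hz (>= 100 so the 12-25 Hz band and the 40 Hz
#'   low-pass are representable).
#' @param duration_s Recording duration in seconds (> 60 so the 2 x 30 s
#'   edge trim leaves data).
#' @param effect_size Standardized mean difference (Cohen's d) of the log
#'   beta-amplitude factor between sexes (female minus male).
#' @param session_correlation Pearson correlation of the subject-level log
#'   beta factors across the pre/post sessions, in [0, 1].
#' @param band_amplitudes Named numeric vector with per-channel standard
#'   deviations (microvolts) of the `background`, `alpha` and `beta`
#'   components.
#' @param subject_log_sd Between-subject standard deviation of the log beta
#'   factor (default 0.35, i.e. about 35% amplitude variability).
#' @param sensor_noise_uv Standard deviation of independent sensor noise.
#' @param mixing_scale Length scale (chord units on the unit sphere) of the
#'   distance-dependent spatial correlation `exp(-(d/scale)^2)`.
#' @param artifact_spec An [artifact_spec()] applied to every recording.
#' @param seed Integer RNG seed; identical configs give bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 134L, n_female = 93L, fs = 250,
                       duration_s = 600, effect_size = sqrt(2) * stats::qnorm(0.75),
                       session_correlation = 0.88,
                       band_amplitudes = c(background = 20, alpha = 10, beta = 5),
                       subject_log_sd = 0.35, sensor_noise_uv = 1,
                       mixing_scale = 1.2,
                       artifact_spec = relbeta::artifact_spec(), seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_female = as.integer(n_female),
              fs = fs, duration_s = duration_s, effect_size = effect_size,
              session_correlation = session_correlation,
              band_amplitudes = band_amplitudes, subject_log_sd = subject_log_sd,
              sensor_noise_uv = sensor_noise_uv, mixing_scale = mixing_scale,
              artifact_spec = artifact_spec, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  check <- function(ok, what) {
    if (!ok) stop_relbeta(paste("invalid simulation config:", what), "config_error")
  }
  check(cfg$n_female > 0 && cfg$n_female < cfg$n_subjects,
        "0 < n_female < n_subjects is required")
  check(cfg$fs >= 100, "fs must be >= 100 Hz")
  check(cfg$duration_s > 60, "duration_s must exceed 60 s (2 x 30 s edge trim)")
  check(cfg$session_correlation >= 0 && cfg$session_correlation <= 1,
        "session_correlation must lie in [0, 1]")
  check(all(c("background", "alpha", "beta") %in% names(cfg$band_amplitudes)) &&
          all(cfg$band_amplitudes >= 0), "band_amplitudes must name background/alpha/beta, >= 0")
  check(cfg$subject_log_sd > 0, "subject_log_sd must be positive")
  invisible(cfg)
}

#' Subject profiles: sex, age and beta-amplitude factors
#'
#' Draws the subject-level structure of a cohort without synthesizing any
#' signals. The log beta factor is `mu_sex + sd * z`, where `z` shares a
#' subject random effect across sessions with weight
#' `sqrt(session_correlation)`, and `mu_female - mu_male` equals
#' `effect_size * sd`.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `subject_id`, `sex`, `age`,
#'   `beta_factor_pre`, `beta_factor_post`.
#' @export
simulate_profiles <- function(config) {
  validate_sim_config(config)
  n <- config$n_subjects
  set.seed(config$seed)
  sex <- c(rep("female", config$n_female), rep("male", n - config$n_female))
  age <- round(pmin(65, pmax(18, stats::rnorm(n, 46, 11.7))))
  rho <- config$session_correlation
  u <- stats::rnorm(n)
  z_pre <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
  z_post <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
  mu <- ifelse(sex == "female", config$effect_size * config$subject_log_sd, 0)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = sex, age = age,
    beta_factor_pre = exp(mu + config$subject_log_sd * z_pre),
    beta_factor_post = exp(mu + config$subject_log_sd * z_post),
    stringsAsFactors = FALSE
  )
}

# Spectral gains of the three components on the DFT grid. The 1/f^gamma
# background is flattened below 0.5 Hz to keep the variance finite.
component_gains <- function(n, fs, gamma = 1) {
  f <- (seq_len(n) - 1) * fs / n
  fa <- pmin(f, fs - f)
  pink <- pmax(fa, 0.5)^(-gamma / 2)
  pink[1] <- 0
  list(background = pink,
       alpha = as.numeric(fa >= 8 & fa < 12),
       beta = as.numeric(fa >= 12 & fa < 25))
}

# Stationary Gaussian noise with prescribed squared DFT gains, drawn
# directly in the frequency domain: x = Re(IDFT(Z * sqrt(G2))) with Z iid
# standard complex Gaussian, giving Var(x_t) = sum(G2) / n^2. One inverse
# FFT synthesizes the full channels x samples matrix.
spectral_noise <- function(n_ch, n, G2) {
  G <- sqrt(G2)
  Z <- matrix(complex(real = stats::rnorm(n * n_ch),
                      imaginary = stats::rnorm(n * n_ch)), n, n_ch)
  t(Re(stats::mvfft(Z * G, inverse = TRUE)) / n)
}

# lower-triangular mixing factor with distance-dependent channel correlation
spatial_mixing <- function(mon, scale) {
  d <- montage_distances(mon)
  C <- exp(-(d / scale)^2)
  L <- t(chol(C + diag(1e-9, nrow(C))))
  L
}

# One synthetic recording for a given beta factor; RNG state is taken as-is.
# The three mixed components are independent Gaussian processes sharing the
# spatial mixing, so their sum is synthesized in a single inverse FFT from
# the summed power spectra.
synth_recording <- function(mon, fs, duration_s, band_amplitudes, beta_factor,
                            sensor_noise_uv, mixing) {
  n_ch <- length(mon$labels)
  n <- round(fs * duration_s)
  gains <- component_gains(n, fs)
  amps <- c(background = band_amplitudes[["background"]],
            alpha = band_amplitudes[["alpha"]],
            beta = band_amplitudes[["beta"]] * beta_factor)
  G2 <- numeric(n)
  for (b in names(gains)) {
    gb2 <- gains[[b]]^2
    s <- sum(gb2)
    # per-band variance amp^2: sum of squared gains must equal n^2 * amp^2
    if (s > 0 && amps[[b]] > 0) G2 <- G2 + gb2 * (n^2 * amps[[b]]^2 / s)
  }
  mixed <- mixing %*% spectral_noise(n_ch, n, G2)
  noise <- matrix(stats::rnorm(n_ch * n, sd = sensor_noise_uv), n_ch, n)
  recording(mixed + noise, fs, mon$labels, montage = mon)
}

#' Simulate a paired pre/post EEG cohort
#'
#' @param config A [sim_config()].
#' @param montage Electrode montage; defaults to [standard_montage_1020()].
#' @return List with `pre` and `post` (lists of `eeg_recording`), `metadata`
#'   (one row per subject x session), `profiles` (the
#'   [simulate_profiles()] table) and `artifact_log` (per recording, the
#'   ground-truth log from [inject_artifacts()], `NULL` when no artifacts
#'   were requested).
#' @export
simulate_cohort <- function(config, montage = standard_montage_1020()) {
  validate_sim_config(config)
  profiles <- simulate_profiles(config)
  mixing <- spatial_mixing(montage, config$mixing_scale)
  n <- config$n_subjects
  spec <- config$artifact_spec
  has_art <- spec$n_flat > 0 || spec$n_decorrelated > 0 || spec$n_bursts > 0
  gen_session <- function(session) {
    factors <- if (session == "pre") profiles$beta_factor_pre else profiles$beta_factor_post
    lapply(seq_len(n), function(i) {
      rec <- synth_recording(montage, config$fs, config$duration_s,
                             config$band_amplitudes, factors[i],
                             config$sensor_noise_uv, mixing)
      if (has_art) {
        out <- inject_artifacts(rec, spec,
                                seed = config$seed + 7919L * i +
                                  ifelse(session == "post", 104729L, 0L))
        attr(out$recording, "artifact_log") <- out$log
        out$recording
      } else {
        rec
      }
    })
  }
  set.seed(config$seed + 1L)
  pre <- gen_session("pre")
  post <- gen_session("post")
  metadata <- rbind(
    data.frame(subject_id = profiles$subject_id, sex = profiles$sex,
               age = profiles$age, session = "pre", stringsAsFactors = FALSE),
    data.frame(subject_id = profiles$subject_id, sex = profiles$sex,
               age = profiles$age, session = "post", stringsAsFactors = FALSE)
  )
  art_log <- if (has_art) {
    list(pre = lapply(pre, attr, "artifact_log"),
         post = lapply(post, attr, "artifact_log"))
  } else NULL
  list(pre = pre, post = post, metadata = metadata, profiles = profiles,
       artifact_log = art_log)
}

#' Plant ground-truth artifacts into a recording
#'
#' Corrupts a copy of the recording with the defect classes the cleaning
#' chain targets -- flat channels, spatially decorrelated channels and
#' high-amplitude bursts -- and returns a machine-readable log usable as
#' ground truth.
#'
#' @param rec An `eeg_recording`.
#' @param spec An [artifact_spec()].
#' @param seed RNG seed for artifact placement.
#' @return List with `recording` (corrupted copy) and `log` (data frame with
#'   columns `type`, `channels` (comma-separated labels), `start_s`, `end_s`).
#' @export
inject_artifacts <- function(rec, spec, seed = 1L) {
  set.seed(seed)
  data <- rec$data
  n_ch <- nrow(data)
  n <- ncol(data)
  fs <- rec$fs
  log <- data.frame(type = character(0), channels = character(0),
                    start_s = numeric(0), end_s = numeric(0),
                    stringsAsFactors = FALSE)
  used <- integer(0)  # channels already corrupted channel-wide
  pick_ch <- function(k) {
    free <- setdiff(seq_len(n_ch), used)
    sample(free, k)
  }
  margin <- round(spec$edge_margin_s * fs)
  pick_start <- function(len) {
    lo <- margin + 1L
    hi <- n - len - margin
    if (hi < lo) stop_relbeta("recording too short for the artifact edge margin",
                              "config_error")
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  if (spec$n_flat > 0) {
    chs <- pick_ch(spec$n_flat)
    used <- c(used, chs)
    for (ch in chs) {
      len <- round(spec$flat_duration_s * fs)
      start <- pick_start(len)
      data[ch, start:(start + len - 1L)] <- data[ch, start]
      log <- rbind(log, data.frame(type = "flat", channels = rec$labels[ch],
                                   start_s = (start - 1) / fs,
                                   end_s = (start - 1 + len) / fs))
    }
  }
  if (spec$n_decorrelated > 0) {
    chs <- pick_ch(spec$n_decorrelated)
    used <- c(used, chs)
    for (ch in chs) {
      data[ch, ] <- stats::rnorm(n, sd = stats::sd(data[ch, ]))
      log <- rbind(log, data.frame(type = "decorrelated", channels = rec$labels[ch],
                                   start_s = 0, end_s = n / fs))
    }
  }
  if (spec$n_bursts > 0) {
    len <- round(spec$burst_duration_s * fs)
    for (b in seq_len(spec$n_bursts)) {
      chs <- sort(pick_ch(min(spec$burst_channels, n_ch - length(used))))
      start <- pick_start(len)
      win <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
      for (ch in chs) {
        amp <- spec$burst_amplitude * stats::sd(data[ch, ])
        data[ch, start:(start + len - 1L)] <-
          data[ch, start:(start + len - 1L)] + amp * win * stats::rnorm(len)
      }
      log <- rbind(log, data.frame(type = "burst",
                                   channels = paste(rec$labels[chs], collapse = ","),
                                   start_s = (start - 1) / fs,
                                   end_s = (start - 1 + len) / fs))
    }
  }
  list(recording = rec_with_data(rec, data), log = log)
}
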