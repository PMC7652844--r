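# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles so they never share code with the package paths they
# check.

# recording made of named per-channel generator functions of time (seconds)
make_recording <- function(fs, duration_s, channel_fns, montage = NULL) {
  t <- seq_len(round(fs * duration_s)) / fs
  data <- do.call(rbind, lapply(channel_fns, function(f) f(t)))
  recording(data, fs, names(channel_fns), montage = montage)
}

rms <- function(x) sqrt(mean(x^2))

# 19-channel synthetic recording from the generator, memoized per
# (seed, duration) so several tests can share one
.fixture_cache <- new.env(parent = emptyenv())
cohort_recording <- function(seed = 1, duration_s = 62) {
  key <- sprintf("rec_%d_%g", seed, duration_s)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(n_subjects = 2, n_female = 1, duration_s = duration_s,
                      seed = seed)
    .fixture_cache[[key]] <- simulate_cohort(cfg)$pre[[1]]
  }
  .fixture_cache[[key]]
}

# Mann-Whitney AUC oracle: concordant pairs plus half ties over n1*n2,
# counted directly
mw_auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent Newton-Raphson logistic MLE with analytic gradient and Hessian
newton_logistic_oracle <- function(x, y, tol = 1e-12, iters = 200) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- t(X) %*% (y - p)
    hess <- -t(X) %*% (X * (p * (1 - p)))
    step <- solve(hess, grad)
    beta <- beta - drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# exhaustive constrained-accuracy oracle: tries every cut between adjacent
# distinct scores (plus the extremes) with predict-positive-at->=-threshold
constrained_accuracy_oracle <- function(scores, y) {
  cuts <- c(sort(unique(scores)), Inf)
  best <- NA_real_
  for (th in cuts) {
    pred <- as.numeric(scores >= th)
    tpr <- sum(pred == 1 & y == 1) / sum(y == 1)
    fpr <- sum(pred == 1 & y == 0) / sum(y == 0)
    if (tpr > 0.5 && fpr < 0.5) {
      acc <- 100 * mean(pred == y)
      if (is.na(best) || acc > best) best <- acc
    }
  }
  best
}

# feature table built directly from subject-level factors (no EEG synthesis):
# every channel is a noisy monotone transform of the shared log beta factor
factor_feature_table <- function(n = 134, n_female = 93,
                                 d = sqrt(2) * qnorm(0.75), sd_log = 0.35,
                                 channel_noise = 0.05, seed = 1,
                                 sessions = "pre", rho = 0.88) {
  set.seed(seed)
  sex <- c(rep("female", n_female), rep("male", n - n_female))
  u <- rnorm(n)
  rows <- list()
  for (ses in sessions) {
    z <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
    logb <- ifelse(sex == "female", d * sd_log, 0) + sd_log * z
    ch <- vapply(1:19, function(j) plogis(logb + rnorm(n, sd = channel_noise)),
                 numeric(n))
    colnames(ch) <- standard_montage_1020()$labels
    tab <- data.frame(subject_id = sprintf("S%03d", 1:n), session = ses,
                      sex = sex, age = 40L, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(ch))
    tab$mean_relative_beta <- rowMeans(ch)
    rows[[ses]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
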