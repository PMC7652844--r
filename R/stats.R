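# Non-parametric group comparisons and pre/post consistency statistics.

new_test_result <- function(statistic, p_value, n, method, p_adjusted = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g%s (n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (!is.na(x$p_adjusted)) sprintf(", p_adj = %.4g", x$p_adjusted) else "",
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Midrank tie handling throughout. For combined sample sizes up to
#' `exact_max_n` the two-sided p-value is exact, from complete enumeration
#' of the permutation distribution of the U statistic (valid with ties);
#' above that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_max_n Enumeration threshold on `length(x) + length(y)`.
#' @return A `test_result` with the Mann-Whitney U of `x` as statistic.
#' @export
wilcoxon_ranksum <- function(x, y, exact_max_n = 20L) {
  m <- length(x)
  n <- length(y)
  if (m == 0L || n == 0L) stop_relbeta("both samples must be non-empty",
                                       "degenerate_input")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  if (N <= exact_max_n) {
    subsets <- utils::combn(N, m)
    usims <- colSums(matrix(r[subsets], nrow = m)) - m * (m + 1) / 2
    p_lo <- mean(usims <= u + 1e-9)
    p_hi <- mean(usims >= u - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    mu <- m * n / 2
    ties <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    p <- min(1, p)
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  new_test_result(u, p, c(m, n), method)
}

#' Bonferroni correction
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_relbeta("p-values must lie in [0, 1]", "validation_error")
  }
  if (m < length(p_values)) {
    stop_relbeta("family size m must be >= number of p-values", "validation_error")
  }
  pmin(1, m * p_values)
}

#' Per-electrode sex differences
#'
#' Rank-sum test of the per-channel relative beta power between sexes for
#' one session, Bonferroni-adjusted within the session (m = 19 by default;
#' set `m = 38` to treat both sessions as one family).
#'
#' @param table A `feature_table`.
#' @param session Session to test.
#' @param m Bonferroni family size (defaults to the channel count).
#' @return Data frame: `channel`, `statistic`, `p_value`, `p_adjusted`,
#'   `direction` (sign of the female-minus-male median difference).
#' @export
electrodewise_sex_tests <- function(table, session, m = NULL) {
  tab <- table[table$session == session & !is.na(table$mean_relative_beta), ,
               drop = FALSE]
  if (length(unique(tab$sex)) < 2L) {
    stop_relbeta("both sexes must be present", "degenerate_input")
  }
  chans <- feature_channels(table)
  if (is.null(m)) m <- length(chans)
  res <- lapply(chans, function(ch) {
    f <- tab[tab$sex == "female", ch]
    ml <- tab[tab$sex == "male", ch]
    t <- wilcoxon_ranksum(f, ml)
    data.frame(channel = ch, statistic = t$statistic, p_value = t$p_value,
               direction = sign(stats::median(f) - stats::median(ml)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_value, m)
  out[, c("channel", "statistic", "p_value", "p_adjusted", "direction")]
}

#' Paired t-test
#'
#' @param pre,post Paired numeric vectors (same subjects, same order).
#' @return A `test_result`.
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop_relbeta("pre and post must be paired (equal lengths)", "alignment_error")
  }
  d <- pre - post
  if (stats::sd(d) == 0) {
    stop_relbeta("differences have zero variance", "degenerate_variance")
  }
  t <- stats::t.test(pre, post, paired = TRUE)
  new_test_result(unname(t$statistic), t$p.value,
                  length(pre), "paired t-test")
}

#' Pearson correlation across sessions
#'
#' @param pre,post Paired numeric vectors (n >= 3).
#' @return List with `r` and `p` (two-sided, from the t transform).
#' @export
session_correlation <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 3L) {
    stop_relbeta("need >= 3 aligned pairs", "alignment_error")
  }
  if (stats::sd(pre) == 0 || stats::sd(post) == 0) {
    stop_relbeta("zero variance in a session vector", "degenerate_variance")
  }
  ct <- stats::cor.test(pre, post, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-channel pre/post correlations from a feature table
#'
#' Pairs the sessions by subject, drops subjects missing either session and
#' returns the per-channel Pearson correlations along with the mean-feature
#' correlation.
#'
#' @param table A `feature_table` containing sessions `pre` and `post`.
#' @return List with `mean_feature` (`r`, `p`), `per_channel` (named r
#'   vector), `mean_r`, `sd_r`.
#' @export
channel_session_correlations <- function(table) {
  pre <- table[table$session == "pre", , drop = FALSE]
  post <- table[table$session == "post", , drop = FALSE]
  common <- intersect(pre$subject_id, post$subject_id)
  pre <- pre[match(common, pre$subject_id), , drop = FALSE]
  post <- post[match(common, post$subject_id), , drop = FALSE]
  ok <- !is.na(pre$mean_relative_beta) & !is.na(post$mean_relative_beta)
  pre <- pre[ok, , drop = FALSE]
  post <- post[ok, , drop = FALSE]
  chans <- feature_channels(table)
  per <- vapply(chans, function(ch) stats::cor(pre[[ch]], post[[ch]]), numeric(1))
  list(mean_feature = session_correlation(pre$mean_relative_beta,
                                          post$mean_relative_beta),
       per_channel = per, mean_r = mean(per), sd_r = stats::sd(per))
}

#' Misclassification overlap across sessions
#'
#' Counts the subjects misclassified before treatment and, of those, how
#' many are also misclassified after.
#'
#' @param pred_pre,pred_post Predicted class labels per subject, aligned.
#' @param labels True class labels, same order.
#' @return List with `n_wrong_pre` and `n_overlap`.
#' @export
misclassification_overlap <- function(pred_pre, pred_post, labels) {
  if (length(pred_pre) != length(labels) || length(pred_post) != length(labels)) {
    stop_relbeta("predictions and labels must be aligned", "alignment_error")
  }
  wrong_pre <- pred_pre != labels
  wrong_post <- pred_post != labels
  list(n_wrong_pre = sum(wrong_pre), n_overlap = sum(wrong_pre & wrong_post))
}
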