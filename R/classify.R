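# Logistic models and their evaluation: ROC curves, AUC, constrained maximum
# accuracy, balanced-subsample averaged ROC and leave-one-out validation.
# Throughout, the positive class is the minority class: men.

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares with convergence tolerance 1e-8 and
#' at most 100 iterations. When the fit fails to converge (the signature of
#' separation), the model is refitted with a tiny quadratic penalty (1e-8)
#' and flagged.
#'
#' @param x Feature matrix (n x p) or vector; no missing values.
#' @param y Binary response: 0/1 numeric, or logical.
#' @param ridge Quadratic penalty; 0 gives the plain ML fit.
#' @param tol Convergence tolerance on the coefficient update.
#' @param max_iter Iteration cap.
#' @return A list of class `logistic_model` with `coefficients` (intercept
#'   first), `converged`, `separable`, `n_iter`.
#' @export
fit_logistic <- function(x, y, ridge = 0, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop_relbeta("missing values in fit_logistic", "fit_error")
  if (length(unique(y)) < 2L) {
    stop_relbeta("labels contain a single class", "degenerate_labels")
  }
  X <- cbind(1, x)
  xnames <- if (ncol(x) == 0L) character(0) else
    if (!is.null(colnames(x))) colnames(x) else paste0("x", seq_len(ncol(x)))
  colnames(X) <- c("(Intercept)", xnames)
  irls <- function(lambda, iters) {
    beta <- numeric(ncol(X))
    pen <- diag(lambda, ncol(X))
    for (it in seq_len(iters)) {
      eta <- drop(X %*% beta)
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-12)
      H <- crossprod(X, X * w) + pen
      g <- crossprod(X, y - p) - lambda * beta
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) return(list(beta = beta, converged = FALSE, n_iter = it))
      beta <- beta + drop(step)
      if (max(abs(step)) < tol) {
        return(list(beta = beta, converged = TRUE, n_iter = it))
      }
    }
    list(beta = beta, converged = FALSE, n_iter = iters)
  }
  fit <- irls(ridge, max_iter)
  separable <- FALSE
  if (!fit$converged || max(abs(fit$beta)) > 1e8) {
    separable <- TRUE
    fit <- irls(ridge + 1e-8, 200L)
  }
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 converged = fit$converged && !separable,
                 separable = separable, n_iter = fit$n_iter),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model>", if (x$separable) "(separation detected, tiny-ridge fit)",
      "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predicted probabilities from a logistic model
#' @param object A `logistic_model`.
#' @param newdata Feature matrix or vector matching the fitted features.
#' @param ... Unused.
#' @return Vector of probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  stats::plogis(drop(X %*% object$coefficients))
}

# labels -> 0/1 with the positive class as 1
encode_labels <- function(labels, positive_class = "male") {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop_relbeta("numeric labels must be 0/1", "label_error")
    }
    return(labels)
  }
  as.numeric(as.character(labels) == positive_class)
}

#' ROC curve
#'
#' Operating points at every distinct score threshold (classify positive
#' when score >= threshold) plus the all-negative endpoint. Tied scores
#' collapse into a single diagonal step. The positive class defaults to the
#' minority-class convention: men.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Class labels (0/1, logical, or values matched against
#'   `positive_class`).
#' @param positive_class Label treated as positive.
#' @return Data frame of class `roc_curve` with columns `threshold`
#'   (strictly decreasing, starting at Inf), `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, positive_class = "male") {
  y <- encode_labels(labels, positive_class)
  if (length(unique(y)) < 2L) {
    stop_relbeta("both classes must be present", "degenerate_labels")
  }
  if (length(scores) != length(y)) {
    stop_relbeta("scores and labels differ in length", "label_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  uniq <- !duplicated(s)
  cpos <- cumsum(yy)
  cneg <- cumsum(1 - yy)
  # at threshold s_k (a distinct value), everything with score >= s_k is positive:
  # take cumulative counts at the LAST index of each tied block
  last <- c(which(uniq)[-1] - 1L, length(s))
  n_pos <- sum(yy)
  n_neg <- length(yy) - n_pos
  out <- data.frame(threshold = c(Inf, s[uniq]),
                    fpr = c(0, cneg[last] / n_neg),
                    tpr = c(0, cpos[last] / n_pos))
  attr(out, "positive_class") <- positive_class
  attr(out, "n") <- c(pos = n_pos, neg = n_neg)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal area; for curves built by [roc_curve()] this equals the
#' normalized Mann-Whitney U statistic (concordant pairs plus half ties over
#' n_pos x n_neg).
#'
#' @param curve A `roc_curve`.
#' @return AUC in [0, 1].
#' @export
auc <- function(curve) {
  f <- curve$fpr
  t <- curve$tpr
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

#' Constrained maximum accuracy
#'
#' Among thresholds whose true positive rate exceeds 50% and false positive
#' rate stays below 50% (both strict), returns the maximum overall pooled
#' accuracy and the threshold attaining it. Accuracy ties are broken by
#' maximal Youden J, then by the larger threshold. When no threshold is
#' feasible the result is flagged rather than silently dropped.
#'
#' @param scores,labels,positive_class As in [roc_curve()].
#' @return List with `accuracy` (percent, NA when infeasible), `threshold`,
#'   `feasible`, `tpr`, `fpr`.
#' @export
constrained_max_accuracy <- function(scores, labels, positive_class = "male") {
  curve <- roc_curve(scores, labels, positive_class)
  n <- attr(curve, "n")
  feasible <- curve$tpr > 0.5 & curve$fpr < 0.5
  if (!any(feasible)) {
    return(list(accuracy = NA_real_, threshold = NA_real_, feasible = FALSE,
                tpr = NA_real_, fpr = NA_real_))
  }
  cf <- curve[feasible, , drop = FALSE]
  acc <- (cf$tpr * n[["pos"]] + (1 - cf$fpr) * n[["neg"]]) / sum(n)
  j <- cf$tpr - cf$fpr
  best <- order(-acc, -j, -cf$threshold)[1]
  list(accuracy = 100 * acc[best], threshold = cf$threshold[best],
       feasible = TRUE, tpr = cf$tpr[best], fpr = cf$fpr[best])
}

#' Balanced-resampling configuration
#'
#' @param n_iterations Number of balanced subsamples (default 100).
#' @param per_class_n Subjects drawn per class per iteration (default 40).
#' @param seed Global seed; iteration i uses `seed + i`.
#' @param fpr_grid Number of fixed FPR points for vertical curve averaging.
#' @return List of class `resample_config`.
#' @export
resample_config <- function(n_iterations = 100L, per_class_n = 40L, seed = 1L,
                            fpr_grid = 101L) {
  if (n_iterations < 1L) stop_relbeta("n_iterations must be >= 1", "config_error")
  structure(list(n_iterations = as.integer(n_iterations),
                 per_class_n = as.integer(per_class_n), seed = as.integer(seed),
                 fpr_grid = as.integer(fpr_grid)), class = "resample_config")
}

interp_tpr <- function(curve, grid) {
  stats::approx(curve$fpr, curve$tpr, xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

#' Balanced-subsample averaged ROC
#'
#' Repeatedly samples `per_class_n` subjects per class without replacement,
#' fits the logistic model, builds a ROC curve and vertically averages the
#' curves on a fixed FPR grid. Scores are in-sample by default; with
#' `scheme = "loocv"` each subsample is scored by leave-one-out.
#'
#' @param x Feature matrix or vector.
#' @param labels Class labels.
#' @param config A [resample_config()].
#' @param scheme `"insample"` or `"loocv"` scoring within each subsample.
#' @param positive_class Positive class label.
#' @return List with `mean_curve` (fpr/tpr data frame), `auc_mean_curve`,
#'   `auc_iterations` (per-iteration AUC vector), `accuracy_iterations`
#'   (per-iteration constrained accuracies, NA when infeasible).
#' @export
balanced_subsample_mean_roc <- function(x, labels, config = resample_config(),
                                        scheme = c("insample", "loocv"),
                                        positive_class = "male") {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  y <- encode_labels(labels, positive_class)
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  if (min(length(idx_pos), length(idx_neg)) < config$per_class_n) {
    stop_relbeta("a class has fewer members than per_class_n", "config_error")
  }
  grid <- seq(0, 1, length.out = config$fpr_grid)
  tprs <- matrix(NA_real_, config$n_iterations, config$fpr_grid)
  aucs <- numeric(config$n_iterations)
  accs <- numeric(config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    set.seed(config$seed + i)
    sel <- c(sample(idx_pos, config$per_class_n),
             sample(idx_neg, config$per_class_n))
    xi <- x[sel, , drop = FALSE]
    yi <- y[sel]
    scores <- if (scheme == "insample") {
      predict(fit_logistic(xi, yi), xi)
    } else {
      loocv_scores(xi, yi)
    }
    curve <- roc_curve(scores, yi, positive_class = 1)
    tprs[i, ] <- interp_tpr(curve, grid)
    aucs[i] <- auc(curve)
    accs[i] <- constrained_max_accuracy(scores, yi, positive_class = 1)$accuracy
  }
  mean_curve <- data.frame(fpr = grid, tpr = colMeans(tprs))
  auc_mean <- sum(diff(grid) * (utils::head(mean_curve$tpr, -1) +
                                  utils::tail(mean_curve$tpr, -1)) / 2)
  list(mean_curve = mean_curve, auc_mean_curve = auc_mean,
       auc_iterations = aucs, accuracy_iterations = accs)
}

#' Leave-one-out cross-validated scores
#'
#' For each observation, fits the model on the remaining n-1 and returns the
#' held-out predicted probability, in the original order.
#'
#' @param x Feature matrix or vector.
#' @param labels Class labels (both classes need >= 3 members).
#' @param positive_class Positive class label.
#' @return Vector of out-of-sample probabilities.
#' @export
loocv_scores <- function(x, labels, positive_class = "male") {
  x <- as.matrix(x)
  y <- encode_labels(labels, positive_class)
  if (min(table(y)) < 3L) {
    stop_relbeta("leave-one-out needs at least 3 members per class",
                 "degenerate_fold")
  }
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    if (length(unique(yt)) < 2L) {
      stop_relbeta("a leave-one-out fold has a single-class training set",
                   "degenerate_fold")
    }
    fit <- fit_logistic(x[-i, , drop = FALSE], yt)
    out[i] <- predict(fit, x[i, , drop = FALSE])
  }
  out
}

#' Rank-sum channel selection
#'
#' Ranks channels by the rank-sum test p-value of the class difference on
#' the supplied (training) data and returns the `k` smallest; ties are
#' broken by channel order. Intended to run inside each cross-validation
#' fold so that selection never sees held-out data.
#'
#' @param x Training feature matrix (columns = channels).
#' @param labels Training class labels.
#' @param k Number of channels to keep, between 1 and ncol(x).
#' @param positive_class Positive class label.
#' @return Sorted integer vector of the selected column indices (so k = ncol
#'   is the identity selection).
#' @export
rank_select_channels <- function(x, labels, k, positive_class = "male") {
  x <- as.matrix(x)
  if (k < 1L || k > ncol(x)) {
    stop_relbeta("k must lie between 1 and the number of channels", "config_error")
  }
  y <- encode_labels(labels, positive_class)
  p <- vapply(seq_len(ncol(x)), function(j) {
    wilcoxon_ranksum(x[y == 1, j], x[y == 0, j])$p_value
  }, numeric(1))
  sort(order(p, seq_along(p))[seq_len(k)])
}

#' Evaluate the six-model grid
#'
#' Reproduces the evaluation grid on a feature table: the mean-beta feature
#' and the 19-channel feature set, each as a full in-sample fit and as a
#' balanced-subsample averaged model, plus leave-one-out validation (plain
#' and balanced) for the all-channels model -- per session.
#'
#' @param table A `feature_table`.
#' @param config A [resample_config()].
#' @param sessions Sessions to evaluate (defaults to those present).
#' @return Data frame of class `eval_grid`: one row per model/session cell
#'   with `auc`, `auc_iterations_mean` (balanced rows), `accuracy_pct`,
#'   `threshold`, `feasible`, `n`, `n_iterations`.
#' @export
evaluate_models <- function(table, config = resample_config(), sessions = NULL) {
  if (is.null(sessions)) sessions <- unique(table$session)
  chans <- feature_channels(table)
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (ses in sessions) {
    tab <- table[table$session == ses & !is.na(table$mean_relative_beta), ,
                 drop = FALSE]
    if (!nrow(tab) || length(unique(tab$sex)) < 2L) {
      emit(model = "mean", scheme = "insample", session = ses, auc = NA_real_,
           auc_iterations_mean = NA_real_, accuracy_pct = NA_real_,
           threshold = NA_real_, feasible = NA, n = nrow(tab),
           n_iterations = NA_integer_)
      next
    }
    y <- tab$sex
    xm <- tab$mean_relative_beta
    xc <- as.matrix(tab[, chans, drop = FALSE])
    insample <- function(model, x) {
      fit <- fit_logistic(x, encode_labels(y))
      scores <- predict(fit, x)
      cma <- constrained_max_accuracy(scores, y)
      emit(model = model, scheme = "insample", session = ses,
           auc = auc(roc_curve(scores, y)), auc_iterations_mean = NA_real_,
           accuracy_pct = cma$accuracy, threshold = cma$threshold,
           feasible = cma$feasible, n = nrow(tab), n_iterations = NA_integer_)
    }
    balanced <- function(model, x, scheme) {
      b <- balanced_subsample_mean_roc(x, y, config, scheme = scheme)
      emit(model = model,
           scheme = paste0("balanced", if (scheme == "loocv") "+loocv" else ""),
           session = ses, auc = b$auc_mean_curve,
           auc_iterations_mean = mean(b$auc_iterations),
           accuracy_pct = mean(b$accuracy_iterations, na.rm = TRUE),
           threshold = NA_real_, feasible = any(!is.na(b$accuracy_iterations)),
           n = 2L * config$per_class_n, n_iterations = config$n_iterations)
    }
    insample("mean", xm)
    balanced("mean", xm, "insample")
    insample("channels", xc)
    balanced("channels", xc, "insample")
    scores_loo <- loocv_scores(xc, y)
    cma <- constrained_max_accuracy(scores_loo, y)
    emit(model = "channels", scheme = "loocv", session = ses,
         auc = auc(roc_curve(scores_loo, y)), auc_iterations_mean = NA_real_,
         accuracy_pct = cma$accuracy, threshold = cma$threshold,
         feasible = cma$feasible, n = nrow(tab), n_iterations = NA_integer_)
    balanced("channels", xc, "loocv")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_grid", "data.frame")
  out
}
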