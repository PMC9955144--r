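as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  abort_avs("avs_invalid_input",
            "`labels` must be logical or 0/1 (TRUE/1 = positive class)")
}

#' Empirical ROC curve
#'
#' Builds the ROC curve of a score against a binary label, with candidate
#' thresholds at every distinct observed score (ties grouped at one
#' threshold) plus the strict endpoint at which nothing is called positive.
#' Thresholding is inclusive: with `direction = "higher_is_positive"` a score
#' at or above the threshold is called positive; with
#' `"lower_is_positive"`, at or below. Points are ordered from strictest
#' (sensitivity 0, specificity 1) to loosest (sensitivity 1, specificity 0),
#' so sensitivity is non-decreasing down the table.
#'
#' @param scores Numeric vector of finite scores.
#' @param labels Logical or 0/1 vector; `TRUE`/1 marks the positive class.
#'   Both classes must be present.
#' @param direction Which tail of the score marks the positive class.
#' @return A data frame of class `avs_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, `lr_positive` (the positive likelihood
#'   ratio sens/(1-spec); `Inf` at perfect-specificity points with positive
#'   sensitivity, `NaN` at the degenerate 0/0 endpoint), and attributes
#'   `direction`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_curve <- function(scores, labels,
                      direction = c("higher_is_positive", "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    abort_avs("avs_invalid_input", "`scores` and `labels` differ in length")
  }
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    abort_avs("avs_invalid_input", "`scores` must be finite numeric")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort_avs("avs_degenerate_labels",
              "need at least one positive and one negative label")
  }
  dec <- direction == "higher_is_positive"
  o <- order(scores, decreasing = dec)
  s <- scores[o]; l <- labels[o]
  first <- c(TRUE, s[-1L] != s[-length(s)])
  grp <- cumsum(first)
  tp_by <- as.vector(rowsum(as.numeric(l), grp))
  n_by <- as.vector(rowsum(rep(1, length(l)), grp))
  sens <- cumsum(tp_by) / n_pos
  spec <- 1 - cumsum(n_by - tp_by) / n_neg
  thr <- c(if (dec) Inf else -Inf, s[first])
  sens <- c(0, sens); spec <- c(1, spec)
  lr <- ifelse(spec < 1, sens / (1 - spec), ifelse(sens > 0, Inf, NaN))
  structure(
    data.frame(threshold = thr, sensitivity = sens, specificity = spec,
               lr_positive = lr),
    class = c("avs_roc", "data.frame"),
    direction = direction, n_pos = n_pos, n_neg = n_neg
  )
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve as the Mann-Whitney concordance probability:
#' (concordant pairs + half the tied pairs) / (n_pos * n_neg), computed from
#' midranks. Identical to the trapezoidal area under [roc_curve()] (ties
#' grouped), but O(n log n).
#'
#' @inheritParams roc_curve
#' @return The AUC, in `[0, 1]`.
#' @examples
#' auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' @export
auc_rank <- function(scores, labels,
                     direction = c("higher_is_positive", "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    abort_avs("avs_invalid_input", "`scores` must be finite numeric")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort_avs("avs_degenerate_labels",
              "need at least one positive and one negative label")
  }
  r <- rank(scores)
  a <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) /
    (as.numeric(n_pos) * as.numeric(n_neg))
  if (direction == "lower_is_positive") 1 - a else a
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve An [roc_curve()] result.
#' @return The trapezoidal AUC; equals [auc_rank()] on the same data.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "avs_roc"))
  fpr <- 1 - curve$specificity
  sens <- curve$sensitivity
  sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
}

#' Likelihood-ratio-maximizing threshold
#'
#' Selects the ROC point maximizing the positive likelihood ratio
#' sens/(1-spec) among points with specificity below 1 and sensitivity above
#' 0 (points with perfect specificity have an infinite likelihood ratio and
#' are excluded; the degenerate 0/0 endpoint likewise). Ties are broken
#' toward higher sensitivity, then toward the less extreme threshold (the one
#' further from the strict end of the score range).
#'
#' @param curve An [roc_curve()] result.
#' @return A list of class `avs_threshold_choice` with `threshold`,
#'   `sensitivity`, `specificity`, `lr_positive`.
#' @export
best_threshold_by_lr <- function(curve) {
  stopifnot(inherits(curve, "avs_roc"))
  ok <- which(curve$specificity < 1 & curve$sensitivity > 0)
  if (!length(ok)) {
    abort_avs("avs_no_finite_lr",
              "no ROC point has a finite positive likelihood ratio")
  }
  lr <- curve$lr_positive[ok]
  cand <- ok[lr >= max(lr) * (1 - 1e-9)]
  sens <- curve$sensitivity[cand]
  cand <- cand[sens >= max(sens) * (1 - 1e-9)]
  thr <- curve$threshold[cand]
  pick <- if (attr(curve, "direction") == "higher_is_positive") {
    cand[which.min(thr)]
  } else {
    cand[which.max(thr)]
  }
  structure(list(threshold = curve$threshold[pick],
                 sensitivity = curve$sensitivity[pick],
                 specificity = curve$specificity[pick],
                 lr_positive = curve$lr_positive[pick]),
            class = "avs_threshold_choice")
}

#' @export
print.avs_threshold_choice <- function(x, ...) {
  cat(sprintf("threshold %.4g: sens %.3f, spec %.3f, LR+ %.3g\n",
              x$threshold, x$sensitivity, x$specificity, x$lr_positive))
  invisible(x)
}

#' Sensitivity and specificity at an arbitrary cutoff
#'
#' Evaluates the curve's inclusive decision rule at a given cutoff, which
#' need not be one of the observed scores: the positive call is
#' `score >= threshold` (or `<=` for `lower_is_positive`).
#'
#' @param curve An [roc_curve()] result.
#' @param threshold Cutoff value.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sens_spec_at <- function(curve, threshold) {
  stopifnot(inherits(curve, "avs_roc"), is.numeric(threshold),
            length(threshold) == 1L)
  thr <- curve$threshold
  fin <- is.finite(thr)
  idx <- if (attr(curve, "direction") == "higher_is_positive") {
    cand <- which(fin & thr >= threshold)
    if (length(cand)) cand[which.min(thr[cand])] else NA_integer_
  } else {
    cand <- which(fin & thr <= threshold)
    if (length(cand)) cand[which.max(thr[cand])] else NA_integer_
  }
  if (is.na(idx)) {
    c(sensitivity = 0, specificity = 1)
  } else {
    c(sensitivity = curve$sensitivity[idx], specificity = curve$specificity[idx])
  }
}

#' Closed-form AUC for two lognormal score distributions
#'
#' When positive and negative scores are lognormal the AUC has the binormal
#' closed form `pnorm((mu_pos - mu_neg) / sqrt(sigma_pos^2 + sigma_neg^2))`
#' on the log scale (sign flipped when lower scores mark the positive class).
#' Serves as an analytic oracle for the empirical rank AUC on simulated
#' cohorts.
#'
#' @param params_pos,params_neg [lognormal_from_moments()] objects (or lists
#'   with elements `mu`, `sigma`) for the positive and negative classes.
#' @param direction As in [roc_curve()].
#' @return The AUC, in `(0, 1)`.
#' @export
binormal_auc_lognormal <- function(params_pos, params_neg,
                                   direction = c("higher_is_positive",
                                                 "lower_is_positive")) {
  direction <- match.arg(direction)
  for (p in list(params_pos, params_neg)) {
    if (!is.numeric(p$sigma) || p$sigma <= 0 || !is.finite(p$sigma)) {
      abort_avs("avs_invalid_parameter", "`sigma` must be positive and finite")
    }
  }
  d <- (params_pos$mu - params_neg$mu) /
    sqrt(params_pos$sigma^2 + params_neg$sigma^2)
  if (direction == "lower_is_positive") d <- -d
  stats::pnorm(d)
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' U statistic with midrank ties. The two-sided p-value uses exact
#' enumeration of the permutation distribution when the combined sample size
#' is at most 12 (`method = "auto"`), and otherwise a moderated normal
#' approximation: the tie-corrected, continuity-corrected z statistic
#' evaluated as the average of the Gaussian and Student-t tail areas (Iman,
#' 1976), which tracks the exact permutation p-value markedly better at
#' moderate sample sizes than the plain normal tail.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param method `"auto"` (exact when combined n <= 12), `"exact"`, or
#'   `"normal"`.
#' @return A list of class `avs_rank_sum` with `statistic` (U for
#'   `group_a`), `p_value`, `method_used`, and group sizes.
#' @examples
#' rank_sum_test(1:4, 5:8) # complete separation, exact p = 2/70
#' @export
rank_sum_test <- function(group_a, group_b,
                          method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(group_a) || !length(group_b) ||
      !is.numeric(group_a) || !is.numeric(group_b) ||
      anyNA(group_a) || anyNA(group_b)) {
    abort_avs("avs_invalid_input", "both groups must be non-empty and free of NA")
  }
  na <- length(group_a); nb <- length(group_b); N <- na + nb
  r <- rank(c(group_a, group_b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (method == "auto") method <- if (N <= 12L) "exact" else "normal"

  if (method == "exact") {
    if (choose(N, na) > 5e5) {
      abort_avs("avs_invalid_input",
                "exact enumeration infeasible at this sample size; use method = \"normal\"")
    }
    subsets <- utils::combn(N, na)
    us <- colSums(matrix(r[subsets], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-9)
  } else {
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    s <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    if (s == 0) {
      p <- 1
    } else {
      z <- max((abs(u_a - mu) - 0.5) / s, 0)
      df <- max(N - 2, 1)
      tstat <- z * sqrt(df / max(N - 1 - z^2, 1e-12))
      p <- min(1, stats::pnorm(-z) + stats::pt(-tstat, df = df))
    }
  }
  structure(list(statistic = c(U = u_a), p_value = p, method_used = method,
                 n = c(a = na, b = nb)),
            class = "avs_rank_sum")
}

#' @export
print.avs_rank_sum <- function(x, ...) {
  cat(sprintf("rank-sum test: U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n[["a"]], x$n[["b"]], x$p_value, x$method_used))
  invisible(x)
}
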