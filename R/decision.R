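# ROC construction, DeLong inference, operating points, confusion-matrix
# reconstruction, and logistic models.
#
# Rule direction is explicit per metric: for "low_predicts_positive" the
# classifier calls score <= cutoff positive (the natural rule for ADC-type
# markers, where restriction predicts disease); for
# "high_predicts_positive", score >= cutoff.
# Internally scores are oriented so that higher means more likely positive,
# and cutoffs are mapped back for reporting.

RULE_DIRECTIONS <- c("high_predicts_positive", "low_predicts_positive")

#' Empirical ROC curve
#'
#' Sweeps all unique score values as candidate cutoffs and records the
#' achieved sensitivity/specificity at each, plus the degenerate endpoints
#' (0,1) and (1,0).
#'
#' @param scores Numeric marker values.
#' @param labels Binary outcome (0/1 or logical); both classes must be
#'   present.
#' @param rule_direction `"low_predicts_positive"` (score <= cutoff calls
#'   positive) or `"high_predicts_positive"` (score >= cutoff).
#' @return An object of class `roc_curve`: data frame `points` with
#'   `cutoff`, `sensitivity`, `specificity`, plus `n_pos`, `n_neg`,
#'   `rule_direction`, and the oriented scores/labels.
#' @export
roc_curve <- function(scores, labels,
                      rule_direction = c("high_predicts_positive",
                                         "low_predicts_positive")) {
  rule_direction <- match.arg(rule_direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep])
  labels <- as.integer(labels[keep] != 0)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("insufficient-data error: both classes must be present",
         call. = FALSE)
  # orient so that higher oriented score predicts positive
  oriented <- if (rule_direction == "low_predicts_positive") -scores
              else scores
  cuts <- sort(unique(scores))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred_pos <- if (rule_direction == "low_predicts_positive")
      scores <= cuts[i] else scores >= cuts[i]
    sens[i] <- sum(pred_pos & labels == 1L) / n_pos
    spec[i] <- sum(!pred_pos & labels == 0L) / n_neg
  }
  pts <- data.frame(cutoff = cuts, sensitivity = sens, specificity = spec)
  # degenerate endpoints: call everything negative / everything positive
  pts <- rbind(pts, data.frame(cutoff = c(Inf, -Inf) *
                                 (if (rule_direction ==
                                      "low_predicts_positive") -1 else 1),
                               sensitivity = c(0, 1),
                               specificity = c(1, 0)))
  pts <- pts[order(-pts$sensitivity, pts$specificity), ]
  pts <- pts[!duplicated(pts[c("sensitivity", "specificity")]), ]
  rownames(pts) <- NULL
  structure(list(points = pts, n_pos = n_pos, n_neg = n_neg,
                 rule_direction = rule_direction,
                 scores = scores, labels = labels, oriented = oriented),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d positives / %d negatives, rule %s, AUC %.3f\n",
              x$n_pos, x$n_neg, x$rule_direction, auc(x)))
  invisible(x)
}

# Mann-Whitney AUC estimator with tie weight 1/2, on oriented scores
auc_mw <- function(oriented, labels) {
  x <- oriented[labels == 1L]  # positives
  y <- oriented[labels == 0L]
  r <- rank(c(x, y))
  n1 <- length(x); n0 <- length(y)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' @param curve A [roc_curve()].
#' @return The empirical AUC (Mann-Whitney estimator, ties weighted 1/2).
#' @export
auc <- function(curve) auc_mw(curve$oriented, curve$labels)

# DeLong placement values for one marker: V10 (per positive), V01 (per
# negative), computed on oriented scores
delong_placements <- function(oriented, labels) {
  x <- oriented[labels == 1L]
  y <- oriented[labels == 0L]
  m <- length(x); n <- length(y)
  # psi(x, y) = 1 if x > y, 1/2 if tie, 0 otherwise
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp), m = m, n = n)
}

#' DeLong inference for a single AUC
#'
#' AUC with its DeLong variance (placement-value decomposition), Wald 95%
#' confidence interval truncated to \[0, 1\], and a two-sided p-value
#' against the null AUC = 0.5. When the empirical variance is zero
#' (e.g. perfect separation) the CI collapses to the point estimate and the
#' result carries `degenerate = TRUE`.
#'
#' @param curve A [roc_curve()] with at least 2 cases per class.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `auc`, `ci_low`, `ci_high`, `p_vs_half`, `variance`,
#'   `degenerate`.
#' @export
delong_auc_inference <- function(curve, conf_level = 0.95) {
  if (curve$n_pos < 2L || curve$n_neg < 2L)
    stop("insufficient-data error: need >= 2 cases per class",
         call. = FALSE)
  pl <- delong_placements(curve$oriented, curve$labels)
  s10 <- stats::var(pl$v10)
  s01 <- stats::var(pl$v01)
  v <- s10 / pl$m + s01 / pl$n
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (v <= 0) {
    return(list(auc = pl$auc, ci_low = pl$auc, ci_high = pl$auc,
                p_vs_half = if (pl$auc == 0.5) 1 else
                  .Machine$double.xmin,
                variance = 0, degenerate = TRUE))
  }
  se <- sqrt(v)
  list(auc = pl$auc,
       ci_low = max(0, pl$auc - z * se),
       ci_high = min(1, pl$auc + z * se),
       p_vs_half = 2 * pnorm(abs(pl$auc - 0.5) / se, lower.tail = FALSE),
       variance = v, degenerate = FALSE)
}

#' DeLong test comparing two correlated ROC curves
#'
#' Two-sided test of equal AUC for two markers measured on the same
#' subjects, using the DeLong covariance of placement values.
#'
#' @param curve_a,curve_b [roc_curve()] objects built on identical subject
#'   sets and labels (the subject order must match).
#' @return A list: `auc_a`, `auc_b`, `delta`, `variance`, `p_value`.
#' @export
delong_compare <- function(curve_a, curve_b) {
  if (curve_a$n_pos != curve_b$n_pos || curve_a$n_neg != curve_b$n_neg ||
      !identical(curve_a$labels, curve_b$labels))
    stop("validation error: curves must share subjects and labels",
         call. = FALSE)
  pa <- delong_placements(curve_a$oriented, curve_a$labels)
  pb <- delong_placements(curve_b$oriented, curve_b$labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  # var(auc_a - auc_b)
  l <- c(1, -1)
  v <- drop(t(l) %*% s10 %*% l) / pa$m + drop(t(l) %*% s01 %*% l) / pa$n
  delta <- pa$auc - pb$auc
  p <- if (v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) 1 else .Machine$double.xmin
  } else {
    2 * pnorm(abs(delta) / sqrt(v), lower.tail = FALSE)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, variance = v,
       p_value = p)
}

operating_point <- function(strategy, cutoff, sens, spec, n_pos, n_neg,
                            degenerate = FALSE) {
  cf <- confusion_from_rates(sens, spec, n_pos, n_neg)
  structure(list(strategy = strategy, cutoff = cutoff,
                 sensitivity = sens, specificity = spec,
                 ppv = cf$ppv, npv = cf$npv, accuracy = cf$accuracy,
                 counts = cf$counts, degenerate = degenerate),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(paste0("operating_point [%s]: cutoff %.4g, sens %.3f, ",
                     "spec %.3f, ppv %.3f, npv %.3f, acc %.3f\n"),
              x$strategy, x$cutoff, x$sensitivity, x$specificity,
              x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over all empirical cutoffs;
#' ties are broken toward higher specificity, then toward the cutoff that
#' classifies fewer subjects positive. A flat curve (J = 0 everywhere) is
#' flagged degenerate.
#'
#' @param curve A [roc_curve()].
#' @return An `operating_point` (strategy `"youden"`).
#' @export
youden_cutoff <- function(curve) {
  pts <- curve$points
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[order(-pts$specificity[best], pts$cutoff[best])][1]
  }
  operating_point("youden", pts$cutoff[best], pts$sensitivity[best],
                  pts$specificity[best], curve$n_pos, curve$n_neg,
                  degenerate = max(j) <= 0)
}

#' Operating point at a fixed sensitivity or specificity target
#'
#' For `fixed_specificity`, selects the empirical ROC point with the
#' smallest achieved specificity >= target (no interpolation; the achieved
#' rates are reported). Symmetric rule for `fixed_sensitivity`. Among
#' points tied on the constrained rate, the one maximizing the free rate is
#' chosen.
#'
#' @param curve A [roc_curve()].
#' @param strategy `"fixed_specificity"` or `"fixed_sensitivity"`.
#' @param target Target rate in (0, 1\].
#' @return An `operating_point`.
#' @export
operating_point_at <- function(curve,
                               strategy = c("fixed_specificity",
                                            "fixed_sensitivity"),
                               target) {
  strategy <- match.arg(strategy)
  if (!is.finite(target) || target <= 0 || target > 1)
    stop("parameter error: target must lie in (0, 1]", call. = FALSE)
  pts <- curve$points
  if (strategy == "fixed_specificity") {
    ok <- pts$specificity >= target
    cand <- pts[ok, ]
    cand <- cand[order(cand$specificity, -cand$sensitivity), ]
  } else {
    ok <- pts$sensitivity >= target
    cand <- pts[ok, ]
    cand <- cand[order(cand$sensitivity, -cand$specificity), ]
  }
  sel <- cand[1, ]
  operating_point(sprintf("%s(%g)", strategy, target), sel$cutoff,
                  sel$sensitivity, sel$specificity, curve$n_pos,
                  curve$n_neg)
}

#' Reconstruct confusion counts from rates and group sizes
#'
#' Inverts reported sensitivity/specificity back to integer confusion
#' counts via half-up rounding (`tp = floor(sens * n_pos + 0.5)`,
#' `tn = floor(spec * n_neg + 0.5)`), then derives PPV, NPV and accuracy.
#' A predictive value with an empty denominator is `NA`.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return A list: `counts` (tp, fp, fn, tn), `ppv`, `npv`, `accuracy`.
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  tp <- floor(sensitivity * n_pos + 0.5)
  tn <- floor(specificity * n_neg + 0.5)
  fn <- n_pos - tp
  fp <- n_neg - tn
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       ppv = ppv, npv = npv,
       accuracy = (tp + tn) / (n_pos + n_neg))
}

#' Apply a frozen threshold to a new cohort
#'
#' Evaluates a previously derived cutoff on an independent cohort without
#' any re-optimization, reporting the achieved confusion counts and rates.
#'
#' @param scores,labels The new cohort's marker values and binary outcome.
#' @param cutoff Frozen cutoff (finite).
#' @param rule_direction As in [roc_curve()].
#' @return An `operating_point` (strategy `"frozen"`).
#' @export
apply_frozen_threshold <- function(scores, labels, cutoff,
                                   rule_direction =
                                     c("high_predicts_positive",
                                       "low_predicts_positive")) {
  rule_direction <- match.arg(rule_direction)
  if (!is.finite(cutoff))
    stop("parameter error: cutoff must be finite", call. = FALSE)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep] != 0)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("insufficient-data error: both classes must be present",
         call. = FALSE)
  pred_pos <- if (rule_direction == "low_predicts_positive")
    scores <= cutoff else scores >= cutoff
  sens <- sum(pred_pos & labels == 1L) / n_pos
  spec <- sum(!pred_pos & labels == 0L) / n_neg
  operating_point("frozen", cutoff, sens, spec, n_pos, n_neg)
}

#' Univariable / multivariable logistic regression with scaled predictors
#'
#' Maximum-likelihood logistic fit with predictor scaling chosen so that
#' odds ratios are clinically interpretable: ADC-type predictors are
#' reported per +0.1 unit (`scale = "per_0.1"`), tumor volume per doubling
#' (`scale = "log2"`). Wald CIs and p-values; model AUC from fitted
#' probabilities. Perfect separation is detected and raised as an error.
#'
#' @param outcome Binary outcome vector (both classes present, n >= 10).
#' @param predictors Named list (or data frame) of numeric predictors.
#' @param scales Character vector (recycled) per predictor:
#'   `"per_0.1"`, `"log2"`, or `"identity"`.
#' @return A list: `coefficients` (data frame with `predictor`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `scale`), `model_auc`, `fit`.
#' @export
fit_logistic <- function(outcome, predictors, scales = "identity") {
  predictors <- as.data.frame(predictors)
  keep <- complete.cases(predictors) & !is.na(outcome)
  predictors <- predictors[keep, , drop = FALSE]
  outcome <- as.integer(outcome[keep] != 0)
  if (length(unique(outcome)) != 2L)
    stop("insufficient-data error: outcome must have both classes",
         call. = FALSE)
  if (length(outcome) < 10L)
    stop("insufficient-data error: need n >= 10", call. = FALSE)
  scales <- rep_len(scales, ncol(predictors))
  for (j in seq_len(ncol(predictors))) {
    predictors[[j]] <- switch(scales[j],
      per_0.1 = predictors[[j]] / 0.1,
      log2 = log2(predictors[[j]]),
      identity = predictors[[j]],
      stop("unknown scale descriptor: ", scales[j]))
  }
  dat <- cbind(.y = outcome, predictors)
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  prob <- fitted(fit)
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15) ||
      all(abs(prob - outcome) < 1e-8))
    stop("separation error: perfect separation detected, no estimates",
         call. = FALSE)
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  z <- qnorm(0.975)
  co <- data.frame(predictor = names(predictors),
                   or = exp(est),
                   ci_low = exp(est - z * se),
                   ci_high = exp(est + z * se),
                   p_value = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                   scale = scales, row.names = NULL)
  model_auc <- auc_mw(prob, outcome)
  list(coefficients = co, model_auc = model_auc, fit = fit)
}
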