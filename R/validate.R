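# Internal validation: repeated stratified k-fold cross-validation and
# bootstrap optimism correction, with deterministic seed streams so a
# ValidationResult is bit-reproducible from its base seed.
#
# Seed streams: CV repeat r uses seed + 1000 * r; bootstrap iteration b uses
# seed + 2000000 + b. Base seeds are expected to be small integers, keeping
# every derived seed below 2^31.

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Evaluate one "rule": either a fixed marker (scores) or a logistic model
# spec refit per training set. Returns a function(train_idx, test_idx) ->
# test-set oriented scores, plus the apparent oriented scores.
make_scorer <- function(scores = NULL, data = NULL, labels,
                        rule_direction) {
  if (!is.null(scores)) {
    oriented <- if (rule_direction == "low_predicts_positive") -scores
                else scores
    list(apparent = oriented,
         score_fn = function(train, test) oriented[test],
         refits = FALSE)
  } else {
    stopifnot(is.data.frame(data))
    fit_all <- suppressWarnings(
      glm(.y ~ ., data = cbind(.y = labels, data), family = binomial()))
    list(apparent = fitted(fit_all),
         score_fn = function(train, test) {
           fit <- suppressWarnings(
             glm(.y ~ ., data = cbind(.y = labels[train],
                                      data[train, , drop = FALSE]),
                 family = binomial()))
           predict(fit, newdata = data[test, , drop = FALSE],
                   type = "response")
         },
         refits = TRUE)
  }
}

#' Internal validation of a marker or model
#'
#' Repeated stratified k-fold cross-validation plus bootstrap optimism
#' correction of the AUC, and bootstrap stability of the Youden cutoff.
#'
#' Cross-validation: per repeat, subjects are assigned to `folds` strata
#' preserving the class balance; the test AUC of every fold is collected
#' and summarized as `cv_mean_auc` / `cv_sd` (mean and SD over all
#' fold-level test AUCs). For a fixed single marker nothing is refit, so
#' the CV mean matches the apparent AUC up to fold-sampling noise; when a
#' model spec is supplied it is refit on each training set.
#'
#' Bootstrap: subjects are resampled with replacement (unstratified);
#' optimism is the mean over resamples of (AUC on the resample - AUC of the
#' resample-derived rule on the original data), and
#' `bootstrap_corrected_auc = apparent_auc - optimism`. The percentile 95%
#' CI of the resample AUCs and the median/IQR of per-resample Youden
#' cutoffs are also reported.
#'
#' @param scores Numeric marker values (mutually exclusive with `model`).
#' @param labels Binary outcome; each class must have at least `folds`
#'   members.
#' @param model Optional data frame of predictors for a logistic model
#'   refit per training set / resample.
#' @param rule_direction As in [roc_curve()] (ignored for model mode,
#'   where fitted probabilities are always oriented high-positive).
#' @param folds,repeats CV geometry (default 5 x 200).
#' @param boot Bootstrap iterations (default 2000).
#' @param seed Base integer seed; the result is bit-reproducible from it.
#' @return A `validation_result` list: `apparent_auc`, `cv_mean_auc`,
#'   `cv_sd`, `bootstrap_corrected_auc`, `bootstrap_ci`, `optimism`,
#'   `cutoff_bootstrap_median`, `cutoff_bootstrap_iqr`, `seed`.
#' @export
validate_internal <- function(scores = NULL, labels, model = NULL,
                              rule_direction = "high_predicts_positive",
                              folds = 5, repeats = 200, boot = 2000,
                              seed = 1) {
  rule_direction <- match.arg(rule_direction, RULE_DIRECTIONS)
  labels <- as.integer(labels != 0)
  n <- length(labels)
  if (min(sum(labels == 1L), sum(labels == 0L)) < folds)
    stop("parameter error: each class needs at least 'folds' members",
         call. = FALSE)
  sc <- make_scorer(scores, model, labels, rule_direction)
  apparent <- auc_mw(sc$apparent, labels)

  # ---- repeated stratified k-fold CV
  fold_aucs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, folds, seed + 1000L * r)
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(labels[test])) < 2L) next
      s <- sc$score_fn(train, test)
      fold_aucs <- c(fold_aucs, auc_mw(s, labels[test]))
    }
  }

  # ---- bootstrap optimism + cutoff stability
  boot_auc <- numeric(boot)
  boot_test <- numeric(boot)
  boot_cut <- numeric(boot)
  raw_scores <- if (is.null(scores)) NULL else scores
  for (b in seq_len(boot)) {
    set.seed(seed + 2000000L + b)
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) {
      boot_auc[b] <- NA; boot_test[b] <- NA; boot_cut[b] <- NA
      next
    }
    if (sc$refits) {
      fitb <- suppressWarnings(
        glm(.y ~ ., data = cbind(.y = labels[idx],
                                 model[idx, , drop = FALSE]),
            family = binomial()))
      sb <- fitted(fitb)
      sb_orig <- predict(fitb, newdata = model, type = "response")
      boot_auc[b] <- auc_mw(sb, labels[idx])
      boot_test[b] <- auc_mw(sb_orig, labels)
      cb <- roc_curve(sb, labels[idx], "high_predicts_positive")
    } else {
      boot_auc[b] <- auc_mw(sc$apparent[idx], labels[idx])
      boot_test[b] <- apparent  # a fixed marker is its own rule
      cb <- roc_curve(raw_scores[idx], labels[idx], rule_direction)
    }
    boot_cut[b] <- youden_cutoff(cb)$cutoff
  }
  optimism <- mean(boot_auc - boot_test, na.rm = TRUE)
  finite_cut <- boot_cut[is.finite(boot_cut)]

  structure(list(apparent_auc = apparent,
                 cv_mean_auc = mean(fold_aucs),
                 cv_sd = sd(fold_aucs),
                 bootstrap_corrected_auc = apparent - optimism,
                 bootstrap_ci = unname(quantile(boot_auc, c(0.025, 0.975),
                                                na.rm = TRUE)),
                 optimism = optimism,
                 cutoff_bootstrap_median = median(finite_cut),
                 cutoff_bootstrap_iqr = unname(quantile(finite_cut,
                                                        c(0.25, 0.75))),
                 seed = seed),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("validation_result: apparent AUC %.3f, CV %.3f ",
                     "(sd %.3f), corrected %.3f (optimism %+.4f), ",
                     "boot 95%% CI [%.3f, %.3f]\n"),
              x$apparent_auc, x$cv_mean_auc, x$cv_sd,
              x$bootstrap_corrected_auc, x$optimism,
              x$bootstrap_ci[1], x$bootstrap_ci[2]))
  invisible(x)
}
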