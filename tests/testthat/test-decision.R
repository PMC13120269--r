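test_that("ROC sweep AUC equals brute-force pair counting", {
  # worked toy: pos {3,5}, neg {1,2,4}, high predicts positive
  sc <- c(3, 5, 1, 2, 4); lb <- c(1, 1, 0, 0, 0)
  cv <- roc_curve(sc, lb, "high_predicts_positive")
  expect_equal(auc(cv), 5 / 6, tolerance = 1e-12)
  expect_equal(auc(cv), brute_force_auc(sc, lb), tolerance = 1e-12)

  # perfect separation
  expect_equal(auc(roc_curve(c(9, 8, 1, 2), c(1, 1, 0, 0))), 1)

  # random fixtures with ties, both rule directions
  set.seed(21)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    sc <- sample(seq(0, 2, by = 0.05), n, TRUE)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(auc(roc_curve(sc, lb, "high_predicts_positive")),
                 brute_force_auc(sc, lb), tolerance = 1e-12)
    expect_equal(auc(roc_curve(sc, lb, "low_predicts_positive")),
                 brute_force_auc(sc, lb, low_positive = TRUE),
                 tolerance = 1e-12)
  }

  # permuted labels: AUC hovers around 0.5
  set.seed(22)
  for (i in 1:5) {
    sc <- rnorm(200); lb <- sample(rep(c(0, 1), 100))
    expect_lt(abs(auc(roc_curve(sc, lb)) - 0.5), 0.1)
  }
  expect_error(roc_curve(1:5, rep(1, 5)), "insufficient")

  # curve endpoints and monotonicity
  cv2 <- roc_curve(rnorm(50), rbinom(50, 1, 0.5))
  pts <- cv2$points
  expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
})

test_that("DeLong single-curve inference matches pROC and the bootstrap", {
  set.seed(23)
  sc <- c(rnorm(30, 1), rnorm(30)); lb <- rep(c(1, 0), each = 30)
  cv <- roc_curve(sc, lb, "high_predicts_positive")
  res <- delong_auc_inference(cv)

  pr <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(res$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(res$ci_low, ci[1], tolerance = 1e-9)
  expect_equal(res$ci_high, ci[3], tolerance = 1e-9)

  # DeLong variance agrees with the bootstrap variance of the AUC
  set.seed(24)
  ba <- replicate(2000, {
    idx <- sample(60, replace = TRUE)
    if (length(unique(lb[idx])) < 2) NA
    else auc(roc_curve(sc[idx], lb[idx]))
  })
  expect_lt(abs(res$variance - var(ba, na.rm = TRUE)) /
              var(ba, na.rm = TRUE), 0.25)

  # fully tied scores: AUC 0.5, p = 1
  cvt <- roc_curve(rep(1, 20), rep(c(0, 1), 10))
  rest <- delong_auc_inference(cvt)
  expect_equal(rest$auc, 0.5)
  expect_equal(rest$p_vs_half, 1)
  expect_true(rest$degenerate)
})

test_that("DeLong paired comparison: self, monotone transforms, pROC", {
  set.seed(25)
  sc <- rnorm(68); lb <- rbinom(68, 1, 0.4)
  cv <- roc_curve(sc, lb)
  expect_equal(delong_compare(cv, cv)$p_value, 1)

  # a monotone transform changes nothing
  cv2 <- roc_curve(exp(sc) + 2, lb)
  cmp <- delong_compare(cv, cv2)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)

  # cross-check p-value against pROC's paired DeLong test
  sc2 <- 0.6 * sc + 0.8 * rnorm(68)
  cv3 <- roc_curve(sc2, lb)
  p_me <- delong_compare(cv, cv3)$p_value
  r1 <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
  r2 <- pROC::roc(lb, sc2, direction = "<", quiet = TRUE)
  p_ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)$p.value
  expect_equal(p_me, p_ref, tolerance = 1e-9)

  expect_error(delong_compare(cv, roc_curve(sc, 1 - lb)), "validation")
})

test_that("Youden selection equals exhaustive search with stated tie-breaks", {
  # separation toy: J = 1
  yj <- youden_cutoff(roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)))
  expect_equal(yj$sensitivity + yj$specificity - 1, 1)

  # random 68-point fixture vs exhaustive scan over all thresholds
  set.seed(26)
  sc <- round(rnorm(68), 2); lb <- rbinom(68, 1, 0.4)
  cv <- roc_curve(sc, lb, "low_predicts_positive")
  yj2 <- youden_cutoff(cv)
  best_j <- -Inf
  for (cut in unique(sc)) {
    pred <- sc <= cut
    s <- sum(pred & lb == 1) / sum(lb == 1)
    p <- sum(!pred & lb == 0) / sum(lb == 0)
    best_j <- max(best_j, s + p - 1)
  }
  expect_equal(yj2$sensitivity + yj2$specificity - 1, best_j,
               tolerance = 1e-12)

  # flat scores: degenerate point with J = 0
  yj3 <- youden_cutoff(roc_curve(rep(1, 10), rep(c(0, 1), 5)))
  expect_equal(yj3$sensitivity + yj3$specificity - 1, 0)
  expect_true(yj3$degenerate)
})

test_that("fixed-rate operating points use achieved empirical rates", {
  # the smallest achieved specificity >= target is selected
  sc <- c(1, 2, 3, 4, 5, 6, 7, 8); lb <- c(0, 0, 0, 0, 0, 1, 1, 1)
  cv <- roc_curve(sc, lb, "high_predicts_positive")
  op <- operating_point_at(cv, "fixed_specificity", 0.5)
  expect_gte(op$specificity, 0.5)
  achievable <- cv$points$specificity[cv$points$specificity >= 0.5]
  expect_equal(op$specificity, min(achievable))

  # achievable specificities {0, 0.78, 0.805, 0.855, 1}: the >= 80% rule
  # picks 0.805, not the higher ones
  neg <- rep(1:4, times = c(156, 5, 10, 29))
  pos <- rep(5, 50)
  cvx <- roc_curve(c(pos, neg), rep(c(1, 0), c(50, 200)),
                   "high_predicts_positive")
  opx <- operating_point_at(cvx, "fixed_specificity", 0.80)
  expect_equal(opx$specificity, 0.805, tolerance = 1e-12)

  # separation: sensitivity 1 at any fixed specificity
  cvs <- roc_curve(c(9, 8, 1, 2), c(1, 1, 0, 0))
  expect_equal(operating_point_at(cvs, "fixed_specificity", 0.9)$sensitivity, 1)

  # reported pair always exists on the empirical curve
  set.seed(27)
  sc <- rnorm(68); lb <- rbinom(68, 1, 0.4)
  cv2 <- roc_curve(sc, lb)
  for (t in c(0.3, 0.8, 0.9)) {
    for (strat in c("fixed_specificity", "fixed_sensitivity")) {
      op <- operating_point_at(cv2, strat, t)
      expect_true(any(abs(cv2$points$sensitivity - op$sensitivity) < 1e-12 &
                      abs(cv2$points$specificity - op$specificity) < 1e-12))
    }
  }
  expect_error(operating_point_at(cv2, "fixed_specificity", 1.2), "parameter")
})

test_that("confusion reconstruction reproduces the consistent published cells", {
  # Youden row: 27 positives, 41 negatives
  y <- confusion_from_rates(0.667, 0.780, 27, 41)
  expect_equal(unname(y$counts), c(18, 9, 9, 32))
  expect_equal(round(y$ppv, 3), 0.667)
  expect_equal(round(y$npv, 3), 0.780)
  expect_equal(round(100 * y$accuracy, 1), 73.5)

  # ~85% specificity row
  s85 <- confusion_from_rates(0.519, 0.854, 27, 41)
  expect_equal(unname(s85$counts[c("tp", "tn")]), c(14, 35))
  expect_equal(round(s85$ppv, 3), 0.700)
  expect_equal(round(s85$npv, 3), 0.729)

  # ~90-95% specificity row
  s90 <- confusion_from_rates(0.333, 0.951, 27, 41)
  expect_equal(round(s90$ppv, 3), 0.818)
  expect_equal(round(s90$npv, 3), 0.684)

  # ~80% sensitivity row
  s80 <- confusion_from_rates(0.815, 0.366, 27, 41)
  expect_equal(round(s80$ppv, 3), 0.458)
  expect_equal(round(s80$npv, 3), 0.750)

  p <- confusion_from_rates(1, 1, 10, 10)
  expect_equal(p$accuracy, 1)
})

test_that("logistic fits: null calibration, reparameterization, separation", {
  set.seed(28)
  # independent predictor: OR near 1 over seeds
  ors <- sapply(1:5, function(s) {
    set.seed(200 + s)
    y <- rbinom(500, 1, 0.4); x <- rnorm(500)
    fit_logistic(y, list(x = x), scales = "identity")$coefficients$or
  })
  expect_true(all(ors > 0.8 & ors < 1.25))

  # rescaling a predictor while adjusting its descriptor leaves the OR alone
  y <- rbinom(200, 1, 0.4); x <- rnorm(200, 1, 0.3)
  f1 <- fit_logistic(y, list(x = x), scales = "per_0.1")
  f2 <- fit_logistic(y, list(x = x / 0.1), scales = "identity")
  expect_equal(f1$coefficients$or, f2$coefficients$or, tolerance = 1e-8)
  expect_equal(f1$coefficients$p_value, f2$coefficients$p_value,
               tolerance = 1e-8)

  # volume doubling scale: OR per doubling equals exp(beta on log2 scale)
  v <- exp(rnorm(200, 8, 1))
  fv <- fit_logistic(y, list(vol = v), scales = "log2")
  fl <- glm(y ~ log2(v), family = binomial())
  expect_equal(fv$coefficients$or, unname(exp(coef(fl)[2])),
               tolerance = 1e-8)

  # perfectly separating predictor raises a separation error
  ys <- rep(c(0, 1), each = 10)
  xs <- c(rnorm(10, -5), rnorm(10, 5))
  expect_error(fit_logistic(ys, list(x = xs)), "separation")
})

test_that("frozen thresholds are applied without refitting", {
  # cutoff below every score with low-positive rule: nothing called positive
  op <- apply_frozen_threshold(c(2, 3, 4, 5), c(1, 0, 1, 0), cutoff = 1,
                               rule_direction = "low_predicts_positive")
  expect_equal(op$sensitivity, 0)
  expect_equal(op$specificity, 1)

  # constructed 10+10 cohort: 5/10 positives below, 8/10 negatives above
  pos <- c(rep(0.4, 5), rep(0.7, 5))
  neg <- c(rep(0.45, 2), rep(0.8, 8))
  op2 <- apply_frozen_threshold(c(pos, neg), rep(c(1, 0), each = 10),
                                cutoff = 0.552,
                                rule_direction = "low_predicts_positive")
  expect_equal(op2$sensitivity, 0.5)
  expect_equal(op2$specificity, 0.8)

  expect_error(apply_frozen_threshold(1:4, rep(0, 4), 2,
                                      "low_predicts_positive"),
               "insufficient")
  expect_error(apply_frozen_threshold(1:4, c(0, 1, 0, 1), Inf,
                                      "low_predicts_positive"),
               "parameter")
})

test_that("internal validation: no-overfit identity, null, determinism", {
  co <- generate_cohort(cohort_sim_spec(
    target_auc = list(ratio_shell1 = 0.725), seed = 31))
  vr <- validate_internal(scores = co$ratio_shell1, labels = co$pN_status,
                          rule_direction = "low_predicts_positive",
                          repeats = 50, boot = 500, seed = 7)
  # a fixed marker is not refit: CV mean tracks the apparent AUC and the
  # bootstrap optimism vanishes
  expect_lt(abs(vr$cv_mean_auc - vr$apparent_auc), 0.02)
  expect_lt(abs(vr$optimism), 0.01)
  expect_equal(vr$bootstrap_corrected_auc, vr$apparent_auc - vr$optimism)
  expect_gte(vr$cv_sd, 0)

  # identical seed, identical result
  vr2 <- validate_internal(scores = co$ratio_shell1, labels = co$pN_status,
                           rule_direction = "low_predicts_positive",
                           repeats = 50, boot = 500, seed = 7)
  expect_identical(vr, vr2)

  # class smaller than fold count
  expect_error(validate_internal(scores = rnorm(10),
                                 labels = c(1, rep(0, 9)), folds = 5),
               "parameter")

  # logistic model mode runs and reports plausible optimism
  vm <- validate_internal(labels = co$pN_status,
                          model = data.frame(x = co$ratio_shell1,
                                             v = log(co$tumor_volume_mm3)),
                          repeats = 10, boot = 100, seed = 9)
  expect_gte(vm$optimism, -0.02)
  expect_true(vm$bootstrap_corrected_auc <= vm$apparent_auc + 0.02)
})
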