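# Nonparametric group comparisons, correlations and reproducibility
# statistics for cohort tables.
#
# The headline analyses are all nonparametric (Mann-Whitney, Kruskal-Wallis
# with Bonferroni post hoc, Spearman); a parametric branch (t test / ANOVA)
# is available behind an opt-in flag. No global correction across metrics is
# applied; Bonferroni only within post hoc families.

med_iqr <- function(v) {
  v <- v[!is.na(v)]
  c(median = median(v), q1 = unname(quantile(v, 0.25)),
    q3 = unname(quantile(v, 0.75)), n = length(v))
}

#' Two-group comparison (Mann-Whitney U, optionally t test)
#'
#' Two-sided Mann-Whitney U with mid-rank tie handling. P-values use exact
#' enumeration when both groups have at most 8 observations and no ties are
#' present, and the normal approximation with continuity correction
#' otherwise. Fully symmetric degenerate input (rank sum at its null mean
#' with zero tie-corrected variance) yields p = 1.
#'
#' @param values Numeric vector of per-patient metric values.
#' @param labels Binary group labels (two levels after `NA` removal).
#' @param parametric If `TRUE`, use Welch's t test instead.
#' @return A `group_comparison` list: `test`, `statistic`, `p_value`,
#'   `groups` (per-group median/IQR/n), `post_hoc = NULL`.
#' @export
compare_two_groups <- function(values, labels, parametric = FALSE) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("insufficient-data error: need exactly two nonempty groups",
         call. = FALSE)
  x <- values[labels == lev[1]]
  y <- values[labels == lev[2]]
  if (parametric) {
    ht <- stats::t.test(x, y)
    test <- "t"
  } else if (length(unique(values)) == 1L) {
    # fully tied input: U at its null mean, no evidence either way
    ht <- list(statistic = length(x) * length(y) / 2, p.value = 1)
    test <- "mann-whitney"
  } else {
    use_exact <- length(x) <= 8 && length(y) <= 8 &&
      !anyDuplicated(values)
    ht <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                       correct = TRUE))
    if (is.nan(ht$p.value)) ht$p.value <- 1
    test <- "mann-whitney"
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 groups = list(g1 = c(label = lev[1], med_iqr(x)),
                               g2 = c(label = lev[2], med_iqr(y))),
                 post_hoc = NULL),
            class = "group_comparison")
}

#' K-group comparison (Kruskal-Wallis with Bonferroni post hoc)
#'
#' Kruskal-Wallis H with tie correction; when the overall p is below
#' `alpha`, all pairwise Mann-Whitney tests are run with Bonferroni
#' adjustment over the k(k-1)/2 pairs (adjusted p = min(1, raw p x pairs)).
#' No post hoc is emitted when the overall test is not significant.
#'
#' @param values Numeric vector.
#' @param labels Categorical labels with k >= 3 nonempty levels.
#' @param alpha Gate for post hoc testing (default 0.05).
#' @param parametric If `TRUE`, one-way ANOVA instead.
#' @return A `group_comparison` list with `post_hoc` a data frame
#'   (`pair`, `p_raw`, `p_adjusted`) or `NULL`.
#' @export
compare_k_groups <- function(values, labels, alpha = 0.05,
                             parametric = FALSE) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- droplevels(factor(labels[keep]))
  lev <- levels(labels)
  if (length(lev) < 3L)
    stop("insufficient-data error: need k >= 3 nonempty groups",
         call. = FALSE)
  if (parametric) {
    fit <- aov(values ~ labels)
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
    test <- "anova"
  } else if (length(unique(values)) == 1L) {
    stat <- 0; p <- 1; test <- "kruskal-wallis"
  } else {
    ht <- kruskal.test(values, labels)
    stat <- unname(ht$statistic); p <- ht$p.value
    test <- "kruskal-wallis"
  }
  post <- NULL
  if (!is.na(p) && p < alpha && !parametric) {
    pairs <- utils::combn(lev, 2)
    n_pairs <- ncol(pairs)
    post <- data.frame(pair = apply(pairs, 2, paste, collapse = " vs "),
                       p_raw = NA_real_, p_adjusted = NA_real_)
    for (j in seq_len(n_pairs)) {
      cmp <- compare_two_groups(values[labels %in% pairs[, j]],
                                as.character(labels[labels %in% pairs[, j]]))
      post$p_raw[j] <- cmp$p_value
      post$p_adjusted[j] <- min(1, cmp$p_value * n_pairs)
    }
  }
  grp <- lapply(lev, function(l) c(label = l, med_iqr(values[labels == l])))
  names(grp) <- lev
  structure(list(test = test, statistic = stat, p_value = p, groups = grp,
                 post_hoc = post),
            class = "group_comparison")
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman rho with a two-sided p-value from the t approximation.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return A list: `rho`, `p_value`, `n_used`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("insufficient-data error: need at least 3 complete pairs",
         call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined-correlation error: constant input vector",
         call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n_used = n)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' standard mean-squares decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with MSR the between-subject, MSC the between-rater and MSE the residual
#' mean square.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, no missing cells).
#' @return A list: `icc`, `model`, `n_subjects`, `n_raters`.
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (anyNA(ratings))
    stop("validation error: missing cells in ratings matrix", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc,
       model = "two-way random, absolute agreement, single measurement",
       n_subjects = n, n_raters = k)
}

#' Association between two categorical variables
#'
#' Chi-square test of independence, switching to Fisher's exact test when
#' any expected cell count is below 5.
#'
#' @param a,b Categorical vectors of equal length.
#' @return A list: `test` (`"chi-square"` or `"fisher"`), `statistic`
#'   (`NA` for Fisher), `p_value`, `table`.
#' @export
compare_categorical <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  tab <- table(a[keep], b[keep])
  if (any(dim(tab) < 2L))
    stop("insufficient-data error: need at least 2 levels per variable",
         call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- fisher.test(tab)
    list(test = "fisher", statistic = NA_real_, p_value = ht$p.value,
         table = tab)
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = "chi-square", statistic = unname(ht$statistic),
         p_value = ht$p.value, table = tab)
  }
}
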