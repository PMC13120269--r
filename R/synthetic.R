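# Synthetic data: ADC phantoms with ground-truth geometry, and patient
# cohorts with the statistical structure the analysis assumes. All
# generators are pure functions of their spec + seed.

#' Phantom specification
#'
#' Defaults describe a bilateral 1 mm isotropic grid with an ellipsoidal
#' tumor in the right breast, compartment ADC levels set to the cohort
#' medians of the study population (tumor 0.88; shells 1.52 / 1.42 / 1.57
#' at 0-2 / 2-5 / 5-10 mm; fibroglandular background and contralateral
#' reference 1.55; all 10^-3 mm^2/s), and mild additive Gaussian noise.
#'
#' @param dim Grid dimensions (voxels).
#' @param spacing Voxel size (mm).
#' @param center Tumor center (mm, physical coordinates; origin at voxel
#'   (1,1,1)). Default places the tumor in the right half.
#' @param semi_axes Ellipsoid semi-axes (mm).
#' @param adc_tumor,adc_background,adc_reference Compartment ADC levels.
#' @param shell_bands Data frame `inner_mm`, `outer_mm`, `value`: ADC level
#'   of each peritumoral band; bands must tile (0, max] without overlap.
#' @param noise_sd Additive Gaussian noise SD (10^-3 mm^2/s).
#' @param adipose Number of adipose blocks to drop into the outer band
#'   (exercises the exclusion-mask path); their ADC level is
#'   `adipose_value`.
#' @param adipose_value ADC assigned to adipose blocks.
#' @param seed Integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(96, 64, 48), spacing = c(1, 1, 1),
                         center = NULL, semi_axes = c(8, 8, 8),
                         adc_tumor = 0.88,
                         shell_bands = data.frame(
                           inner_mm = c(0, 2, 5),
                           outer_mm = c(2, 5, 10),
                           value = c(1.52, 1.42, 1.57)),
                         adc_background = 1.55, adc_reference = 1.55,
                         noise_sd = 0.1, adipose = 0L,
                         adipose_value = 0.40, seed = 1L) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  if (any(c(adc_tumor, shell_bands$value, adc_background,
            adc_reference) <= 0))
    stop("compartment ADC values must be positive", call. = FALSE)
  check_shell_spec(shell_bands)
  if (is.null(center))
    center <- c(0.75 * (dim[1] - 1) * spacing[1],
                0.5 * (dim[2] - 1) * spacing[2],
                0.5 * (dim[3] - 1) * spacing[3])
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 adc_tumor = adc_tumor, shell_bands = shell_bands,
                 adc_background = adc_background,
                 adc_reference = adc_reference, noise_sd = noise_sd,
                 adipose = as.integer(adipose),
                 adipose_value = adipose_value, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate an ADC phantom with ground-truth geometry
#'
#' Voxels take the ADC level of their ground-truth compartment (tumor,
#' distance band, or background) plus optional Gaussian noise. Compartment
#' membership is decided by the Euclidean distance field of the voxelized
#' tumor mask - the same canonical distance definition the measurement
#' pipeline uses - so that a zero-noise phantom is recovered exactly. The
#' left half of the grid is homogeneous reference tissue; shells are
#' required to stay clear of it by the fit margin.
#'
#' @param spec A [phantom_spec()].
#' @param allow_clipping Permit the tumor + outermost band to touch the
#'   grid boundary (default FALSE: a geometry error is raised).
#' @return A list: `volume` ([image_volume()]), `tumor` ([binary_mask()]),
#'   `exclusion` (mask, empty when `spec$adipose == 0`), `truth`
#'   (`shell_set` with the analytic band masks), `reference_voi`.
#' @export
generate_phantom <- function(spec = phantom_spec(), allow_clipping = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim; sp <- spec$spacing
  cx <- lapply(1:3, function(a) axis_coords(d[a], sp[a], 0))
  # ellipsoid membership at voxel centers
  ex <- (cx[[1]] - spec$center[1])^2 / spec$semi_axes[1]^2
  ey <- (cx[[2]] - spec$center[2])^2 / spec$semi_axes[2]^2
  ez <- (cx[[3]] - spec$center[3])^2 / spec$semi_axes[3]^2
  inside <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  if (!any(inside))
    stop("geometry error: tumor does not cover any voxel", call. = FALSE)
  margin <- max(spec$shell_bands$outer_mm)
  ext <- spec$semi_axes + margin
  lo <- spec$center - ext; hi <- spec$center + ext
  grid_hi <- (d - 1) * sp
  if (!allow_clipping &&
      (any(lo < 0) || any(hi > grid_hi) || lo[1] < grid_hi[1] / 2))
    stop(paste("geometry error: tumor + outer band does not fit in the",
               "right half of the grid; enlarge the grid or set",
               "allow_clipping"), call. = FALSE)

  tumor <- binary_mask(array(as.numeric(inside), d), spacing = sp,
                       origin = c(0, 0, 0), role = "tumor")
  dfield <- boundary_distance_field(tumor)
  dv <- dfield$data

  vol <- array(spec$adc_background, d)
  # contralateral (left, low-x) half is homogeneous reference tissue
  left <- seq_len(floor(d[1] / 2))
  vol[left, , ] <- spec$adc_reference
  for (k in seq_len(nrow(spec$shell_bands)))
    vol[dv > spec$shell_bands$inner_mm[k] &
        dv <= spec$shell_bands$outer_mm[k]] <- spec$shell_bands$value[k]
  vol[inside] <- spec$adc_tumor

  excl <- array(FALSE, d)
  if (spec$adipose > 0L) {
    set.seed(spec$seed + 500L)
    outer_band <- spec$shell_bands[nrow(spec$shell_bands), ]
    cand <- which(dv > outer_band$inner_mm & dv <= outer_band$outer_mm)
    for (i in seq_len(spec$adipose)) {
      ctr <- arrayInd(sample(cand, 1), d)
      rng <- lapply(1:3, function(a)
        max(1, ctr[a] - 1):min(d[a], ctr[a] + 1))
      blk <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      vol[blk] <- spec$adipose_value
      excl[blk] <- TRUE
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(rnorm(prod(d), 0, spec$noise_sd), d)
  }

  volume <- image_volume(vol, spacing = sp, origin = c(0, 0, 0))
  exclusion <- binary_mask(array(as.numeric(excl), d), spacing = sp,
                           origin = c(0, 0, 0), role = "exclusion")
  truth <- build_shells(tumor,
                        shell_spec(c(spec$shell_bands$inner_mm[1],
                                     spec$shell_bands$outer_mm)),
                        exclusion = exclusion)
  truth$reference_voi <- mirror_reference_voi(tumor, volume)
  list(volume = volume, tumor = tumor, exclusion = exclusion,
       truth = truth, reference_voi = truth$reference_voi)
}

#' Binormal mean shift for a target AUC
#'
#' For two unit-variance normal classes, a mean separation of
#' `sqrt(2) * qnorm(auc)` yields exactly that AUC
#' (`P(X1 > X0) = pnorm(delta / sqrt(2))`).
#'
#' @param target_auc Target AUC in (0.5, 1).
#' @return The mean separation in pooled-SD units.
#' @export
binormal_shift <- function(target_auc) {
  if (!is.finite(target_auc) || target_auc <= 0.5 || target_auc >= 1)
    stop("parameter error: target_auc must lie in (0.5, 1)", call. = FALSE)
  sqrt(2) * qnorm(target_auc)
}

# log-normal parameters from a median and IQR
lnorm_from_median_iqr <- function(med, q1, q3) {
  c(mu = log(med), sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

# Per-pN-group median (q1-q3) anchors for the five ADC compartments, taken
# from the study population (reference compartment: overall cohort summary,
# no per-group split is reported).
compartment_anchors <- function() {
  list(
    neg = list(adc_tumor  = c(0.94, 0.81, 1.12),
               adc_shell1 = c(1.49, 1.43, 1.62),
               adc_shell2 = c(1.39, 1.31, 1.54),
               adc_shell3 = c(1.56, 1.48, 1.66),
               adc_reference = c(1.55, 1.50, 1.69)),
    pos = list(adc_tumor  = c(0.75, 0.715, 0.93),
               adc_shell1 = c(1.62, 1.44, 1.78),
               adc_shell2 = c(1.48, 1.23, 1.67),
               adc_shell3 = c(1.72, 1.42, 1.83),
               adc_reference = c(1.55, 1.50, 1.69)))
}

# overall anchors used for target-AUC calibrated markers (pooled margins)
pooled_anchors <- function() {
  list(adc_tumor = c(0.88, 0.75, 1.12), adc_shell1 = c(1.52, 1.43, 1.67),
       adc_shell2 = c(1.42, 1.27, 1.56), adc_shell3 = c(1.57, 1.47, 1.77),
       adc_reference = c(1.55, 1.50, 1.69),
       radc_tumor = c(0.57, 0.49, 0.71), radc_shell1 = c(0.97, 0.90, 1.05),
       radc_shell2 = c(0.91, 0.78, 0.97), radc_shell3 = c(0.99, 0.89, 1.11),
       ratio_shell1 = c(0.59, 0.49, 0.74),
       ratio_shell2 = c(0.66, 0.55, 0.83),
       ratio_shell3 = c(0.55, 0.48, 0.73))
}

# markers for which LOW values predict pN+ (diffusion restriction)
LOW_POSITIVE_MARKERS <- c("adc_tumor", "radc_tumor", "ratio_shell1",
                          "ratio_shell2", "ratio_shell3")

#' Cohort simulation specification
#'
#' Defaults emulate the study population: 68 patients, pN+ prevalence
#' 39.7% (27/68 in fixed-count mode), LVI prevalence 25%, molecular
#' subtype proportions 19.1 / 64.7 / 8.8 / 7.4% (LumA / LumB / HER2E /
#' TNBC), grade proportions 32.4 / 51.5 / 16.2%, Ki-67 median 0.25
#' (IQR 0.15-0.43). Compartment ADCs follow per-pN-group log-normal
#' margins anchored to the reported group medians/IQRs, coupled by a
#' Gaussian copula with cross-compartment correlation
#' `compartment_correlation` on the log scale. Ki-67 and grade share a
#' latent with intratumoral ADC (loading `-aggressiveness_loading`), so
#' the ratio metrics inherit negative rank correlations with both.
#'
#' @param n_patients Cohort size.
#' @param prevalence_pN pN+ prevalence.
#' @param fixed_count If `TRUE` (default), exactly
#'   `round(n * prevalence)` positives; otherwise binomial sampling.
#' @param prevalence_LVI LVI+ prevalence.
#' @param subtype_props Named proportions over LumA/LumB/HER2E/TNBC.
#' @param grade_props Proportions of grades 1-3.
#' @param compartment_correlation Cross-compartment copula correlation.
#' @param aggressiveness_loading Magnitude of the loading tying Ki-67 and
#'   grade to the intratumoral-ADC latent (sign is applied internally).
#' @param target_auc Optional named list: marker name -> target AUC. Those
#'   markers are drawn directly from the binormal calibration (pooled
#'   log-normal margins, group separation `binormal_shift(auc)`), replacing
#'   the anchor-derived values. `target_auc = 0.5` draws a null marker.
#' @param volume_auc Target AUC of log tumor volume for pN+ (default
#'   0.655).
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 68, prevalence_pN = 0.397,
                            fixed_count = TRUE, prevalence_LVI = 0.25,
                            subtype_props = c(LumA = 0.191, LumB = 0.647,
                                              HER2E = 0.088, TNBC = 0.074),
                            grade_props = c(0.324, 0.515, 0.161),
                            compartment_correlation = 0.5,
                            aggressiveness_loading = 0.5,
                            target_auc = list(), volume_auc = 0.655,
                            seed = 1L) {
  if (prevalence_pN <= 0 || prevalence_pN >= 1 ||
      prevalence_LVI <= 0 || prevalence_LVI >= 1)
    stop("parameter error: prevalences must lie in (0, 1)", call. = FALSE)
  subtype_props <- subtype_props / sum(subtype_props)
  grade_props <- grade_props / sum(grade_props)
  if (compartment_correlation < 0 || compartment_correlation >= 1)
    stop("parameter error: infeasible correlation", call. = FALSE)
  for (a in target_auc)
    if (a != 0.5 && (a <= 0.5 || a >= 1))
      stop("parameter error: target AUC must be 0.5 or in (0.5, 1)",
           call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_pN = prevalence_pN, fixed_count = fixed_count,
                 prevalence_LVI = prevalence_LVI,
                 subtype_props = subtype_props, grade_props = grade_props,
                 compartment_correlation = compartment_correlation,
                 aggressiveness_loading = aggressiveness_loading,
                 target_auc = target_auc, volume_auc = volume_auc,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Generate a synthetic patient cohort
#'
#' @param spec A [cohort_sim_spec()].
#' @return A validated `cohort_table` data frame with the 12 per-patient
#'   metrics, tumor volume, and clinical labels.
#' @export
generate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients

  pn <- if (spec$fixed_count) {
    k <- round(n * spec$prevalence_pN)
    sample(rep(c(1L, 0L), c(k, n - k)))
  } else {
    rbinom(n, 1, spec$prevalence_pN)
  }

  # Gaussian copula over the five ADC compartments: shared factor model
  # with pairwise correlation rho on the log scale
  rho <- spec$compartment_correlation
  comp <- c("adc_tumor", "adc_shell1", "adc_shell2", "adc_shell3",
            "adc_reference")
  f <- rnorm(n)
  z <- sapply(comp, function(cc) sqrt(rho) * f +
                sqrt(1 - rho) * rnorm(n))
  anchors <- compartment_anchors()
  vals <- sapply(comp, function(cc) {
    out <- numeric(n)
    for (g in c(0L, 1L)) {
      an <- if (g == 1L) anchors$pos[[cc]] else anchors$neg[[cc]]
      par <- lnorm_from_median_iqr(an[1], an[2], an[3])
      sel <- pn == g
      out[sel] <- exp(par["mu"] + par["sigma"] * z[sel, cc])
    }
    out
  })
  vals <- as.data.frame(vals)

  df <- data.frame(id = sprintf("P%03d", seq_len(n)))
  df$adc_tumor <- vals$adc_tumor
  df$adc_shell1 <- vals$adc_shell1
  df$adc_shell2 <- vals$adc_shell2
  df$adc_shell3 <- vals$adc_shell3
  df$adc_reference <- vals$adc_reference
  df$radc_tumor <- vals$adc_tumor / vals$adc_reference
  df$radc_shell1 <- vals$adc_shell1 / vals$adc_reference
  df$radc_shell2 <- vals$adc_shell2 / vals$adc_reference
  df$radc_shell3 <- vals$adc_shell3 / vals$adc_reference
  df$ratio_shell1 <- vals$adc_tumor / vals$adc_shell1
  df$ratio_shell2 <- vals$adc_tumor / vals$adc_shell2
  df$ratio_shell3 <- vals$adc_tumor / vals$adc_shell3

  # target-AUC calibrated markers override the anchor-derived columns
  pooled <- pooled_anchors()
  for (mk in names(spec$target_auc)) {
    a <- spec$target_auc[[mk]]
    zz <- rnorm(n)
    if (a > 0.5) {
      delta <- binormal_shift(a)
      sgn <- if (mk %in% LOW_POSITIVE_MARKERS) -1 else 1
      zz <- zz + sgn * delta * (pn == 1L)
    }
    an <- pooled[[mk]]
    if (is.null(an)) an <- c(1, 0.8, 1.25)
    par <- lnorm_from_median_iqr(an[1], an[2], an[3])
    df[[mk]] <- exp(par["mu"] + par["sigma"] * zz)
  }

  # tumor volume: log-normal, group separation tuned to the target AUC
  vol_par <- lnorm_from_median_iqr(3999, 1123, 9618)
  zv <- rnorm(n)
  if (spec$volume_auc > 0.5)
    zv <- zv + binormal_shift(spec$volume_auc) *
      ((pn == 1L) - spec$prevalence_pN)
  df$tumor_volume_mm3 <- exp(vol_par["mu"] + vol_par["sigma"] * zv)

  # aggressiveness latent: the idiosyncratic (factor-free) part of the
  # intratumoral-ADC score, negated, so Ki-67/grade stay uncorrelated with
  # the shell and reference compartments
  lam <- spec$aggressiveness_loading
  z_aggr <- -(z[, "adc_tumor"] - sqrt(rho) * f) / sqrt(1 - rho)
  z_ki <- lam * z_aggr + sqrt(1 - lam^2) * rnorm(n)
  ki_par <- lnorm_from_median_iqr(0.25, 0.15, 0.43)
  df$ki67 <- pmin(0.99, exp(ki_par["mu"] + ki_par["sigma"] * z_ki))
  z_gr <- lam * z_aggr + sqrt(1 - lam^2) * rnorm(n)
  cuts <- qnorm(cumsum(spec$grade_props))[1:2]
  df$grade <- cut(z_gr, c(-Inf, cuts, Inf), labels = FALSE)

  z_lvi <- lam * z_aggr + sqrt(1 - lam^2) * rnorm(n)
  df$LVI <- as.integer(z_lvi > qnorm(1 - spec$prevalence_LVI))
  df$pN_status <- pn
  df$molecular_subtype <- sample(names(spec$subtype_props), n,
                                 replace = TRUE,
                                 prob = spec$subtype_props)
  validate_cohort(df)
}
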