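# Per-patient quantitative metrics: compartment mean ADCs, contralateral
# normalization (rADC), and intratumoral-to-peritumoral ratios.
#
# Units: ADC is stored and reported in 10^-3 mm^2/s throughout; rADC and
# ratios are dimensionless. Empty compartments yield NA, never 0, so that
# downstream nonparametric statistics drop the patient pairwise.

#' Mean of a volume over a mask
#'
#' Arithmetic mean of the volume values at mask voxels; `NA`-flagged voxels
#' are excluded from both numerator and count. An empty mask (or a mask
#' whose voxels are all missing) yields `NA` with a warning rather than an
#' error, so cohort-scale runs degrade gracefully.
#'
#' @param volume An [image_volume()].
#' @param mask A [binary_mask()] on the same grid.
#' @return A scalar, or `NA` for an empty mask.
#' @export
mean_in_mask <- function(volume, mask) {
  if (!same_grid(volume, mask))
    stop("geometry error: mask grid does not match volume", call. = FALSE)
  v <- volume$data[mask$data]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("empty mask: mean is NA")
    return(NA_real_)
  }
  sum(v) / length(v)
}

#' Normalize an ADC value by the contralateral reference
#'
#' @param value Mean ADC of a compartment (10^-3 mm^2/s).
#' @param reference Mean ADC of the contralateral reference VOI (> 0).
#' @return `value / reference`, or `NA` (with warning) when the reference
#'   is missing or non-positive.
#' @export
normalize_radc <- function(value, reference) {
  if (is.na(value)) return(NA_real_)
  if (is.na(reference) || reference <= 0) {
    warning("missing or non-positive reference ADC: rADC is NA")
    return(NA_real_)
  }
  value / reference
}

#' Intratumoral-to-peritumoral ADC ratio
#'
#' Computed per patient (before any cohort summarization): the cohort
#' summary of this metric is the median of per-patient ratios, not a ratio
#' of cohort medians.
#'
#' @param adc_tumor Intratumoral mean ADC.
#' @param adc_shell Mean ADC of one peritumoral shell (> 0).
#' @return `adc_tumor / adc_shell`, or `NA` when either input is missing.
#' @export
tumor_to_shell_ratio <- function(adc_tumor, adc_shell) {
  if (is.na(adc_tumor) || is.na(adc_shell)) return(NA_real_)
  if (adc_shell <= 0) {
    warning("non-positive shell ADC: ratio is NA")
    return(NA_real_)
  }
  adc_tumor / adc_shell
}

#' Extract the full per-patient metric set
#'
#' Computes the 12 per-patient quantities (intratumoral, three shell and
#' reference mean ADCs; four rADCs; three ratios) plus the tumor volume.
#' The intratumoral mean uses the ERODED tumor VOI (erosion exists to keep
#' tumor signal out of the shells); tumor volume is the anatomical quantity
#' and uses the un-eroded mask (voxel count times voxel volume). Empty
#' shells propagate to missing metrics.
#'
#' @param volume An [image_volume()].
#' @param shells A `shell_set` from [build_shells()], built on the same
#'   grid.
#' @param reference_voi Optional reference [binary_mask()]; defaults to
#'   `shells$reference_voi`, else the mirrored tumor VOI cannot be inferred
#'   and reference-dependent metrics are `NA`.
#' @return A one-row data frame with columns `adc_tumor`, `adc_shell1..3`,
#'   `adc_reference`, `radc_tumor`, `radc_shell1..3`, `ratio_shell1..3`,
#'   `tumor_volume_mm3`.
#' @export
extract_patient_metrics <- function(volume, shells, reference_voi = NULL) {
  if (!inherits(shells, "shell_set")) stop("'shells' must be a shell_set")
  if (!same_grid(volume, shells$tumor))
    stop("geometry error: shells were not built on this volume's grid",
         call. = FALSE)
  if (is.null(reference_voi)) reference_voi <- shells$reference_voi

  n_shell <- length(shells$shells)
  adc_t <- mean_in_mask(volume, shells$tumor_voi)
  adc_s <- vapply(seq_len(n_shell), function(k) {
    if (shells$empty[k]) NA_real_
    else mean_in_mask(volume, shells$shells[[k]])
  }, numeric(1))
  adc_ref <- if (is.null(reference_voi)) NA_real_
             else mean_in_mask(volume, reference_voi)

  # an absent reference VOI is an allowed configuration: rADC metrics are
  # missing without further noise
  if (is.na(adc_ref) || adc_ref <= 0) {
    radc_t <- NA_real_
    radc_s <- rep(NA_real_, length(adc_s))
  } else {
    radc_t <- normalize_radc(adc_t, adc_ref)
    radc_s <- vapply(adc_s, normalize_radc, numeric(1), reference = adc_ref)
  }
  ratio_s <- vapply(adc_s, function(s) tumor_to_shell_ratio(adc_t, s),
                    numeric(1))
  vox_vol <- prod(shells$tumor$spacing)

  out <- data.frame(adc_tumor = adc_t,
                    adc_shell1 = adc_s[1], adc_shell2 = adc_s[2],
                    adc_shell3 = adc_s[3],
                    adc_reference = adc_ref,
                    radc_tumor = radc_t,
                    radc_shell1 = radc_s[1], radc_shell2 = radc_s[2],
                    radc_shell3 = radc_s[3],
                    ratio_shell1 = ratio_s[1], ratio_shell2 = ratio_s[2],
                    ratio_shell3 = ratio_s[3],
                    tumor_volume_mm3 = sum(shells$tumor$data) * vox_vol)
  attr(out, "qc") <- list(clipped = shells$clipped, empty = shells$empty,
                          erosion_fallback = shells$erosion_fallback)
  out
}
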