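# Geometry: isotropic resampling, one-voxel erosion, Euclidean distance
# field, concentric peritumoral shells, and the mirrored contralateral
# reference VOI.
#
# Convention: shell distances are measured from the ORIGINAL (un-eroded)
# tumor boundary; the one-voxel erosion defines only the intratumoral
# measurement VOI. Shell bands are half-open intervals (inner, outer] in mm
# so that 0-2 / 2-5 / 5-10 tile without overlap.

#' Default peritumoral shell specification
#'
#' Three concentric bands at 0-2, 2-5 and 5-10 mm from the tumor surface,
#' as half-open intervals `(inner, outer]`.
#'
#' @param breaks Increasing numeric vector of band edges in mm, starting
#'   at 0.
#' @return A data frame with columns `inner_mm`, `outer_mm`, one row per
#'   shell.
#' @export
shell_spec <- function(breaks = c(0, 2, 5, 10)) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || any(diff(breaks) <= 0) || breaks[1] < 0)
    stop("parameter error: shell breaks must be increasing and start >= 0",
         call. = FALSE)
  data.frame(inner_mm = breaks[-length(breaks)], outer_mm = breaks[-1])
}

check_shell_spec <- function(specs) {
  if (!is.data.frame(specs) ||
      !all(c("inner_mm", "outer_mm") %in% names(specs)))
    stop("parameter error: specs must have inner_mm/outer_mm columns",
         call. = FALSE)
  if (any(specs$inner_mm >= specs$outer_mm) || any(specs$inner_mm < 0))
    stop("parameter error: need 0 <= inner_mm < outer_mm", call. = FALSE)
  if (nrow(specs) > 1L) {
    o <- order(specs$inner_mm)
    s <- specs[o, ]
    if (any(s$outer_mm[-nrow(s)] > s$inner_mm[-1] + 1e-9))
      stop("parameter error: overlapping shell specs", call. = FALSE)
    specs <- s
  }
  specs
}

# physical voxel-center coordinate of 1-based index i along one axis
axis_coords <- function(n, sp, or) or + (seq_len(n) - 1) * sp

#' Resample a volume (and its masks) to isotropic spacing
#'
#' The volume is interpolated tri-linearly at the new voxel centers; masks
#' are interpolated nearest-neighbor and re-binarized. The new grid keeps
#' the same origin and covers the original physical extent to within one
#' voxel.
#'
#' @param volume An [image_volume()].
#' @param masks Optional list of [binary_mask()] on the same grid.
#' @param target_mm Isotropic target voxel size in mm (default 1).
#' @return A list with elements `volume` and `masks`.
#' @export
resample_isotropic <- function(volume, masks = list(), target_mm = 1.0) {
  if (!is.finite(target_mm) || target_mm <= 0)
    stop("parameter error: target_mm must be > 0", call. = FALSE)
  olddim <- dim(volume$data)
  sp <- volume$spacing
  # keep last voxel center inside the original extent
  newdim <- pmax(1L, as.integer(floor((olddim - 1) * sp / target_mm + 1e-9)) + 1L)
  newsp <- rep(target_mm, 3)

  # continuous (1-based) source index of each new voxel center, per axis
  idx <- lapply(1:3, function(a) {
    x <- axis_coords(newdim[a], newsp[a], volume$origin[a])
    (x - volume$origin[a]) / sp[a] + 1
  })

  vol_out <- interp_trilinear(volume$data, idx, newdim)
  out_masks <- lapply(masks, function(m) {
    if (!same_grid(m, volume))
      stop("geometry error: mask grid does not match volume", call. = FALSE)
    md <- interp_nearest(m$data, idx, newdim, dim(m$data))
    binary_mask(md, spacing = newsp, origin = volume$origin, role = m$role)
  })
  list(volume = image_volume(vol_out, spacing = newsp,
                             origin = volume$origin),
       masks = out_masks)
}

# vectorized trilinear interpolation at continuous 1-based indices given as
# per-axis vectors (tensor grid)
interp_trilinear <- function(arr, idx, newdim) {
  d <- dim(arr)
  cl <- lapply(1:3, function(a) pmin(pmax(idx[[a]], 1), d[a]))
  i0 <- lapply(1:3, function(a) pmin(floor(cl[[a]]), d[a] - ifelse(d[a] > 1, 1, 0)))
  fr <- lapply(1:3, function(a) if (d[a] > 1) cl[[a]] - i0[[a]] else rep(0, newdim[a]))
  i0 <- lapply(1:3, function(a) pmax(i0[[a]], 1))
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, d[a]))

  gx0 <- rep(i0[[1]], times = newdim[2] * newdim[3])
  gx1 <- rep(i1[[1]], times = newdim[2] * newdim[3])
  fx <- rep(fr[[1]], times = newdim[2] * newdim[3])
  gy0 <- rep(rep(i0[[2]], each = newdim[1]), times = newdim[3])
  gy1 <- rep(rep(i1[[2]], each = newdim[1]), times = newdim[3])
  fy <- rep(rep(fr[[2]], each = newdim[1]), times = newdim[3])
  gz0 <- rep(i0[[3]], each = newdim[1] * newdim[2])
  gz1 <- rep(i1[[3]], each = newdim[1] * newdim[2])
  fz <- rep(fr[[3]], each = newdim[1] * newdim[2])

  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v <-
    at(gx0, gy0, gz0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(gx1, gy0, gz0) * fx       * (1 - fy) * (1 - fz) +
    at(gx0, gy1, gz0) * (1 - fx) * fy       * (1 - fz) +
    at(gx1, gy1, gz0) * fx       * fy       * (1 - fz) +
    at(gx0, gy0, gz1) * (1 - fx) * (1 - fy) * fz +
    at(gx1, gy0, gz1) * fx       * (1 - fy) * fz +
    at(gx0, gy1, gz1) * (1 - fx) * fy       * fz +
    at(gx1, gy1, gz1) * fx       * fy       * fz
  array(v, dim = newdim)
}

interp_nearest <- function(arr, idx, newdim, d) {
  nn <- lapply(1:3, function(a) pmin(pmax(round(idx[[a]]), 1), d[a]))
  gx <- rep(nn[[1]], times = newdim[2] * newdim[3])
  gy <- rep(rep(nn[[2]], each = newdim[1]), times = newdim[3])
  gz <- rep(nn[[3]], each = newdim[1] * newdim[2])
  array(arr[cbind(gx, gy, gz)], dim = newdim)
}

shift_and <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx + dx; fy <- sy + dy; fz <- sz + dz
  ok_x <- fx >= 1 & fx <= d[1]
  ok_y <- fy >= 1 & fy <= d[2]
  ok_z <- fz >= 1 & fz <= d[3]
  out[sx[ok_x], sy[ok_y], sz[ok_z]] <- m[fx[ok_x], fy[ok_y], fz[ok_z]]
  out
}

#' One-voxel binary erosion (6-connected)
#'
#' A voxel survives the erosion iff it and all six face-adjacent neighbors
#' are inside the mask; neighbors beyond the image border count as outside.
#' If the erosion empties the mask (degenerately small tumors), the original
#' mask is returned with attribute `erosion_fallback = TRUE` and a warning,
#' so measurement can still proceed.
#'
#' @param mask A nonempty [binary_mask()].
#' @return The eroded [binary_mask()] (role `"tumor"` retained); attribute
#'   `erosion_fallback` is `TRUE` when the fallback was taken.
#' @export
erode_one_voxel <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("'mask' must be a binary_mask")
  m <- mask$data
  if (!any(m)) stop("empty-mask error: cannot erode an empty mask",
                    call. = FALSE)
  er <- m &
    shift_and(m, 1, 0, 0) & shift_and(m, -1, 0, 0) &
    shift_and(m, 0, 1, 0) & shift_and(m, 0, -1, 0) &
    shift_and(m, 0, 0, 1) & shift_and(m, 0, 0, -1)
  if (!any(er)) {
    warning("erosion emptied the tumor VOI; falling back to the un-eroded mask")
    out <- mask
    attr(out, "erosion_fallback") <- TRUE
    return(out)
  }
  out <- binary_mask(er, spacing = mask$spacing, origin = mask$origin,
                     role = mask$role)
  attr(out, "erosion_fallback") <- FALSE
  out
}

#' Euclidean distance to the tumor surface
#'
#' For every voxel outside the tumor, the Euclidean distance in mm (using
#' the physical voxel spacing) to the nearest tumor voxel center; voxels
#' inside the tumor get 0. Computed with a separable exact distance
#' transform.
#'
#' @param tumor A nonempty [binary_mask()].
#' @return An [image_volume()] holding the distance field (mm).
#' @export
boundary_distance_field <- function(tumor) {
  if (!any(tumor$data))
    stop("empty-mask error: tumor mask is empty", call. = FALSE)
  d <- .edt_cpp(as.logical(tumor$data), dim(tumor$data),
                as.numeric(tumor$spacing))
  image_volume(array(d, dim = dim(tumor$data)), spacing = tumor$spacing,
               origin = tumor$origin)
}

#' Build the eroded tumor VOI and concentric peritumoral shells
#'
#' Shell k contains the voxels with `inner < distance <= outer` (mm, from
#' the un-eroded tumor surface) that lie outside the tumor, inside the
#' image, and outside the optional exclusion mask. The tumor VOI is the
#' one-voxel-eroded tumor. A shell's `clipped` flag is set when tissue at
#' distance <= outer falls outside the grid (the band touches the image
#' border); its `empty` flag when it has zero voxels.
#'
#' @param tumor Nonempty tumor [binary_mask()].
#' @param specs Shell bands from [shell_spec()]; must be sorted and
#'   non-overlapping.
#' @param exclusion Optional exclusion [binary_mask()] (may be empty).
#' @return An object of class `shell_set`: list with `tumor_voi`, `shells`
#'   (list of masks), `distance_field`, `specs`, `clipped`, `empty`,
#'   `erosion_fallback`, and `tumor` (the un-eroded input mask).
#' @export
build_shells <- function(tumor, specs = shell_spec(), exclusion = NULL) {
  specs <- check_shell_spec(specs)
  if (!is.null(exclusion) && !same_grid(exclusion, tumor))
    stop("geometry error: exclusion grid does not match tumor grid",
         call. = FALSE)
  dfield <- boundary_distance_field(tumor)
  tumor_voi <- erode_one_voxel(tumor)
  d <- dfield$data
  excl <- if (is.null(exclusion)) array(FALSE, dim(d)) else exclusion$data
  dd <- dim(d)
  on_border <- array(FALSE, dd)
  on_border[c(1, dd[1]), , ] <- TRUE
  on_border[, c(1, dd[2]), ] <- TRUE
  on_border[, , c(1, dd[3])] <- TRUE

  shells <- vector("list", nrow(specs))
  clipped <- logical(nrow(specs))
  empty <- logical(nrow(specs))
  for (k in seq_len(nrow(specs))) {
    inner <- specs$inner_mm[k]; outer <- specs$outer_mm[k]
    sel <- d > inner & d <= outer & !tumor$data & !excl
    clipped[k] <- any(on_border & d <= outer & !tumor$data)
    empty[k] <- !any(sel)
    # built under the empty-tolerant role, then relabelled: a shell may be
    # legitimately empty (fully excluded), signalled via the empty flag
    shells[[k]] <- binary_mask(array(as.numeric(sel), dd),
                               spacing = tumor$spacing,
                               origin = tumor$origin, role = "exclusion")
    shells[[k]]$role <- "shell"
  }
  structure(list(tumor = tumor, tumor_voi = tumor_voi, shells = shells,
                 distance_field = dfield, specs = specs, clipped = clipped,
                 empty = empty,
                 erosion_fallback = isTRUE(attr(tumor_voi,
                                                "erosion_fallback")),
                 reference_voi = NULL),
            class = "shell_set")
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("shell_set: tumor VOI %d voxels (un-eroded %d), %d shells\n",
              sum(x$tumor_voi$data), sum(x$tumor$data), length(x$shells)))
  for (k in seq_along(x$shells))
    cat(sprintf("  shell %d (%g, %g] mm: %d voxels%s%s\n", k,
                x$specs$inner_mm[k], x$specs$outer_mm[k],
                sum(x$shells[[k]]$data),
                if (x$clipped[k]) " [clipped]" else "",
                if (x$empty[k]) " [empty]" else ""))
  invisible(x)
}

#' Mirror the tumor VOI into the contralateral breast
#'
#' Reflects the tumor VOI across the mid-plane of the left-right (x) axis,
#' producing a reference VOI of identical voxel count at the same
#' z-range ("same anatomical level"). The volume must span both breasts:
#' if the reflected VOI overlaps the tumor itself the reflection is not
#' anatomically meaningful and a geometry error asks for a manual
#' reference mask instead.
#'
#' @param tumor_voi A [binary_mask()] (typically the un-eroded tumor).
#' @param volume The [image_volume()] the mask lives on (grid check only).
#' @return A [binary_mask()] with role `"reference"`.
#' @export
mirror_reference_voi <- function(tumor_voi, volume) {
  if (!same_grid(tumor_voi, volume))
    stop("geometry error: mask grid does not match volume", call. = FALSE)
  m <- tumor_voi$data
  refl <- m[dim(m)[1]:1, , , drop = FALSE]
  if (any(refl & m))
    stop(paste("geometry error: reflected VOI overlaps the tumor;",
               "supply a manual reference mask"), call. = FALSE)
  binary_mask(array(as.numeric(refl), dim(m)), spacing = tumor_voi$spacing,
              origin = tumor_voi$origin, role = "reference")
}
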