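# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive elementwise loops so they share no code path with the package.

make_sphere_mask <- function(radius_mm, dim = rep(2 * ceiling(radius_mm) + 21, 3),
                             spacing = c(1, 1, 1), center = NULL) {
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  cx <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
  d2 <- outer(outer((cx[[1]] - center[1])^2, (cx[[2]] - center[2])^2, "+"),
              (cx[[3]] - center[3])^2, "+")
  binary_mask(array(as.numeric(d2 <= radius_mm^2), dim), spacing = spacing)
}

make_blob_mask <- function(dim, spacing = c(1, 1, 1), p = 0.03, seed = 1) {
  set.seed(seed)
  m <- array(runif(prod(dim)) < p, dim)
  if (!any(m)) m[ceiling(dim[1] / 2), ceiling(dim[2] / 2),
                 ceiling(dim[3] / 2)] <- TRUE
  binary_mask(array(as.numeric(m), dim), spacing = spacing)
}

# O(N * M) exhaustive distance field: per-voxel minimum over all tumor
# voxels of the physical Euclidean distance
brute_force_edt <- function(mask) {
  d <- dim(mask$data); sp <- mask$spacing
  idx <- which(mask$data, arr.ind = TRUE)
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  best <- rep(Inf, nrow(co))
  for (r in seq_len(nrow(idx))) {
    dd <- ((co[, 1] - idx[r, 1]) * sp[1])^2 +
          ((co[, 2] - idx[r, 2]) * sp[2])^2 +
          ((co[, 3] - idx[r, 3]) * sp[3])^2
    best <- pmin(best, dd)
  }
  array(sqrt(best), d)
}

# brute-force 6-connected erosion: a voxel survives iff all face neighbors
# (outside counts as background) are inside
brute_force_erode <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    ok <- TRUE
    for (r in 1:6) {
      if (any(nb[r, ] < 1) || any(nb[r, ] > d)) { ok <- FALSE; break }
      if (!m[nb[r, 1], nb[r, 2], nb[r, 3]]) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  out
}

# brute-force AUC: concordant-pair counting with tie weight 1/2
brute_force_auc <- function(scores, labels, low_positive = FALSE) {
  if (low_positive) scores <- -scores
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

write_temp_nifti <- function(x) {
  f <- tempfile(fileext = ".nii.gz")
  write_volume(x, f)
  f
}
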