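# Low-level array machinery shared by the smoothing, marker and watershed
# code: reflective-boundary separable convolution, shift operators, 3D
# connected-component labelling and neighbourhood offsets. Volumes are plain
# numeric arrays indexed [x, y, z]; nz = 1 encodes 2D.

# Coerce a matrix or EBImage Image to a 3D array [nx, ny, nz].
as_volume <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 2D or 3D array, got ", length(dim(x)), " dimensions")
  x
}

is_flat <- function(x) dim(as_volume(x))[3] == 1L

# Reflective (symmetric, edge-inclusive) index map for positions 1..n; this
# padding preserves constants and conserves total intensity under convolution
# with a normalized kernel.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j >= n, period - 1L - j, j) + 1L)
}

# 1D convolution along dimension `along` of a 3D array with reflective
# boundary. Kernel is centred (odd length).
conv1d <- function(vol, kernel, along) {
  vol <- as_volume(vol)
  n <- dim(vol)[along]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(vol))
  for (k in seq_along(kernel)) {
    w <- kernel[k]
    if (w == 0) next
    src <- reflect_index(seq_len(n) + (k - 1L - r), n)
    out <- out + w * switch(along,
      vol[src, , , drop = FALSE],
      vol[, src, , drop = FALSE],
      vol[, , src, drop = FALSE])
  }
  out
}

gaussian_kernel <- function(sd, radius = max(1L, ceiling(3 * sd))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

# Separable Gaussian smoothing in-plane (and through z when planewise = FALSE
# and the volume has depth). `sd` is in voxels.
gauss_smooth <- function(vol, sd, planewise = TRUE, radius = NULL) {
  vol <- as_volume(vol)
  if (sd <= 0) return(vol)
  k <- if (is.null(radius)) gaussian_kernel(sd) else gaussian_kernel(sd, radius)
  out <- conv1d(conv1d(vol, k, 1L), k, 2L)
  if (!planewise && dim(vol)[3] > 1L) out <- conv1d(out, k, 3L)
  out
}

# Box (moving-average) filter in-plane; window = 2*rad + 1 per axis.
box_mean <- function(vol, rad) {
  k <- rep(1 / (2 * rad + 1), 2 * rad + 1)
  conv1d(conv1d(as_volume(vol), k, 1L), k, 2L)
}

# Central-difference derivative along one dimension, reflective boundary
# (so the one-sided boundary derivative is zero, consistent with mirroring).
deriv_central <- function(vol, along, spacing = 1) {
  vol <- as_volume(vol)
  n <- dim(vol)[along]
  fwd <- reflect_index(seq_len(n) + 1L, n)
  bwd <- reflect_index(seq_len(n) - 1L, n)
  d <- switch(along,
    vol[fwd, , , drop = FALSE] - vol[bwd, , , drop = FALSE],
    vol[, fwd, , drop = FALSE] - vol[, bwd, , drop = FALSE],
    vol[, , fwd, drop = FALSE] - vol[, , bwd, drop = FALSE])
  d / (2 * spacing)
}

# Offsets of the 8- (2D) or 26- (3D) connected neighbourhood as linear-index
# deltas on a padded array. Returns list(delta=..., pad_dim=...).
neighbour_offsets <- function(dm) {
  nx <- dm[1] + 2L; ny <- dm[2] + 2L
  flat <- dm[3] == 1L
  dz <- if (flat) 0L else -1L:1L
  off <- expand.grid(dx = -1L:1L, dy = -1L:1L, dz = dz)
  off <- off[!(off$dx == 0L & off$dy == 0L & off$dz == 0L), ]
  as.integer(off$dx + off$dy * nx + off$dz * nx * ny)
}

pad_volume <- function(vol, value = 0) {
  dm <- dim(vol)
  out <- array(value, dm + c(2L, 2L, if (dm[3] > 1L) 2L else 0L))
  if (dm[3] > 1L) out[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- vol
  else out[2:(dm[1] + 1L), 2:(dm[2] + 1L), 1L] <- vol
  out
}

unpad_volume <- function(pv, dm) {
  if (dm[3] > 1L) pv[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L), drop = FALSE]
  else array(pv[2:(dm[1] + 1L), 2:(dm[2] + 1L), 1L], dm)
}

# Connected components of a binary volume, 8/26-connectivity, labels 1..K in
# first-voxel order. Pure label propagation to a fixed point; adequate for the
# stack sizes this package targets.
label_components <- function(mask) {
  mask <- as_volume(mask) > 0
  dm <- dim(mask)
  if (!any(mask)) return(array(0L, dm))
  pv <- pad_volume(mask, FALSE)
  lab <- array(0L, dim(pv))
  fg <- which(pv)
  lab[fg] <- seq_along(fg)
  delta <- neighbour_offsets(dm)
  repeat {
    cur <- lab[fg]
    for (d in delta) {
      nb <- lab[fg + d]
      upd <- nb > 0L & nb < cur
      cur[upd] <- nb[upd]
    }
    if (all(cur == lab[fg])) break
    lab[fg] <- cur
  }
  # second sweep: propagation above only lowers towards local minima; iterate
  # until global fixed point is genuine (handles snake-shaped components)
  repeat {
    changed <- FALSE
    cur <- lab[fg]
    for (d in delta) {
      nb <- lab[fg + d]
      upd <- nb > 0L & nb < cur
      if (any(upd)) { cur[upd] <- nb[upd]; changed <- TRUE }
    }
    lab[fg] <- cur
    if (!changed) break
  }
  out <- unpad_volume(lab, dm)
  ids <- unique(out[out > 0L])
  out[out > 0L] <- match(out[out > 0L], sort(ids))
  storage.mode(out) <- "integer"
  out
}

# Binary erosion/dilation with a 3x3 (planewise) cross or box element.
binary_erode1 <- function(mask, planewise = TRUE) {
  mask <- as_volume(mask) > 0
  dm <- dim(mask)
  pv <- pad_volume(mask, TRUE)      # pad TRUE: border voxels keep support
  out <- pv
  delta <- if (planewise || dm[3] == 1L) neighbour_offsets(c(dm[1], dm[2], 1L)) else neighbour_offsets(dm)
  idx <- which(pad_volume(array(TRUE, dm), FALSE))
  keep <- rep(TRUE, length(idx))
  for (d in delta) keep <- keep & pv[idx + d]
  out[idx] <- pv[idx] & keep
  unpad_volume(out, dm)
}

binary_dilate1 <- function(mask, planewise = TRUE) {
  mask <- as_volume(mask) > 0
  dm <- dim(mask)
  pv <- pad_volume(mask, FALSE)
  delta <- if (planewise || dm[3] == 1L) neighbour_offsets(c(dm[1], dm[2], 1L)) else neighbour_offsets(dm)
  idx <- which(pad_volume(array(TRUE, dm), FALSE))
  hit <- pv[idx]
  for (d in delta) hit <- hit | pv[idx + d]
  out <- pv
  out[idx] <- hit
  unpad_volume(out, dm)
}

# Voxels of `labels` adjacent (8/26) to a voxel carrying a different label;
# background (0) does not count as different unless include_bg.
boundary_shell <- function(labels, include_bg = FALSE) {
  labels <- as_volume(labels)
  dm <- dim(labels)
  pv <- pad_volume(labels, -1L)
  idx <- which(pad_volume(array(TRUE, dm), FALSE))
  ctr <- pv[idx]
  diffnb <- rep(FALSE, length(idx))
  for (d in neighbour_offsets(dm)) {
    nb <- pv[idx + d]
    diffnb <- diffnb | (nb != ctr & nb != -1L & (include_bg | nb != 0L))
  }
  out <- array(FALSE, dm)
  out[ctr > 0L & diffnb] <- TRUE
  out
}

# Normalize an array to [0, 1]; constant arrays map to 0.
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(array(0, dim(as_volume(x))))
  (as_volume(x) - r[1]) / (r[2] - r[1])
}

# Evaluate an expression with a locally fixed RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
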