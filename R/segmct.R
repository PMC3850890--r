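# Segmentation of stained nuclei (or cytoplasmically stained cells):
# binarize by adaptive or iterative thresholding, optionally split fused
# objects on a distance transform, label components, and filter by physical
# volume. Used stand-alone and to generate nucleus-derived watershed markers.

#' Otsu threshold
#'
#' Histogram threshold maximizing the between-class variance, computed over
#' `nbins` equal-width bins of the intensity range.
#'
#' @param im Numeric array or vector.
#' @param nbins Number of histogram bins.
#' @return Threshold on the intensity scale of `im`.
#' @export
otsu_threshold <- function(im, nbins = 256L) {
  v <- as.numeric(im)
  r <- range(v)
  if (r[1] == r[2]) stop("degenerate histogram: image is constant")
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins), nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, nbins)
  sb[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sb)
  edges[k + 1L]   # threshold between bin k and k+1; foreground: im > T
}

#' Adaptive (local-mean) thresholding
#'
#' A voxel is foreground when it exceeds its local mean by `adth` times the
#' global intensity range. Capturing whole cells requires a window radius of
#' the order of the cell radius. Applied planewise on 3D stacks.
#'
#' @param im 2D/3D intensity array.
#' @param filtrad Window radius in voxels (window size `2*filtrad + 1`).
#' @param adth Relative offset (fraction of `max(im) - min(im)`).
#' @return Logical array.
#' @export
threshold_adaptive <- function(im, filtrad = 20, adth = 0.20) {
  if (filtrad < 1) stop("filtrad must be >= 1")
  im <- as_volume(im)
  localmean <- box_mean(im, as.integer(filtrad))
  im - localmean > adth * (max(im) - min(im))
}

#' Iterative global thresholding
#'
#' Starts at `th_multiplier` times the Otsu threshold and lowers the threshold
#' by a factor 0.95 per iteration until the largest foreground component
#' reaches the minimum cell volume (or the threshold hits zero). The
#' foreground grows monotonically as the threshold decreases.
#'
#' @param im 2D/3D intensity array (non-constant).
#' @param th_multiplier Multiplier of the initial Otsu threshold.
#' @param minvol Minimum cell volume in cubic micrometres.
#' @param h Voxel size (um).
#' @return Logical array.
#' @export
threshold_iterative <- function(im, th_multiplier = 1.0, minvol = 0, h = c(1, 1, 1)) {
  im <- as_volume(im)
  Tcur <- th_multiplier * otsu_threshold(im)
  vvox <- prod(h)
  lowest <- min(im)
  repeat {
    fg <- im > Tcur
    if (any(fg)) {
      cc <- label_components(fg)
      if (max(tabulate(cc[cc > 0L])) * vvox >= minvol) break
    }
    if (Tcur <= lowest || Tcur <= 0) break
    Tcur <- Tcur * 0.95
  }
  im > Tcur
}

# --- distance transform and h-maxima ----------------------------------------

# Exact Euclidean distance transform of a binary 2D plane with anisotropic
# pixel spacing (hx, hy): squared-distance lower envelope (Felzenszwalb &
# Huttenlocher) pass along x then y.
edt2d <- function(mask, hx = 1, hy = 1) {
  mask <- as.matrix(mask[, , 1, drop = TRUE])
  if (is.null(dim(mask))) mask <- matrix(mask, ncol = 1)
  INF <- 1e18
  f <- ifelse(mask > 0, INF, 0)
  f <- apply(f, 2, dt1d, spacing = hx)
  f <- t(apply(t(f), 2, dt1d, spacing = hy))
  sqrt(f)
}

# 1D squared-distance transform (lower envelope of parabolas).
dt1d <- function(f, spacing = 1) {
  n <- length(f)
  if (all(f == 0) || n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  s2 <- spacing^2
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + s2 * q^2) - (f[v[k]] + s2 * v[k]^2)) / (2 * s2 * (q - v[k]))
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- s2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

# Grayscale reconstruction by dilation of `marker` under `mask` (2D matrix),
# 8-connected; iterative geodesic dilation to a fixed point.
grayrec2d <- function(marker, mask) {
  m <- pmin(marker, mask)
  dm <- c(dim(m), 1L)
  pv_mask <- pad_volume(array(mask, dm), -Inf)
  pv <- pad_volume(array(m, dm), -Inf)
  idx <- which(pad_volume(array(TRUE, dm), FALSE))
  delta <- neighbour_offsets(dm)
  repeat {
    cur <- pv[idx]
    upd <- cur
    for (d in delta) upd <- pmax(upd, pv[idx + d])
    upd <- pmin(upd, pv_mask[idx])
    if (all(upd == cur)) break
    pv[idx] <- upd
  }
  matrix(pv[idx], dim(mask)[1], dim(mask)[2])
}

# Extended maxima (regional maxima of the h-maxima transform) of a 2D map.
extended_maxima2d <- function(x, hdepth) {
  H <- grayrec2d(x - hdepth, x)
  pos <- unique(sort(H))
  eps <- if (length(pos) > 1) min(diff(pos)) / 2 else 1e-9
  rm_ <- H - grayrec2d(H - eps, H) > 0
  rm_
}

#' Split fused objects via the distance transform
#'
#' Fused nuclei lack strong edges between them but pinch at the fusion waist.
#' At one reference plane (default one third of the stack height) the
#' Euclidean distance transform of the foreground is computed in physical
#' units; its extended maxima of depth `splitth` seed a marker-controlled
#' watershed on the negated distance map, cutting the foreground where the
#' distance to one maximum equals the distance to another. Smaller `splitth`
#' values split more aggressively. The 2D cut is propagated through the stack
#' by stamping the split-plane labels down each foreground column (unlabelled
#' foreground falls to the nearest split label in-plane).
#'
#' @param binary Binary 2D/3D array (non-empty).
#' @param splitth h-maxima depth in micrometres (> 0).
#' @param splitplane `"auto"` (=> `max(1, round(nz/3))`) or a 1-based plane.
#' @param h Voxel size (um).
#' @return Integer label array partitioning the input foreground exactly.
#' @export
split_cells <- function(binary, splitth = 1.0, splitplane = "auto", h = c(1, 1, 1)) {
  binary <- as_volume(binary) > 0
  if (!any(binary)) stop("split_cells: empty foreground")
  if (splitth <= 0) stop("splitth must be > 0")
  dm <- dim(binary)
  nz <- dm[3]
  pl <- if (identical(splitplane, "auto")) max(1L, as.integer(round(nz / 3))) else as.integer(splitplane)
  if (pl < 1L || pl > nz) stop("splitplane out of range")
  plane <- binary[, , pl, drop = FALSE]
  if (!any(plane)) {
    # reference plane empty: fall back to the plane with most foreground
    pl <- which.max(apply(binary, 3, sum))
    plane <- binary[, , pl, drop = FALSE]
  }
  dist <- edt2d(plane, h[1], h[2])
  seeds <- extended_maxima2d(dist, splitth) & plane[, , 1]
  seed_lab <- label_components(seeds)
  if (max(seed_lab) <= 1L) {
    out <- array(0L, dm); out[binary] <- 1L
    return(out)
  }
  plane_lab <- watershed_markers(-dist, seed_lab, mask = plane[, , 1] > 0)
  plane_lab <- plane_lab[, , 1]
  # stamp the split-plane labels down/up every column; foreground columns with
  # no split label take the nearest label in-plane (geodesic dilation)
  filled <- plane_lab
  while (any(filled == 0L & plane[, , 1])) {
    grown <- grow_labels_once(filled)
    grown[!plane[, , 1]] <- 0L
    if (identical(grown, filled)) break
    filled <- grown
  }
  # columns outside the reference-plane foreground: nearest label anywhere
  full <- filled
  while (any(full == 0L)) {
    grown <- grow_labels_once(full)
    if (identical(grown, full)) break
    full <- grown
  }
  storage.mode(full) <- "integer"
  # 3D components intersecting the split plane take the stamped column labels
  # (vertical cut walls; slivers inherit their column's label); components
  # that never reach the split plane keep one fresh label each
  comp3d <- label_components(binary)
  stamp <- array(rep(full, nz), dm)
  out <- array(0L, dm)
  nxt <- max(full)
  for (cid in seq_len(max(comp3d))) {
    vox <- comp3d == cid
    at_plane <- any(vox[, , pl] & plane_lab > 0L)
    if (at_plane) out[vox] <- stamp[vox]
    else { nxt <- nxt + 1L; out[vox] <- nxt }
  }
  storage.mode(out) <- "integer"
  out
}

# One step of label dilation on a 2D label matrix (ties -> lower label).
grow_labels_once <- function(labmat) {
  dm <- c(dim(labmat), 1L)
  pv <- pad_volume(array(labmat, dm), 0L)
  idx <- which(pad_volume(array(TRUE, dm), FALSE))
  cur <- pv[idx]
  best <- cur
  for (d in neighbour_offsets(dm)) {
    nb <- pv[idx + d]
    take <- best == 0L & nb > 0L
    best[take] <- nb[take]
    tie <- best > 0L & nb > 0L & nb < best & cur == 0L
    best[tie] <- nb[tie]
  }
  matrix(best, dim(labmat)[1], dim(labmat)[2])
}

#' Segment stained nuclei or cytoplasmically stained cells
#'
#' Binarizes the image by the chosen thresholding method, optionally splits
#' fused objects ([split_cells()]), labels connected components and removes
#' components outside the allowed physical volume range. An empty result is
#' permitted (zero regions), not an error.
#'
#' @param im 2D/3D intensity array.
#' @param minv,maxv Minimum/maximum object volume in cubic micrometres.
#' @param prm Parameter list at the segmct level (see [default_parameters()]
#'   entry `segmct`): `method` ('thrs' or 'adth'), `thrs.th`, `adth.adth`,
#'   `adth.filtrad`, `split`, `splitth`, `splitplane`, `smoothim.*`.
#' @param h Voxel size (um).
#' @param smooth Apply the configured smoothing before thresholding.
#' @return List (class `memseg_ct`): `labels` (integer array), `nregions`,
#'   `volumes` (um^3 per region), `prm`.
#' @export
segment_nuclei <- function(im, minv, maxv, prm = NULL, h = c(1, 1, 1), smooth = TRUE) {
  if (!(minv < maxv)) stop("minv must be < maxv")
  prm <- merge_params(structure(segmct_defaults(), class = "memseg_params"), prm)
  im <- as_volume(im)
  lim <- adjust_volume_limits(minv, maxv, h, dim(im)[3])
  if (max(im) == min(im)) {
    # constant image: nothing to segment
    return(structure(list(labels = array(0L, dim(im)), nregions = 0L,
                          volumes = numeric(0), prm = prm), class = "memseg_ct"))
  }
  work <- if (smooth) smooth_image(im, prm$smoothim$method, prm$smoothim) else im
  fg <- switch(prm$method,
    adth = threshold_adaptive(work, prm$adth$filtrad, prm$adth$adth),
    thrs = threshold_iterative(work, prm$thrs$th, lim$minvol, h),
    stop("unknown segmct method: '", prm$method, "'"))
  vvox <- prod(h)
  if (!any(fg)) {
    labs <- array(0L, dim(im))
    return(structure(list(labels = labs, nregions = 0L, volumes = numeric(0), prm = prm),
                     class = "memseg_ct"))
  }
  labs <- if ((prm$split %||% 1) != 0) {
    split_cells(fg, prm$splitth, prm$splitplane, h)
  } else label_components(fg)
  # compact label ids
  ids <- sort(unique(labs[labs > 0L]))
  labs[labs > 0L] <- match(labs[labs > 0L], ids)
  vols <- tabulate(labs[labs > 0L]) * vvox
  keep <- which(vols >= lim$minvol & vols <= lim$maxvol)
  out <- array(0L, dim(labs))
  out[labs > 0L & labs %in% keep] <- match(labs[labs > 0L & labs %in% keep], keep)
  storage.mode(out) <- "integer"
  vols <- vols[keep]
  structure(list(labels = out, nregions = length(keep), volumes = vols, prm = prm),
            class = "memseg_ct")
}

#' @export
print.memseg_ct <- function(x, ...) {
  cat(sprintf("nucleus/cytoplasm segmentation: %d region(s)\n", x$nregions))
  invisible(x)
}
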