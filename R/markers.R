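# Marker (seed) generation for the watershed. Three routes: 'automated'
# (adaptive thresholding of the ridge-enhanced surface stain), 'nucleus'
# (segmentation of the nucleus channel; one marker per nucleus) and 'manual'
# (user-painted masks). Output is always a marker set whose cell markers are
# a subset of all markers, with exactly one background-marker component.

#' Detect watershed markers
#'
#' Dispatches to [minima_automated()], [minima_from_nuclei()] or passes
#' manual masks through. Manual markers take priority over the nucleus route
#' when both are configured. When only `minimacell` is supplied manually, the
#' background marker is computed automatically and united with it.
#'
#' @param imsegm Preprocessed (smoothed, ridge-enhanced) surface-stain array.
#' @param imnucl Nucleus-channel array (required for `method = "nucleus"`).
#' @param manual List with `minima` and/or `minimacell` binary arrays
#'   (required for `method = "manual"`).
#' @param method One of `"automated"`, `"nucleus"`, `"manual"`.
#' @param minvol,maxvol Adjusted cell-volume limits (um^3).
#' @param level `"strong"` places the marker-extraction plane at maximal
#'   total intensity; otherwise the mid-plane is used.
#' @param prm Full parameter tree (the nucleus route resolves its segmct
#'   sub-tree from `segmsurf.getminima.nucleus`).
#' @param h Voxel size (um).
#' @return A [marker_set()].
#' @export
get_minima <- function(imsegm, imnucl = NULL, manual = NULL,
                       method = "automated", minvol, maxvol,
                       level = "default", prm = NULL, h = c(1, 1, 1)) {
  imsegm <- as_volume(imsegm)
  if (!is.null(manual) && is.null(manual[["minima"]]) && is.null(manual[["minimacell"]]))
    manual <- NULL
  if (identical(method, "manual") && is.null(manual))
    stop("method 'manual' requires minima and/or minimacell masks")
  if (!is.null(manual)) {
    if (!is.null(manual[["minima"]])) {
      # full manual specification: marker detection is skipped entirely
      return(marker_set(manual[["minima"]], manual[["minimacell"]]))
    }
    # only cell markers given: compute the background marker automatically
    bg <- background_marker(imsegm, h)
    mc <- as_volume(manual[["minimacell"]]) > 0
    return(marker_set(mc | bg, mc))
  }
  switch(method,
    automated = minima_automated(imsegm, minvol, maxvol, level = level,
                                 prm = prm, h = h),
    nucleus = {
      if (is.null(imnucl)) stop("method 'nucleus' requires a nucleus image")
      minima_from_nuclei(imsegm, imnucl, minvol, maxvol,
                         segmct_prm = if (is.null(prm)) NULL else nucleus_segmct_params(prm),
                         h = h)
    },
    stop("unknown marker method: '", method, "'")
  )
}

# Largest below-threshold connected component touching the volume border,
# taken as the background marker (eroded once to stay off membranes).
background_marker <- function(imsegm, h = c(1, 1, 1), membrane = NULL) {
  imsegm <- as_volume(imsegm)
  if (is.null(membrane)) {
    lm <- box_mean(imsegm, max(3L, min(dim(imsegm)[1:2]) %/% 4L))
    membrane <- imsegm > lm
  }
  low <- label_components(!membrane)
  dm <- dim(imsegm)
  if (max(low) == 0L) return(array(FALSE, dm))
  border <- array(FALSE, dm)
  border[1, , ] <- TRUE; border[dm[1], , ] <- TRUE
  border[, 1, ] <- TRUE; border[, dm[2], ] <- TRUE
  ids <- unique(low[border & low > 0L])
  if (length(ids) == 0L) ids <- seq_len(max(low))
  sizes <- tabulate(low[low > 0L], max(low))
  best <- ids[which.max(sizes[ids])]
  bg <- low == best
  er <- binary_erode1(bg)
  if (any(er)) er else bg
}

#' Automated markers from the surface stain
#'
#' Adaptive thresholding separates membrane from membrane-free voxels at a
#' reference plane: a voxel is "membrane" when it exceeds `(1 + a)` times its
#' local mean over a window matched to the expected cell diameter
#' `d = (6 maxvol / pi)^(1/3)`. The below-threshold connected components of
#' that plane, eroded by one voxel and kept when their (plane-extruded)
#' volume lies in `[minvol / 4, maxvol]`, become cell markers -- a marker
#' need not span its cell, it only has to sit inside it, hence the lowered
#' floor. The largest below-threshold component touching the image border
#' becomes the background marker. `level = "strong"` extracts markers at the
#' plane of maximal total intensity (useful for tissue, where that plane is
#' the most complete); the default is the mid-plane. Markers are stamped into
#' the 3D volume at the reference plane only; the watershed floods the rest.
#'
#' @inheritParams get_minima
#' @return A [marker_set()].
#' @export
minima_automated <- function(imsegm, minvol, maxvol, level = "default",
                             prm = NULL, h = c(1, 1, 1)) {
  imsegm <- as_volume(imsegm)
  dm <- dim(imsegm)
  a <- if (!is.null(prm)) prm$segmsurf$getminima$adapt_a %||% 0.02 else 0.02
  zref <- if (identical(level, "strong")) {
    which.max(apply(imsegm, 3, sum))
  } else max(1L, as.integer(ceiling(dm[3] / 2)))
  plane <- imsegm[, , zref, drop = FALSE]
  d_um <- (6 * maxvol / pi)^(1 / 3)
  win <- max(2L, as.integer(round(d_um * (1 + a) / h[1] / 2)))
  membrane <- threshold_adaptive(plane, win, a)
  if (all(membrane)) stop("no markers: the whole reference plane is membrane-like")
  free <- label_components(!membrane)
  # background: largest border-touching low component (on the reference plane)
  bgplane <- background_marker(plane, h, membrane = membrane)
  # cell candidates: interior low components, eroded, volume-filtered; a
  # candidate touching the image border cannot be membrane-enclosed and is
  # dropped. 2D areas are extruded by the axial cell extent for volume.
  border2d <- array(FALSE, dim(plane))
  border2d[c(1, dm[1]), , 1] <- TRUE; border2d[, c(1, dm[2]), 1] <- TRUE
  area_per_vox <- h[1] * h[2]
  zext <- min(dm[3] * h[3], d_um)
  minarea <- (minvol / 4) / zext / area_per_vox
  maxarea <- maxvol / max(h[3], 1e-9) / area_per_vox
  cells <- array(FALSE, dim(plane))
  ncell <- 0L
  for (k in seq_len(max(free))) {
    compk <- free == k
    if (any(compk & bgplane) || any(compk & border2d)) next
    er <- binary_erode1(compk)
    if (!any(er)) er <- compk
    npx <- sum(er)
    if (npx >= minarea && npx <= maxarea) { cells <- cells | er; ncell <- ncell + 1L }
  }
  if (ncell == 0L) stop("no markers: no candidate cell regions survived filtering")
  minima <- array(FALSE, dm); minimacell <- array(FALSE, dm)
  minima[, , zref] <- cells[, , 1] | bgplane[, , 1]
  minimacell[, , zref] <- cells[, , 1]
  marker_set(minima, minimacell)
}

#' Markers from the nucleus channel
#'
#' Runs the nucleus segmentation ([segment_nuclei()]) on the nucleus image;
#' each detected nucleus, eroded by one voxel, becomes a cell marker
#' (normally one distinct marker per cell). The background marker is taken
#' from the surface stain as in [minima_automated()].
#'
#' @param imsegm Preprocessed surface-stain array (background marker source).
#' @param imnucl Nucleus-channel array.
#' @inheritParams get_minima
#' @param segmct_prm Parameters for the nucleus segmentation (segmct level).
#' @return A [marker_set()].
#' @export
minima_from_nuclei <- function(imsegm, imnucl, minvol, maxvol,
                               segmct_prm = NULL, h = c(1, 1, 1)) {
  imnucl <- as_volume(imnucl)
  if (max(imnucl) == min(imnucl))
    stop("no markers: nucleus channel is empty/constant")
  # nuclei are smaller than cells; accept from a fraction of minvol upward
  ct <- segment_nuclei(imnucl, minv = minvol / 10, maxv = maxvol,
                       prm = segmct_prm, h = h)
  if (ct$nregions == 0L) stop("no markers: nucleus segmentation found no regions")
  cellmask <- array(FALSE, dim(imnucl))
  for (k in seq_len(ct$nregions)) {
    er <- binary_erode1(ct$labels == k)
    if (!any(er)) er <- ct$labels == k
    cellmask <- cellmask | er
  }
  bg <- background_marker(as_volume(imsegm), h)
  bg <- bg & !binary_dilate1(cellmask)
  marker_set(cellmask | bg, cellmask)
}
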