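# Surface-stain pipeline: nucleus-channel subtraction, illumination
# correction, smoothing, ridge enhancement, marker detection,
# marker-controlled watershed, and feature-based classification of the
# watershed regions into cells and background.

#' Adjust cell-volume limits for partial stacks
#'
#' The user supplies the physical volume range of a whole cell, but a stack
#' may cover less than one cell diameter in z, so observed cell volumes are
#' smaller. With expected diameter `d = (6 maxv / pi)^(1/3)` and axial extent
#' `nz * hz`, the scale `s = min(1, nz * hz / d)` shrinks the limits:
#' `minvol = s * minv`, `maxvol = maxv * (s + (1 - s) / 2)`. Full stacks
#' (`s = 1`) keep the limits unchanged; thinner stacks get strictly smaller
#' limits, the maximum less aggressively so that border-merged oversized
#' candidates are still rejected.
#'
#' @param minv,maxv Whole-cell volume limits (um^3).
#' @param h Voxel size (um).
#' @param nz Number of planes.
#' @return List with `minvol`, `maxvol`.
#' @export
adjust_volume_limits <- function(minv, maxv, h, nz) {
  d <- (6 * maxv / pi)^(1 / 3)
  s <- min(1, (nz * h[3]) / d)
  list(minvol = s * minv, maxvol = maxv * (s + (1 - s) * 0.5))
}

#' Per-region features of a label volume
#'
#' For each watershed region: physical volume; mean interior intensity and
#' mean boundary-shell intensity, both normalized by the background mean (the
#' mean intensity of the background regions, unless `meanintbck` overrides
#' it); and two convexity measures, region size over convex-hull size for the
#' area and hull boundary over region boundary for the perimeter (both <= 1
#' up to voxelization). Convex hulls are computed planewise on the voxel
#' point set and aggregated over planes.
#'
#' @param labels Integer label array from the watershed.
#' @param im Intensity array the features are measured on.
#' @param background_labels Labels flagged as background (for the mean).
#' @param meanintbck Optional manual background mean intensity.
#' @param h Voxel size (um).
#' @return `data.frame` with one row per label.
#' @export
compute_features <- function(labels, im, background_labels = integer(0),
                             meanintbck = NA_real_, h = c(1, 1, 1)) {
  labels <- as_volume(labels); im <- as_volume(im)
  ids <- sort(unique(labels[labels > 0L]))
  vvox <- prod(h)
  bck <- if (is.finite(meanintbck)) meanintbck
         else if (length(background_labels)) mean(im[labels %in% background_labels])
         else NA_real_
  if (!is.finite(bck) || bck <= 0)
    stop("background mean intensity is zero or unavailable; supply meanintbck")
  shell <- boundary_shell(labels, include_bg = TRUE)
  out <- data.frame(label = ids, volume = NA_real_, intincell = NA_real_,
                    intborder = NA_real_, convexarea = NA_real_, convexperim = NA_real_)
  for (i in seq_along(ids)) {
    k <- ids[i]
    sel <- labels == k
    nvox <- sum(sel)
    out$volume[i] <- nvox * vvox
    border <- sel & shell
    interior <- sel & !shell
    if (!any(interior)) interior <- sel
    if (!any(border)) border <- sel
    out$intincell[i] <- mean(im[interior]) / bck
    out$intborder[i] <- mean(im[border]) / bck
    hull <- region_hull_measures(sel)
    out$convexarea[i] <- hull$area_ratio
    out$convexperim[i] <- hull$perim_ratio
  }
  out
}

# Planewise convex-hull measures of one region: sum over planes of region
# area / hull area, and hull perimeter / region boundary length.
region_hull_measures <- function(sel) {
  dm <- dim(sel)
  area_reg <- 0; area_hull <- 0; per_reg <- 0; per_hull <- 0
  for (z in seq_len(dm[3])) {
    pz <- sel[, , z]
    n <- sum(pz)
    if (n == 0) next
    area_reg <- area_reg + n
    pts <- which(pz, arr.ind = TRUE)
    if (n <= 2) {
      area_hull <- area_hull + n
      per_reg <- per_reg + n; per_hull <- per_hull + n
      next
    }
    ch <- chull(pts)
    poly <- pts[ch, , drop = FALSE]
    area_hull <- area_hull + max(polygon_area(poly), n)
    per_hull <- per_hull + polygon_perimeter(poly)
    # region boundary length: pixels with a non-region 4-neighbour
    per_reg <- per_reg + boundary_length2d(pz)
  }
  list(area_ratio = min(1, area_reg / max(area_hull, 1)),
       perim_ratio = if (per_reg > 0) min(1, per_hull / per_reg) else 1)
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  dx <- diff(c(p[, 1], p[1, 1])); dy <- diff(c(p[, 2], p[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

boundary_length2d <- function(pz) {
  dm <- dim(pz)
  pad <- matrix(FALSE, dm[1] + 2, dm[2] + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1)] <- pz
  ctr <- pad[2:(dm[1] + 1), 2:(dm[2] + 1)]
  nb4 <- pad[1:dm[1], 2:(dm[2] + 1)] & pad[3:(dm[1] + 2), 2:(dm[2] + 1)] &
         pad[2:(dm[1] + 1), 1:dm[2]] & pad[2:(dm[1] + 1), 3:(dm[2] + 2)]
  sum(ctr & !nb4)
}

#' Classify watershed regions into cells and background
#'
#' Two methods. `"threshold"`: a region is a cell iff it satisfies every
#' active feature threshold (volume within `[minvol, maxvol]`, interior
#' intensity ratio at most `intincell`, boundary ratio at least `intborder`,
#' convexity measures at least their thresholds); `propname` selects which
#' gates are active (`"all"` or a subset of
#' `c("volume", "intincell", "intborder", "convexarea", "convexperim")`).
#' `"minimacell"`: a region is a cell iff it overlaps a cell marker and its
#' volume is within limits -- the volume gates stay active because a cell
#' region merged into the background would otherwise be accepted. Regions
#' holding only background markers are never cells.
#'
#' @param features Feature table from [compute_features()].
#' @param minvol,maxvol Adjusted volume limits (um^3).
#' @param prm `classifycells` parameter list (see [default_parameters()]).
#' @param marker_overlap Logical vector per feature row: region overlaps a
#'   cell marker (required for method `"minimacell"`).
#' @param background_labels Labels of background-marker regions.
#' @return Logical vector of cell flags, aligned with `features` rows.
#' @export
classify_cells <- function(features, minvol, maxvol, prm = NULL,
                           marker_overlap = NULL, background_labels = integer(0)) {
  defaults <- default_parameters()$segmsurf$classifycells
  prm <- if (is.null(prm)) defaults else utils::modifyList(defaults, prm)
  props <- prm$propname
  if (identical(props, "all"))
    props <- c("volume", "intincell", "intborder", "convexarea", "convexperim")
  flags <- rep(TRUE, nrow(features))
  if (identical(prm$method, "minimacell")) {
    if (is.null(marker_overlap))
      stop("classification method 'minimacell' requires cell markers")
    flags <- marker_overlap &
      features$volume >= minvol & features$volume <= maxvol
  } else if (identical(prm$method, "threshold")) {
    if ("volume" %in% props)
      flags <- flags & features$volume >= minvol & features$volume <= maxvol
    if ("intincell" %in% props) flags <- flags & features$intincell <= prm$intincell
    if ("intborder" %in% props) flags <- flags & features$intborder >= prm$intborder
    if ("convexarea" %in% props) flags <- flags & features$convexarea >= prm$convexarea
    if ("convexperim" %in% props) flags <- flags & features$convexperim >= prm$convexperim
  } else stop("unknown classification method: '", prm$method, "'")
  flags & !(features$label %in% background_labels)
}

#' Whole-cell segmentation of surface-stained cells
#'
#' The full membrane pipeline, in order: nucleus-channel subtraction (when a
#' nucleus image is given), top-hat illumination correction (when enabled),
#' smoothing, Hessian ridge enhancement (when enabled), marker detection
#' ([get_minima()]), marker-controlled watershed ([watershed_markers()]) and
#' classification ([classify_cells()]).
#'
#' @param im Surface-stain 2D/3D intensity array.
#' @param minv,maxv Whole-cell volume limits (um^3), `minv < maxv`.
#' @param prm Parameter overrides (nested list validated against
#'   [default_parameters()]).
#' @param imnucl Optional nucleus-channel array (same shape).
#' @param minima,minimacell Optional manual marker masks (binary arrays).
#' @param h Voxel size (um).
#' @return List (class `memseg_surf`): `labels` (the watershed label volume),
#'   `cell_flags` (named by label), `features`, `markers`, `prm`,
#'   `background_labels`, `minvol`/`maxvol`.
#' @export
segment_surface <- function(im, minv, maxv, prm = NULL, imnucl = NULL,
                            minima = NULL, minimacell = NULL, h = c(1, 1, 1)) {
  if (!(minv < maxv)) stop("minv must be < maxv")
  prm <- merge_params(default_parameters(), prm)
  im <- as_volume(im)
  lim <- adjust_volume_limits(minv, maxv, h, dim(im)[3])

  work <- im
  if (!is.null(imnucl)) work <- subtract_nucleus_channel(work, imnucl, prm$subtractsd)
  if ((prm$illum %||% 0) != 0)
    work <- illumination_correct(work, max(1, round(prm$illumdiameter / (2 * h[1]))))
  work <- smooth_image(work, prm$smoothim$method, prm$smoothim)
  if ((prm$segmsurf$filterridges %||% 1) != 0)
    work <- ridge_enhance(work, scale = prm$segmsurf$ridge$scale,
                          weight = prm$segmsurf$ridge$weight)

  manual <- if (!is.null(minima) || !is.null(minimacell))
    list(minima = minima, minimacell = minimacell) else NULL
  mk <- get_minima(work, imnucl = imnucl, manual = manual,
                   method = prm$segmsurf$getminima$method,
                   minvol = lim$minvol, maxvol = lim$maxvol,
                   level = prm$segmsurf$getminima$level, prm = prm, h = h)

  labels <- watershed_markers(work, mk)
  # identify which watershed labels grew from cell vs background markers
  comp <- label_components(mk$minima)
  cellmask <- if (!is.null(mk$minimacell)) mk$minimacell else array(FALSE, dim(im))
  lab_ids <- sort(unique(labels[labels > 0L]))
  overlap <- vapply(lab_ids, function(k) any(cellmask & labels == k), logical(1))
  background_labels <- lab_ids[vapply(lab_ids, function(k) {
    cs <- unique(comp[comp > 0L & labels == k])
    length(cs) > 0L && all(!vapply(cs, function(cc) any(cellmask & comp == cc), logical(1)))
  }, logical(1))]
  if (!any(cellmask)) {
    # marker typing unknown (manual minima only): take the dimmest region as
    # the background reference for intensity normalization
    mu <- vapply(lab_ids, function(k) mean(im[labels == k]), numeric(1))
    background_labels <- lab_ids[which.min(mu)]
  }

  feats <- compute_features(labels, im, background_labels = background_labels,
                            meanintbck = prm$segmsurf$classifycells$meanintbck, h = h)
  flags <- classify_cells(feats, lim$minvol, lim$maxvol,
                          prm = prm$segmsurf$classifycells,
                          marker_overlap = overlap,
                          background_labels = background_labels)
  structure(list(labels = labels, cell_flags = setNames(flags, feats$label),
                 features = feats, markers = mk, prm = prm,
                 background_labels = background_labels,
                 minvol = lim$minvol, maxvol = lim$maxvol, h = h),
            class = "memseg_surf")
}

#' @export
print.memseg_surf <- function(x, ...) {
  cat(sprintf("surface segmentation: %d region(s), %d flagged as cells\n",
              nrow(x$features), sum(x$cell_flags)))
  invisible(x)
}
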