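# Marker-controlled watershed by immersion. Each connected marker component
# floods exactly one region of the intensity landscape; flooding proceeds in
# increasing order of (quantized) intensity, within a level by breadth-first
# waves so basins grow geodesically. Where two basins meet in the same wave
# (the watershed line), the contested voxel goes to the region whose marker
# centroid is nearest, ties to the lower label -- the output is a full
# partition with no line voxels. Connectivity is 8 (2D) / 26 (3D).

#' Marker-controlled watershed
#'
#' Floods the intensity landscape `im` from the connected components of
#' `markers$minima`; every component yields exactly one region and every voxel
#' (within `mask`, if given) receives a label. Bright ridges between markers
#' become the region boundaries.
#'
#' @param im 2D/3D intensity array (bright boundaries).
#' @param markers A [marker_set()] or a binary/label array of seeds.
#' @param mask Optional binary array: flood only inside it (outside stays 0).
#' @param nlevels Number of quantization levels of the landscape.
#' @return Integer label array; labels 1..K in marker-component order.
#' @export
watershed_markers <- function(im, markers, mask = NULL, nlevels = 256L) {
  im <- as_volume(im)
  seeds <- if (inherits(markers, "memseg_markers")) markers$minima else as_volume(markers)
  if (!identical(dim(as_volume(seeds)), dim(im)))
    stop("markers must match the image dimensions")
  lab0 <- if (max(seeds) > 1L && !all(seeds %in% c(0, 1))) {
    s <- as_volume(seeds); storage.mode(s) <- "integer"; s
  } else label_components(seeds)
  K <- max(lab0)
  if (K == 0L) stop("empty marker set: no seed components to flood from")
  dm <- dim(im)
  if (!is.null(mask)) {
    mask <- as_volume(mask) > 0
    if (any(lab0 > 0L & !mask)) mask <- mask | lab0 > 0L
  } else mask <- array(TRUE, dm)

  # centroids (voxel coordinates) of each marker component, for tie-breaking
  cent <- matrix(0, K, 3)
  idx0 <- which(lab0 > 0L)
  co <- arrayInd(idx0, dm)
  for (k in seq_len(K)) cent[k, ] <- colMeans(co[lab0[idx0] == k, , drop = FALSE])

  # quantize landscape
  r <- range(im[mask])
  lev <- if (r[2] > r[1]) {
    q <- pmin(floor((im - r[1]) / (r[2] - r[1]) * (nlevels - 1L)), nlevels - 1L) + 1L
    q[q < 1L] <- 1L
    storage.mode(q) <- "integer"
    array(q, dm)
  } else array(1L, dm)

  pv_lab <- pad_volume(lab0, -1L)          # -1 marks outside the frame
  pv_lab[pad_volume(array(TRUE, dm), FALSE) & pad_volume(!mask, TRUE)] <- -1L
  pv_lev <- pad_volume(lev, 0L)
  delta <- neighbour_offsets(dm)
  inside <- which(pad_volume(array(TRUE, dm), FALSE))
  # padded coordinates for distance computation
  pdm <- dim(pv_lab)
  n_remaining <- sum(pv_lab[inside] == 0L)

  for (l in seq_len(max(lev[mask]))) {
    if (n_remaining == 0L) break
    # seed the level's breadth-first waves from every labeled voxel that still
    # touches an unlabeled one; subsequent waves grow from newly assigned voxels
    labeled <- inside[pv_lab[inside] > 0L]
    has_open <- rep(FALSE, length(labeled))
    for (d in delta) has_open <- has_open | pv_lab[labeled + d] == 0L
    frontier <- labeled[has_open]
    repeat {
      if (n_remaining == 0L || length(frontier) == 0L) break
      src <- frontier
      cand_t <- integer(0); cand_l <- integer(0)
      for (d in delta) {
        tgt <- src + d
        ok <- pv_lab[tgt] == 0L & pv_lev[tgt] <= l & pv_lev[tgt] > 0L
        if (any(ok)) {
          cand_t <- c(cand_t, tgt[ok])
          cand_l <- c(cand_l, pv_lab[src[ok]])
        }
      }
      if (length(cand_t) == 0L) break
      # resolve multi-label claims by marker-centroid distance, tie -> lower label
      tco <- arrayInd(cand_t, pdm)
      dist2 <- (tco[, 1] - 1 - cent[cand_l, 1])^2 +
               (tco[, 2] - 1 - cent[cand_l, 2])^2 +
               (if (ncol(tco) >= 3) (tco[, 3] - 1 - cent[cand_l, 3])^2 else 0)
      ord <- order(cand_t, dist2, cand_l)
      first <- !duplicated(cand_t[ord])
      assign_t <- cand_t[ord][first]
      assign_l <- cand_l[ord][first]
      pv_lab[assign_t] <- assign_l
      n_remaining <- n_remaining - length(assign_t)
      frontier <- assign_t
    }
  }
  out <- unpad_volume(pv_lab, dm)
  out[out < 0L] <- 0L
  storage.mode(out) <- "integer"
  out
}
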