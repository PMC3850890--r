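# Batch segmentation over folders of stacks. Each folder holds stack1.tif,
# stack2.tif, ... (channel-then-plane multi-page TIFF, optional -h.txt voxel
# sidecar and stackN-mask.tif manual markers). Results are written next to
# the data: stackN-segm.tif (uint16 labels), stackN-features.csv and
# stackN-log.yaml with the fully resolved parameter set, so a run is
# reproducible from its own outputs. A stack that fails is logged and
# skipped; the batch always continues.

#' Copy a reference plane's segmentation down a stack
#'
#' Lower planes of a stack are often poorly stained; the labels of plane
#' `segmplane` replace the labels of every plane below it (planes
#' `1 .. segmplane - 1`). Planes at or above `segmplane` are untouched;
#' `segmplane = 1` is the identity. This differs from cropping: cropping
#' removes data before segmentation, copy-down overwrites labels after it.
#'
#' @param labels Integer label array.
#' @param segmplane 1-based plane index.
#' @return Label array.
#' @export
apply_segmplane <- function(labels, segmplane) {
  labels <- as_volume(labels)
  nz <- dim(labels)[3]
  segmplane <- as.integer(segmplane)
  if (segmplane < 1L || segmplane > nz)
    stop("segmplane out of range: ", segmplane, " (stack has ", nz, " planes)")
  if (segmplane > 1L)
    for (z in seq_len(segmplane - 1L)) labels[, , z] <- labels[, , segmplane]
  labels
}

#' Batch cell segmentation over folders of stacks
#'
#' For each folder and each stack index in `[sts, ste]`: load
#' `stackN.tif`, crop to planes `[pls, ple]`, run the configured
#' segmentation (`segmentation = "segmsurf"` or `"segmct"` in the parameter
#' file), apply the `segmplane` copy-down, and write `stackN-segm.tif`,
#' `stackN-features.csv` and `stackN-log.yaml` into the data folder.
#' `pls`/`ple` may be scalars or `[folder, stack]` matrices; an `NA` entry
#' skips that stack. A stack that cannot be loaded is reported and skipped;
#' remaining stacks are still processed.
#'
#' @param folders Character vector of folder paths.
#' @param sts,ste First and last 1-based stack index.
#' @param pls,ple Start/end plane, scalar or `length(folders) x n_stacks`
#'   matrix; `ple` beyond the stack depth is clamped with a warning.
#' @param minv,maxv Cell volume limits (um^3).
#' @param prmfile Parameter file path, a parameter list, or `NULL` for
#'   defaults.
#' @return Data frame log: one row per (folder, stack) with `status`
#'   (`ok`/`skipped`/`failed`), `message`, `n_cells`, and output paths.
#' @export
run_batch <- function(folders, sts, ste, pls = 1, ple = Inf, minv, maxv, prmfile = NULL) {
  if (sts > ste) stop("sts must be <= ste")
  prm <- if (is.null(prmfile)) default_parameters()
         else if (is.character(prmfile)) read_parameter_file(prmfile)
         else merge_params(default_parameters(), prmfile)
  stacks <- seq.int(sts, ste)
  get_plane <- function(m, fi, si) {
    if (length(m) == 1L) return(rep(m, 1)[1])
    m <- as.matrix(m); m[fi, si]
  }
  log <- data.frame()
  for (fi in seq_along(folders)) {
    folder <- folders[fi]
    for (si in seq_along(stacks)) {
      sn <- stacks[si]
      rec <- list(folder = folder, stack = sn, status = "ok", message = "",
                  n_cells = NA_integer_, segm_file = NA_character_)
      res <- tryCatch({
        p0 <- get_plane(pls, fi, si); p1 <- get_plane(ple, fi, si)
        if (is.na(p0) || is.na(p1)) {
          rec$status <- "skipped"; rec$message <- "missing plane entry (NA)"
          NULL
        } else {
          process_one_stack(folder, sn, p0, p1, minv, maxv, prm, rec)
        }
      }, error = function(e) {
        rec$status <- "failed"; rec$message <- conditionMessage(e)
        message(sprintf("stack %d in %s failed: %s -- continuing",
                        sn, folder, conditionMessage(e)))
        rec
      })
      if (!is.null(res) && is.list(res) && !is.null(res$status)) rec <- res
      log <- rbind(log, as.data.frame(rec, stringsAsFactors = FALSE))
    }
  }
  log
}

process_one_stack <- function(folder, sn, pls, ple, minv, maxv, prm, rec) {
  path <- file.path(folder, sprintf("stack%d.tif", sn))
  nch <- as.integer(prm$nchannels %||% 2)
  st <- read_stack(path, nch, h = prm$h)
  nz <- st$dim[3]
  if (ple > nz) {
    if (is.finite(ple)) warning(sprintf("stack %d: ple %d beyond depth %d, clamping", sn, ple, nz))
    ple <- nz
  }
  pls <- max(1L, as.integer(pls)); ple <- as.integer(ple)
  if (pls > ple) stop("empty plane range after cropping")
  crop <- lapply(st$channels, function(ch) ch[, , pls:ple, drop = FALSE])
  h <- st$h
  manual <- NULL
  if (identical(prm$segmsurf$getminima$method, "manual")) {
    mk <- read_marker_masks(sn, folder, dim_expect = st$dim)
    manual <- list(minima = mk$minima[, , pls:ple, drop = FALSE],
                   minimacell = if (!is.null(mk$minimacell))
                     mk$minimacell[, , pls:ple, drop = FALSE] else NULL)
  }
  if (identical(prm$segmentation, "segmct")) {
    ct <- segment_nuclei(crop[[1]], minv, maxv, prm = prm$segmct, h = h)
    labels <- ct$labels
    feats <- if (ct$nregions > 0)
      data.frame(label = seq_len(ct$nregions), volume = ct$volumes, cell = TRUE)
      else data.frame(label = integer(0), volume = numeric(0), cell = logical(0))
    ncells <- ct$nregions
  } else {
    imnucl <- if (nch >= 2) crop[[2]] else NULL
    sr <- segment_surface(crop[[1]], minv, maxv, prm = prm, imnucl = imnucl,
                          minima = manual[["minima"]], minimacell = manual[["minimacell"]], h = h)
    labels <- sr$labels
    feats <- cbind(sr$features, cell = as.logical(sr$cell_flags))
    ncells <- sum(sr$cell_flags)
  }
  segmplane <- min(as.integer(prm$segmplane %||% 1), dim(labels)[3])
  labels <- apply_segmplane(labels, max(1L, segmplane))
  segm_file <- file.path(folder, sprintf("stack%d-segm.tif", sn))
  write_labels(labels, segm_file)
  write.csv(feats, file.path(folder, sprintf("stack%d-features.csv", sn)), row.names = FALSE)
  yaml::write_yaml(list(stack = sn, planes = c(pls, ple),
                        minv = minv, maxv = maxv,
                        parameters = unclass_tree(prm)),
                   file.path(folder, sprintf("stack%d-log.yaml", sn)))
  rec$status <- "ok"; rec$n_cells <- as.integer(ncells); rec$segm_file <- segm_file
  rec
}

unclass_tree <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (is.list(v)) unclass_tree(v) else v)
}
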