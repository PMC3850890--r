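# Stack and mask I/O. Stacks are multi-page TIFFs with pages ordered
# channel-then-plane: for C channels and Z planes the pages are
# c1z1, c2z1, ..., cCz1, c1z2, ... Voxel size h = (hx, hy, hz) in micrometres
# comes from a plain-text sidecar "<stem>-h.txt" when present (three numbers),
# else from the TIFF resolution tags, else from a caller-supplied default.
# The sidecar wins when both are present.

#' Construct an image stack
#'
#' An image stack holds one or more same-shaped intensity channels as
#' `[nx, ny, nz]` arrays plus the voxel size in micrometres. `nz = 1` encodes
#' a 2D image.
#'
#' @param channels Named list of 2D/3D numeric arrays, all the same shape.
#' @param h Voxel size `c(hx, hy, hz)` in micrometres, strictly positive.
#' @return An object of class `memseg_stack`.
#' @export
image_stack <- function(channels, h = c(1, 1, 1)) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("channels must be a non-empty list of arrays")
  channels <- lapply(channels, as_volume)
  dm <- dim(channels[[1]])
  for (ch in channels)
    if (!identical(dim(ch), dm)) stop("all channels must share dimensions")
  h <- as.numeric(h)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0))
    stop("h must be three strictly positive voxel sizes (um)")
  if (is.null(names(channels)))
    names(channels) <- paste0("ch", seq_along(channels))
  structure(list(channels = channels, h = h, dim = dm), class = "memseg_stack")
}

#' @export
print.memseg_stack <- function(x, ...) {
  cat(sprintf("image stack: %d x %d x %d, %d channel(s) [%s], h = (%g, %g, %g) um\n",
              x$dim[1], x$dim[2], x$dim[3], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$h[1], x$h[2], x$h[3]))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.tiff?$", "-h.txt", path, ignore.case = TRUE)

#' Read a multi-page TIFF stack
#'
#' Pages are de-interleaved into channels assuming channel-then-plane order.
#' Integer (8/16-bit) data are returned on their native integer scale; float
#' pages are returned as stored.
#'
#' @param path TIFF file.
#' @param n_channels Number of interleaved channels; the page count must be a
#'   multiple of it.
#' @param h Fallback voxel size used when neither a sidecar file nor TIFF
#'   resolution tags provide one.
#' @param channel_names Optional channel names.
#' @return A [image_stack()] object.
#' @export
read_stack <- function(path, n_channels = 1, h = c(1, 1, 1), channel_names = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% n_channels != 0L)
    stop(sprintf("page count %d is not divisible by %d channels", np, n_channels))
  nz <- np %/% n_channels
  # resolution tags (pixels per unit) -> voxel size; sidecar has priority
  hx <- h
  info <- attributes(pages[[1]])
  if (!is.null(info$x.resolution) && info$x.resolution > 0 &&
      !is.null(info$y.resolution) && info$y.resolution > 0)
    hx <- c(1 / info$x.resolution, 1 / info$y.resolution, h[3])
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    v <- scan(sc, quiet = TRUE)
    if (length(v) >= 3) hx <- v[1:3]
  }
  chan <- vector("list", n_channels)
  for (c in seq_len(n_channels)) {
    planes <- lapply(seq_len(nz), function(z) {
      pg <- pages[[(z - 1L) * n_channels + c]]
      t(as.matrix(pg))          # readTIFF gives row-major [y, x]; store [x, y]
    })
    chan[[c]] <- array(unlist(planes), c(dim(planes[[1]]), nz))
  }
  if (!is.null(channel_names)) names(chan) <- channel_names
  image_stack(chan, hx)
}

#' Write a multi-page TIFF stack
#'
#' Inverse of [read_stack()]: channels are interleaved channel-then-plane.
#' Non-negative integer-valued data are written as 8- or 16-bit pages
#' (bit-exact round trip); other data are written as 32-bit float and must lie
#' in `[0, 1]`. The voxel size is stored in a `<stem>-h.txt` sidecar.
#'
#' @param stack A [image_stack()] object (or a bare array, taken as one channel).
#' @param path Output file.
#' @param h Voxel size when `stack` is a bare array.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, h = c(1, 1, 1)) {
  if (!inherits(stack, "memseg_stack")) stack <- image_stack(list(as_volume(stack)), h)
  if (length(stack$channels) == 0L) stop("empty channel list")
  nz <- stack$dim[3]
  vals <- unlist(stack$channels, use.names = FALSE)
  integerish <- all(vals >= 0) && all(vals == floor(vals)) && max(vals) <= 65535
  bits <- if (integerish) { if (max(vals) <= 255) 8L else 16L } else 32L
  scale <- if (bits == 8L) 255 else if (bits == 16L) 65535 else 1
  if (bits == 32L && (min(vals) < 0 || max(vals) > 1))
    stop("float stacks must be scaled to [0, 1] before writing")
  pages <- vector("list", nz * length(stack$channels))
  i <- 1L
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      pages[[i]] <- t(ch[, , z]) / scale
      i <- i + 1L
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  if (!ok && !file.exists(path)) stop("could not write ", path)
  writeLines(paste(format(stack$h, digits = 12), collapse = " "), sidecar_path(path))
  invisible(path)
}

# Undo the 0..1 scaling readTIFF applies to integer pages (as.is=TRUE already
# returns integers, so read_stack pages are native-scale).

#' Quantize a float stack to 16-bit integers
#'
#' Maps each channel's intensities jointly from `[0, max]` to `0..65535`,
#' giving a stack that round-trips bit-exactly through TIFF.
#'
#' @param stack An [image_stack()].
#' @return The quantized stack.
#' @export
quantize_stack <- function(stack) {
  top <- max(1e-12, max(unlist(lapply(stack$channels, max))))
  image_stack(lapply(stack$channels, function(ch) round(ch / top * 65535)), stack$h)
}

#' Write / read a label volume as uint16 TIFF
#' @param labels Integer label array (0 = background).
#' @param path File path.
#' @return `path` / integer array.
#' @export
write_labels <- function(labels, path) {
  labels <- as_volume(labels)
  if (any(labels < 0) || max(labels) > 65535) stop("labels must be in 0..65535")
  write_stack(image_stack(list(labels = labels), c(1, 1, 1)), path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  st <- read_stack(path, 1)
  out <- st$channels[[1]]
  storage.mode(out) <- "integer"
  out
}

#' Construct a marker set
#'
#' Markers (seeds) for the watershed: `minima` holds every marker component
#' (cells and background), `minimacell` the cell markers only and must be a
#' voxelwise subset of `minima`.
#'
#' @param minima Binary volume of all markers.
#' @param minimacell Binary volume of cell markers, or `NULL`.
#' @return An object of class `memseg_markers`.
#' @export
marker_set <- function(minima, minimacell = NULL) {
  minima <- as_volume(minima) > 0
  if (!is.null(minimacell)) {
    minimacell <- as_volume(minimacell) > 0
    if (!identical(dim(minima), dim(minimacell)))
      stop("minima and minimacell must share dimensions")
    if (any(minimacell & !minima))
      stop("minimacell must be a subset of minima")
  }
  structure(list(minima = minima, minimacell = minimacell), class = "memseg_markers")
}

#' Read manual marker masks for a batch stack
#'
#' Batch folders may carry `stackN-mask.tif` files: two-channel binary TIFFs
#' whose first channel is `minima` (all markers) and second `minimacell` (cell
#' markers). The subset invariant is verified on load.
#'
#' @param stack_index 1-based stack number.
#' @param folder Folder containing the masks.
#' @param dim_expect Optional expected volume dimensions.
#' @return A [marker_set()].
#' @export
read_marker_masks <- function(stack_index, folder, dim_expect = NULL) {
  path <- file.path(folder, sprintf("stack%d-mask.tif", stack_index))
  if (!file.exists(path))
    stop("missing marker mask for stack ", stack_index, ": ", path)
  st <- read_stack(path, 2, channel_names = c("minima", "minimacell"))
  if (!is.null(dim_expect) && !identical(st$dim, as.integer(dim_expect)))
    stop(sprintf("mask dimensions (%s) do not match stack dimensions (%s)",
                 paste(st$dim, collapse = "x"), paste(dim_expect, collapse = "x")))
  marker_set(st$channels$minima, st$channels$minimacell)
}
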