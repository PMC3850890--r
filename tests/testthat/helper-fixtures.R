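# Shared fixtures: geometric binary shapes and small phantoms, all built in
# code at test time.

# Binary image of one or two disks on a nx x ny grid.
disk_image <- function(r, sep = 0, nx = 64, ny = 40) {
  cx1 <- nx / 2 - sep / 2; cx2 <- nx / 2 + sep / 2; cy <- ny / 2
  x <- matrix(seq_len(nx), nx, ny); y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  d1 <- sqrt((x - cx1)^2 + (y - cy)^2)
  d2 <- sqrt((x - cx2)^2 + (y - cy)^2)
  if (sep > 0) (d1 <= r) | (d2 <= r) else d1 <= r
}

# Random label volume with k blob-like regions (voronoi of k random sites).
random_labels <- function(k, nx = 24, ny = 24, seed = 1) {
  set.seed(seed)
  sites <- cbind(runif(k, 1, nx), runif(k, 1, ny))
  x <- matrix(seq_len(nx), nx, ny); y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  lab <- matrix(0L, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    d <- (sites[, 1] - i)^2 + (sites[, 2] - j)^2
    lab[i, j] <- which.min(d)
  }
  # carve out some background
  lab[x + y > nx + ny - 4] <- 0L
  lab
}

# Small default phantom used across tests (kept small for speed).
small_phantom <- function(seed = 4, n_cells = 6, grid = c(96, 96, 1),
                          radius_range = c(7, 9), ...) {
  generate_phantom(phantom_spec(grid = grid, n_cells = n_cells,
                                radius_range = radius_range, vesicle_density = 0.5,
                                seed = seed, ...))
}

# Keep only flagged cell labels of a surface segmentation result.
cells_only <- function(res) {
  keep <- as.integer(names(res$cell_flags))[res$cell_flags]
  L <- res$labels
  L[!(L %in% keep)] <- 0L
  L
}
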