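# Independent oracle: exhaustive between-class-variance maximization on the
# binned histogram, computed split by split with direct weighted sums.
otsu_oracle <- function(v, nbins = 64L) {
  edges <- seq(min(v), max(v), length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins), nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  sb <- rep(-Inf, nbins)
  for (k in seq_len(nbins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):nbins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * mids[(k + 1):nbins]) / n1
    w0 <- n0 / length(v); w1 <- n1 / length(v)
    sb[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  edges[which.max(sb) + 1L]
}

test_that("otsu threshold maximizes between-class variance (exhaustive oracle)", {
  set.seed(17)
  for (rep in 1:20) {
    mu <- sort(runif(2, 0, 1)); n1 <- sample(100:400, 1); n2 <- sample(100:400, 1)
    v <- c(rnorm(n1, mu[1], 0.05), rnorm(n2, mu[2], 0.08))
    # same maximizer: the induced foreground partitions agree exactly
    expect_identical(v > otsu_threshold(v, nbins = 64), v > otsu_oracle(v, 64))
  }
  expect_error(otsu_threshold(rep(1, 10)), "constant")
})

test_that("adaptive thresholding recovers a bright disk and maps constants to empty", {
  expect_true(!any(threshold_adaptive(matrix(1, 20, 20), 5, 0.1)))
  disk <- disk_image(8, 0, 48, 48) * 1.0
  fg <- threshold_adaptive(disk, filtrad = 10, adth = 0.2)
  inner <- disk_image(6, 0, 48, 48)
  expect_true(all(fg[memseg:::as_volume(inner)]))          # core recovered
  expect_true(!any(fg[!memseg:::as_volume(disk_image(10, 0, 48, 48))]))  # background clean
  expect_true(!any(threshold_adaptive(disk, 10, 2)))       # offset too large -> empty
  expect_error(threshold_adaptive(disk, 0.2, 0.1), ">= 1")
})

test_that("iterative thresholding lowers the threshold until the volume floor is met", {
  set.seed(18)
  v <- c(rnorm(600, 0.2, 0.04), rnorm(400, 0.8, 0.04))
  im <- matrix(sample(v), 40, 25)
  # multiplier 1, no volume floor: exactly the otsu binarization
  fg <- threshold_iterative(im, 1, minvol = 0)
  expect_identical(as.vector(fg), as.vector(im > otsu_threshold(im)))
  # the implied threshold sits in the inter-mode valley
  th <- otsu_threshold(im)
  expect_gt(th, 0.3); expect_lt(th, 0.7)

  # a tiny bright blob below the floor forces the threshold down to capture
  # the larger dim structure
  im2 <- matrix(0.05, 40, 40)
  im2[5:6, 5:6] <- 1                      # 4-voxel bright blob
  im2[20:35, 20:35] <- 0.4                # large dim structure
  fg2 <- threshold_iterative(im2, 1, minvol = 100, h = c(1, 1, 1))
  expect_true(all(fg2[20:35, 20:35, 1]))
  # monotone: lower thresholds can only grow the foreground
  expect_true(all(fg2[im2 > otsu_threshold(im2)]))
  expect_error(threshold_iterative(matrix(2, 5, 5), 1, 0), "constant")
})

test_that("splitting cuts a fused double disk at the analytic midline", {
  b <- disk_image(10, 18)                  # centres 18 apart, midline at x = 32
  sp <- split_cells(b, 1.0, 1, c(1, 1, 1))
  expect_identical(max(sp), 2L)
  # voxels gained/lost: the labels partition the input exactly
  expect_identical(sp > 0L, memseg:::as_volume(b))
  # cut position: label changes along x within 1 voxel of 32
  cuts <- which(sp[-1, , 1] != sp[-64, , 1] & sp[-1, , 1] > 0 & sp[-64, , 1] > 0,
                arr.ind = TRUE)
  expect_true(all(abs(cuts[, 1] - 32) <= 1))

  expect_identical(max(split_cells(disk_image(10), 1.0, 1, c(1, 1, 1))), 1L)
  # larger depth -> fewer labels
  expect_identical(max(split_cells(b, 6, 1, c(1, 1, 1))), 1L)
  expect_error(split_cells(matrix(FALSE, 5, 5), 1, 1), "empty")
  expect_error(split_cells(b, 0, 1), "> 0")
})

test_that("anisotropic distance transform matches brute force", {
  set.seed(19)
  m <- matrix(runif(15 * 12) > 0.6, 15, 12)
  if (!any(m)) m[5, 5] <- TRUE
  d <- memseg:::edt2d(memseg:::as_volume(m), 0.5, 1.25)
  bg <- which(!m, arr.ind = TRUE)
  for (idx in which(m)) {
    ij <- arrayInd(idx, dim(m))
    ref <- if (nrow(bg)) min(sqrt(((bg[, 1] - ij[1]) * 0.5)^2 + ((bg[, 2] - ij[2]) * 1.25)^2)) else Inf
    expect_equal(d[ij[1], ij[2]], ref, tolerance = 1e-9)
  }
  expect_true(all(d[!m] == 0))
})

test_that("nucleus segmentation finds each nucleus with either method", {
  ph <- generate_phantom(phantom_spec(grid = c(96, 96, 1), n_cells = 5,
                                      radius_range = c(7, 9), seed = 6))
  nuc <- ph$stack$channels$nucleus
  for (method in c("thrs", "adth")) {
    ct <- segment_nuclei(nuc, 5, 4000, prm = list(method = method, adth = list(adth = 0.1, filtrad = 15)),
                         h = ph$stack$h)
    expect_identical(ct$nregions, 5L)
  }
  expect_identical(segment_nuclei(array(0, c(16, 16)), 5, 100)$nregions, 0L)
  expect_error(segment_nuclei(matrix(1, 4, 4), 10, 5), "minv")
  expect_error(segment_nuclei(matrix(runif(16), 4, 4), 1, 5, prm = list(method = "zzz")),
               "unknown")
})

test_that("split flag controls whether fused nuclei separate", {
  ph <- generate_phantom(phantom_spec(n_cells = 6, touching_fraction = 0.34, seed = 13))
  lim <- adjust_volume_limits(300, 8000, ph$stack$h, 8)
  on <- segment_nuclei(ph$stack$channels$nucleus, lim$minvol / 10, lim$maxvol,
                       prm = list(split = 1), h = ph$stack$h)
  off <- segment_nuclei(ph$stack$channels$nucleus, lim$minvol / 10, lim$maxvol,
                        prm = list(split = 0), h = ph$stack$h)
  expect_identical(on$nregions, 6L)
  expect_identical(off$nregions, 5L)
})

test_that("split labels partition the foreground exactly in 3D", {
  ph <- generate_phantom(phantom_spec(n_cells = 5, seed = 23))
  work <- smooth_image(ph$stack$channels$nucleus, "eed",
                       memseg:::segmct_defaults()$smoothim)
  fg <- threshold_iterative(work, 1, 10, ph$stack$h)
  sp <- split_cells(fg, 1.0, "auto", ph$stack$h)
  expect_identical(sp > 0L, memseg:::as_volume(fg))
})
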