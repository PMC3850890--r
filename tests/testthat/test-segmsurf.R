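test_that("volume limits shrink for partial stacks and stay put for full ones", {
  h <- c(0.5, 0.5, 1.5)
  maxv <- 8000
  d <- (6 * maxv / pi)^(1 / 3)
  # deep stack covering a full cell diameter: unchanged
  nz_full <- ceiling(d / h[3]) + 2
  lim <- adjust_volume_limits(300, maxv, h, nz_full)
  expect_equal(lim$minvol, 300); expect_equal(lim$maxvol, maxv)
  # thin plane: both limits strictly below the inputs
  lim1 <- adjust_volume_limits(300, maxv, h, 1)
  expect_lt(lim1$minvol, 300); expect_lt(lim1$maxvol, maxv)
  # continuity at s = 1
  nz_edge <- d / h[3]
  lim_edge <- adjust_volume_limits(300, maxv, h, nz_edge)
  expect_equal(lim_edge$minvol, 300, tolerance = 1e-9)
  expect_equal(lim_edge$maxvol, maxv, tolerance = 1e-9)
})

test_that("region features: volume, convexity and intensity ratios", {
  # cube of side 10 at unit voxel size: volume 1000
  lab <- array(0L, c(20, 20, 12)); lab[6:15, 6:15, 2:11] <- 1L
  im <- array(1, c(20, 20, 12)); im[lab == 1L] <- 5
  bg <- array(0L, dim(lab)); bg[lab == 0L] <- 2L
  labs <- lab + bg
  ft <- compute_features(labs, im, background_labels = 2L, h = c(1, 1, 1))
  cube <- ft[ft$label == 1L, ]
  expect_equal(cube$volume, 1000)
  expect_equal(cube$convexarea, 1, tolerance = 0.05)
  expect_gt(cube$intborder, 1)

  # disk vs disk-with-bite: convexity drops below 1
  disk <- disk_image(12, 0, 48, 48)
  bite <- disk & !disk_image(8, 0, 48, 48)
  bite_lab <- memseg:::as_volume(ifelse(bite, 1L, ifelse(!disk, 2L, 0L)))
  disk_lab <- memseg:::as_volume(ifelse(disk, 1L, 2L))
  imc <- memseg:::as_volume(matrix(1, 48, 48))
  f_disk <- compute_features(disk_lab, imc, background_labels = 2L)
  f_bite <- compute_features(bite_lab, imc, background_labels = 2L)
  expect_gt(f_disk$convexarea[1], 0.95)
  expect_lt(f_bite$convexarea[1], f_disk$convexarea[1] - 0.2)

  expect_error(compute_features(disk_lab, imc * 0, background_labels = 2L),
               "background mean")
  # manual background mean rescues a zero background
  f_manual <- compute_features(disk_lab, imc, background_labels = integer(0),
                               meanintbck = 2)
  expect_equal(f_manual$intincell[1], 0.5)
})

test_that("classification is a conjunction of active gates and monotone in thresholds", {
  ft <- data.frame(label = 1:4,
                   volume = c(50, 500, 500, 5000),
                   intincell = c(2, 2, 30, 2),
                   intborder = c(5, 5, 5, 5),
                   convexarea = c(0.9, 0.9, 0.9, 0.9),
                   convexperim = c(0.9, 0.9, 0.9, 0.9))
  fl <- classify_cells(ft, minvol = 100, maxvol = 1000, prm = list(method = "threshold"))
  expect_identical(as.vector(fl), c(FALSE, TRUE, FALSE, FALSE))
  # volume-only gating
  fl_vol <- classify_cells(ft, 100, 1000,
                           prm = list(method = "threshold", propname = "volume"))
  expect_identical(as.vector(fl_vol), c(FALSE, TRUE, TRUE, FALSE))
  # relaxing one threshold never shrinks the accepted set
  fl_relax <- classify_cells(ft, 100, 1000,
                             prm = list(method = "threshold", intincell = 100))
  expect_true(all(fl_relax[fl]))

  # marker-based classification: overlap plus volume limits
  fl_mk <- classify_cells(ft, 100, 1000, prm = list(method = "minimacell"),
                          marker_overlap = c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(as.vector(fl_mk), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(classify_cells(ft, 100, 1000, prm = list(method = "minimacell")),
               "requires cell markers")
})

test_that("surface pipeline recovers all phantom cells with nucleus markers (3D)", {
  ph <- generate_phantom(phantom_spec(seed = 7))
  res <- segment_surface(ph$stack$channels$surface, 300, 8000,
                         prm = list(segmsurf = list(
                           getminima = list(method = "nucleus"),
                           classifycells = list(method = "minimacell"))),
                         imnucl = ph$stack$channels$nucleus, h = ph$stack$h)
  expect_identical(sum(res$cell_flags), max(ph$truth))
  m <- match_regions(cells_only(res), ph$truth)
  expect_identical(nrow(m$pairs), max(ph$truth))
  expect_gte(mean(m$pairs$c1), 0.7)
  # every flagged cell overlaps its matched ground-truth cell substantially
  expect_true(all(m$pairs$c1 >= 0.7))
})

test_that("surface pipeline with automated markers finds every 2D phantom cell", {
  ph <- small_phantom(seed = 8)
  res <- segment_surface(ph$stack$channels$surface, 300, 8000, h = ph$stack$h)
  expect_identical(sum(res$cell_flags), max(ph$truth))
  expect_identical(nrow(res$features), max(ph$truth) + 1L)  # cells + background
})

test_that("manual markers produce exactly one region per marker", {
  ph <- small_phantom(seed = 10, n_cells = 4)
  dm <- dim(memseg:::as_volume(ph$stack$channels$surface))
  minima <- array(FALSE, dm); minimacell <- array(FALSE, dm)
  for (k in 1:4) {
    cx <- round(ph$centers[k, 1] / ph$stack$h[1]); cy <- round(ph$centers[k, 2] / ph$stack$h[2])
    minima[cx, cy, 1] <- TRUE; minimacell[cx, cy, 1] <- TRUE
  }
  minima[2, 2, 1] <- TRUE
  res <- segment_surface(ph$stack$channels$surface, 300, 8000,
                         prm = list(segmsurf = list(getminima = list(method = "manual"))),
                         minima = minima, minimacell = minimacell, h = ph$stack$h)
  expect_identical(nrow(res$features), 5L)   # 4 cells + 1 background
  expect_true(all(res$labels > 0L))
  # watershed partition: region volumes sum to the full volume
  expect_equal(sum(res$features$volume), prod(dim(res$labels)) * prod(ph$stack$h))
})

test_that("empty markers abort with a diagnostic", {
  expect_error(segment_surface(matrix(1, 32, 32) + 0, 10, 100), "no markers")
})
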