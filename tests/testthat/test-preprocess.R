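test_that("top-hat illumination correction removes slow ramps, keeps specks", {
  cst <- matrix(5, 32, 32)
  expect_true(all(illumination_correct(cst, 5) == 0))
  expect_error(illumination_correct(cst, 0.5), ">= 1")

  # linear ramp + small bright disk: disk preserved, ramp removed
  ramp <- outer(seq(0, 1, length.out = 64), rep(1, 64))
  disk <- matrix(0, 64, 64); disk[30:33, 30:33] <- 2
  im <- ramp + disk
  out <- illumination_correct(im, 10)
  expect_true(mean(out[30:33, 30:33, 1]) > 1.5)        # disk survives
  expect_lt(max(out[1:20, 1:20, 1]), 0.2)              # ramp gone
  expect_true(all(out >= 0))
})

test_that("gaussian smoothing: identity on constants, kernel on impulses, mass conserved", {
  cst <- matrix(3.7, 16, 16)
  expect_equal(as.vector(smooth_gaussian(cst, 3, 1)), rep(3.7, 256), tolerance = 1e-12)

  imp <- matrix(0, 17, 17); imp[9, 9] <- 1
  out <- smooth_gaussian(imp, 4, 1.2)
  k <- memseg:::gaussian_kernel(1.2, 4)
  expect_equal(out[9, 5:13, 1], k * k[5], tolerance = 1e-12)  # separable kernel row
  expect_equal(out[5:13, 9, 1], k * k[5], tolerance = 1e-12)

  set.seed(1)
  vol <- array(runif(32^3), c(32, 32, 32))
  sm <- smooth_gaussian(vol, 4, 1.5, planewise = FALSE)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-6)   # reflective padding conserves mass
})

test_that("diffusion filters: zero iterations and constants are identities", {
  set.seed(2)
  im <- matrix(runif(100), 10, 10)
  expect_equal(as.vector(smooth_ced(im, list(iterations = 0))), as.vector(im))
  expect_equal(as.vector(smooth_eed(im, list(iterations = 0))), as.vector(im))
  cst <- matrix(2, 12, 12)
  expect_equal(as.vector(smooth_ced(cst, list(iterations = 5))), rep(2, 144), tolerance = 1e-9)
  expect_equal(as.vector(smooth_eed(cst, list(iterations = 5))), rep(2, 144), tolerance = 1e-9)
  expect_error(smooth_ced(im, list(time_step = 0.5)), "stability")
})

test_that("coherence diffusion preserves ridge contrast better than gaussian", {
  set.seed(2)
  im <- matrix(0, 128, 64)
  im[, 32] <- 1; im[, 31] <- 0.6; im[, 33] <- 0.6      # bright line along x
  im <- im + matrix(rnorm(128 * 64, 0, 0.15), 128, 64)
  online <- function(x) mean(x[, 31:33, 1]); offline <- function(x) mean(x[, c(1:25, 40:64), 1])
  n_it <- 20; tau <- 0.15
  ced <- smooth_ced(im, list(iterations = n_it, time_step = tau, sigma = 1, rho = 4))
  # isotropic reference at the same total diffusion time t = n*tau (sd = sqrt(2t))
  sd_eq <- sqrt(2 * n_it * tau)
  gs <- smooth_gaussian(im, ceiling(3 * sd_eq), sd_eq)
  expect_gt(online(ced) - offline(ced), online(gs) - offline(gs))
  # anisotropy must not amplify off-line noise
  var_off <- function(x) stats::var(as.vector(x[, c(1:25, 40:64), 1]))
  expect_lte(var_off(ced), stats::var(as.vector(im[, c(1:25, 40:64)])))
})

test_that("edge-enhancing diffusion keeps step edges sharper than gaussian and flattens blobs", {
  prof <- matrix(rep(c(rep(0, 16), rep(1, 16)), each = 8), 8, 32)
  eed <- smooth_eed(prof, list(iterations = 15, sigma = 0.8, lambda = 0.1))
  gs <- smooth_gaussian(prof, 5, 2)
  grad_at_edge <- function(x) max(abs(diff(x[4, , 1])))
  expect_gt(grad_at_edge(eed), grad_at_edge(gs))

  # within-blob variance strictly decreases per iteration (piecewise constancy)
  set.seed(3)
  blob <- matrix(0, 32, 32); blob[10:22, 10:22] <- 1
  noisy <- blob + matrix(rnorm(1024, 0, 0.1), 32, 32)
  v <- numeric(4); cur <- noisy
  for (i in 1:4) {
    cur <- smooth_eed(cur, list(iterations = 2, sigma = 0.8, lambda = 0.2))
    v[i] <- stats::var(as.vector(cur[12:20, 12:20, 1]))
  }
  expect_true(all(diff(v) < 0))
})

test_that("directional morphological smoothing bridges line gaps and removes specks", {
  im <- matrix(0, 32, 32)
  im[8:24, 16] <- 1; im[15, 16] <- 0       # line with a 1-voxel gap
  im[12, 26] <- 1                          # isolated interior speck
  out <- smooth_dirced(im, list(dirced_line_length = 9, dirced_n_orientations = 8))
  expect_gte(out[15, 16, 1], min(im[8:24, 16][im[8:24, 16] > 0]))  # gap bridged
  expect_lt(out[12, 26, 1], 0.5)                                   # speck suppressed
  expect_gte(min(out), min(im)); expect_lte(max(out), max(im))     # bounded
  cst <- matrix(4, 16, 16)
  expect_equal(as.vector(smooth_dirced(cst)), rep(4, 256))
  expect_error(smooth_dirced(im, list(dirced_line_length = 2)), ">= 3")
  expect_error(smooth_dirced(im, list(dirced_n_orientations = 3)), ">= 4")
})

test_that("smoothing dispatcher routes methods and rejects unknown names", {
  set.seed(4)
  im <- matrix(runif(64), 8, 8)
  expect_identical(smooth_image(im, "off"), memseg:::as_volume(im))
  expect_equal(smooth_image(im, "gaussian", list(gaussian_radius = 2, gaussian_sd = 0.8)),
               smooth_gaussian(im, 2, 0.8))
  expect_equal(smooth_image(im, "dirced"), smooth_dirced(im, list()))
  expect_error(smooth_image(im, "fancy"), "unknown smoothing method")
  expect_identical(default_parameters()$smoothim$method, "dirced")
})

test_that("planewise smoothing equals independent per-plane smoothing", {
  set.seed(5)
  vol <- array(runif(16 * 16 * 4), c(16, 16, 4))
  whole <- smooth_gaussian(vol, 3, 1, planewise = TRUE)
  per <- vapply(1:4, function(z) smooth_gaussian(vol[, , z], 3, 1)[, , 1],
                matrix(0, 16, 16))
  expect_equal(as.vector(whole), as.vector(per))
  wd <- smooth_dirced(vol)
  pd <- vapply(1:4, function(z) smooth_dirced(vol[, , z])[, , 1], matrix(0, 16, 16))
  expect_equal(as.vector(wd), as.vector(pd))
})

test_that("nucleus-channel subtraction removes bleed-through", {
  set.seed(3)
  im <- matrix(runif(400), 20, 20)
  expect_equal(subtract_nucleus_channel(im, matrix(0, 20, 20), 1),
               memseg:::gauss_smooth(im, 1))
  expect_true(all(subtract_nucleus_channel(im, im, 1) == 0))
  expect_error(subtract_nucleus_channel(im, matrix(0, 10, 10), 1), "dimensions")

  ph <- generate_phantom(phantom_spec(grid = c(64, 64, 1), n_cells = 4,
                                      radius_range = c(6, 8), seed = 3))
  deg <- degrade_stack(ph$stack, bleedthrough = 0.5)
  nucmask <- ph$stack$channels$nucleus > 0.5
  before <- mean(deg$channels$surface[nucmask])
  after <- mean(subtract_nucleus_channel(deg$channels$surface, deg$channels$nucleus, 1)[nucmask])
  expect_lt(after, before)
})
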