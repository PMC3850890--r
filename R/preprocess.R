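# Preprocessing of the segmentation image: top-hat illumination correction,
# the four smoothing operators dispatched by smooth_image(), and subtraction
# of the nucleus channel from the surface-stain channel (cross-talk removal).

#' Top-hat illumination correction
#'
#' Removes slowly varying background intensity by subtracting the grayscale
#' morphological opening with a disk of the given radius (applied planewise
#' for 3D stacks). Structures wider than the disk are treated as background.
#'
#' @param im 2D/3D intensity array.
#' @param radius Disk radius in voxels (>= 1).
#' @return Corrected array, non-negative.
#' @export
illumination_correct <- function(im, radius) {
  if (radius < 1) stop("illumination radius must be >= 1 voxel")
  im <- as_volume(im)
  sz <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(sz, shape = "disc")
  # grayscale morphology operates on the [0, 1] scale; rescale around it
  r <- range(im)
  if (r[2] == r[1]) return(array(0, dim(im)))
  work <- (im - r[1]) / (r[2] - r[1])
  opened <- as_volume(as.array(EBImage::opening(work, brush))) * (r[2] - r[1]) + r[1]
  pmax(im - opened, 0)
}

#' Gaussian smoothing
#'
#' Truncated-Gaussian convolution with reflective boundary, suitable for
#' gentle general-purpose smoothing (small radius, low standard deviation);
#' stronger settings suppress the membrane detail needed downstream.
#'
#' @param im 2D/3D intensity array.
#' @param radius Kernel radius in voxels.
#' @param sd Standard deviation in voxels (> 0).
#' @param planewise Smooth each z-plane independently (default) or in 3D.
#' @return Smoothed array.
#' @export
smooth_gaussian <- function(im, radius = 4, sd = 1, planewise = TRUE) {
  if (sd <= 0) stop("sd must be > 0")
  if (radius < 1) stop("radius must be >= 1")
  gauss_smooth(as_volume(im), sd, planewise = planewise, radius = as.integer(radius))
}

# --- Weickert-style anisotropic diffusion -----------------------------------
#
# Both PDE filters share an explicit finite-difference scheme. 2D planes use
# the analytic eigen-decomposition of the 2x2 structure tensor; the full-3D
# coherence filter decomposes the 3x3 tensor numerically per voxel.

diffusion_step_2d <- function(u, D11, D12, D22, tau) {
  ux <- deriv_central(u, 1L); uy <- deriv_central(u, 2L)
  j1 <- D11 * ux + D12 * uy
  j2 <- D12 * ux + D22 * uy
  u + tau * (deriv_central(j1, 1L) + deriv_central(j2, 2L))
}

# Coherence-enhancing diffusion tensor for one 2D plane.
ced_tensor_2d <- function(u, sigma, rho, alpha, Ccoh) {
  us <- gauss_smooth(u, sigma)
  ux <- deriv_central(us, 1L); uy <- deriv_central(us, 2L)
  J11 <- gauss_smooth(ux * ux, rho)
  J12 <- gauss_smooth(ux * uy, rho)
  J22 <- gauss_smooth(uy * uy, rho)
  # analytic eigen-decomposition of [[J11, J12], [J12, J22]]
  tr <- J11 + J22
  disc <- sqrt(pmax((J11 - J22)^2 + 4 * J12^2, 0))
  mu1 <- (tr + disc) / 2; mu2 <- (tr - disc) / 2
  # first eigenvector (cos t, sin t) along largest eigenvalue
  vx <- 2 * J12; vy <- J22 - J11 + disc
  nrm <- sqrt(vx^2 + vy^2)
  deg <- nrm < 1e-12
  vx <- ifelse(deg, 1, vx / pmax(nrm, 1e-12))
  vy <- ifelse(deg, 0, vy / pmax(nrm, 1e-12))
  dmu <- (mu1 - mu2)^2
  c1 <- array(alpha, dim(as_volume(u)))
  c2 <- ifelse(dmu > 0, alpha + (1 - alpha) * exp(-Ccoh / dmu), alpha)
  # D = c1 v v^T + c2 w w^T with w = (-vy, vx)
  list(D11 = c1 * vx^2 + c2 * vy^2,
       D12 = (c1 - c2) * vx * vy,
       D22 = c1 * vy^2 + c2 * vx^2)
}

# Edge-enhancing diffusion tensor for one 2D plane: diffusivity across the
# (Gaussian-regularized) gradient suppressed by a Perona-Malik-type function,
# full diffusion along the level line.
eed_tensor_2d <- function(u, sigma, lambda) {
  us <- gauss_smooth(u, sigma)
  ux <- deriv_central(us, 1L); uy <- deriv_central(us, 2L)
  g2 <- ux^2 + uy^2
  cpar <- 1 / (1 + g2 / lambda^2)  # across-gradient diffusivity
  nrm <- sqrt(pmax(g2, 0))
  deg <- nrm < 1e-12
  vx <- ifelse(deg, 1, ux / pmax(nrm, 1e-12))
  vy <- ifelse(deg, 0, uy / pmax(nrm, 1e-12))
  list(D11 = cpar * vx^2 + vy^2 * 1,
       D12 = (cpar - 1) * vx * vy,
       D22 = cpar * vy^2 + vx^2 * 1)
}

run_diffusion_2d <- function(im, iterations, tau, tensor_fun) {
  im <- as_volume(im)
  for (z in seq_len(dim(im)[3])) {
    u <- im[, , z, drop = FALSE]
    for (it in seq_len(iterations)) {
      Dt <- tensor_fun(u)
      u <- diffusion_step_2d(u, Dt$D11, Dt$D12, Dt$D22, tau)
    }
    im[, , z] <- u
  }
  im
}

check_diffusion_params <- function(params, dims3d) {
  it <- params$iterations %||% 10
  tau <- params$time_step %||% if (dims3d) 1 / 12 else 0.15
  if (tau <= 0) stop("time_step must be > 0")
  if (it < 0) stop("iterations must be >= 0")
  # explicit-scheme stability: tau <= 1/(2d) for d space dimensions
  bound <- if (dims3d) 1 / 6 else 1 / 4
  if (tau > bound + 1e-12)
    stop(sprintf("time_step %.4g violates the explicit-scheme stability bound %.4g", tau, bound))
  list(iterations = as.integer(it), tau = tau)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coherence-enhancing anisotropic diffusion
#'
#' PDE-based smoothing that diffuses along coherent line-like structures
#' (membranes) and hardly across them, closing staining gaps while preserving
#' ridge sharpness. The diffusion tensor shares the structure tensor's
#' eigenvectors with eigenvalues `alpha` and
#' `alpha + (1 - alpha) exp(-C / (mu1 - mu2)^2)`.
#'
#' @param im 2D/3D intensity array.
#' @param params List: `iterations`, `time_step`, `sigma` (derivative scale,
#'   voxels), `rho` (integration scale, voxels), `planewise` (default 1),
#'   `alpha` (default 0.001), `C` (default 1).
#' @return Smoothed array.
#' @export
smooth_ced <- function(im, params = list()) {
  im <- as_volume(im)
  planewise <- (params$planewise %||% 1) != 0 || dim(im)[3] == 1L
  sc <- check_diffusion_params(params, dims3d = !planewise)
  sigma <- params$sigma %||% 1; rho <- params$rho %||% 3
  alpha <- params$alpha %||% 0.001; Ccoh <- params$C %||% 1
  if (sc$iterations == 0L) return(im)
  if (planewise) {
    run_diffusion_2d(im, sc$iterations, sc$tau,
                     function(u) ced_tensor_2d(u, sigma, rho, alpha, Ccoh))
  } else {
    smooth_ced_3d(im, sc$iterations, sc$tau, sigma, rho, alpha, Ccoh)
  }
}

# Full-3D coherence diffusion: numeric eigen-decomposition of the 3x3
# structure tensor per voxel. Intended for small volumes; the planewise path
# is the practical default.
smooth_ced_3d <- function(u, iterations, tau, sigma, rho, alpha, Ccoh) {
  dm <- dim(u)
  n <- prod(dm)
  for (it in seq_len(iterations)) {
    us <- gauss_smooth(u, sigma, planewise = FALSE)
    g <- list(deriv_central(us, 1L), deriv_central(us, 2L), deriv_central(us, 3L))
    J <- list()
    for (a in 1:3) for (b in a:3)
      J[[paste0(a, b)]] <- gauss_smooth(g[[a]] * g[[b]], rho, planewise = FALSE)
    D <- array(0, c(n, 6))  # D11 D22 D33 D12 D13 D23
    for (i in seq_len(n)) {
      Jm <- matrix(c(J[["11"]][i], J[["12"]][i], J[["13"]][i],
                     J[["12"]][i], J[["22"]][i], J[["23"]][i],
                     J[["13"]][i], J[["23"]][i], J[["33"]][i]), 3, 3)
      eg <- eigen(Jm, symmetric = TRUE)
      lam <- rep(alpha, 3)
      d12 <- (eg$values[1] - eg$values[2])^2
      if (d12 > 0) lam[2] <- alpha + (1 - alpha) * exp(-Ccoh / d12)
      d13 <- (eg$values[1] - eg$values[3])^2
      if (d13 > 0) lam[3] <- alpha + (1 - alpha) * exp(-Ccoh / d13)
      Dm <- eg$vectors %*% diag(lam) %*% t(eg$vectors)
      D[i, ] <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
    }
    dim6 <- function(k) array(D[, k], dm)
    ux <- deriv_central(u, 1L); uy <- deriv_central(u, 2L); uz <- deriv_central(u, 3L)
    j1 <- dim6(1) * ux + dim6(4) * uy + dim6(5) * uz
    j2 <- dim6(4) * ux + dim6(2) * uy + dim6(6) * uz
    j3 <- dim6(5) * ux + dim6(6) * uy + dim6(3) * uz
    u <- u + tau * (deriv_central(j1, 1L) + deriv_central(j2, 2L) + deriv_central(j3, 3L))
  }
  u
}

#' Edge-enhancing anisotropic diffusion
#'
#' Suited to blob-like objects (stained nuclei, cytoplasmic stain): smooths
#' within regions while suppressing diffusion across strong gradients, driving
#' the image towards piecewise constancy.
#'
#' @param im 2D/3D intensity array.
#' @param params List: `iterations`, `time_step`, `sigma`, `lambda` (gradient
#'   contrast scale, image-intensity units; default 0.05 on a [0,1] image),
#'   `planewise`.
#' @return Smoothed array.
#' @export
smooth_eed <- function(im, params = list()) {
  im <- as_volume(im)
  sc <- check_diffusion_params(params, dims3d = FALSE)
  sigma <- params$sigma %||% 1
  lambda <- params$lambda %||% 0.05
  if (sc$iterations == 0L) return(im)
  run_diffusion_2d(im, sc$iterations, sc$tau,
                   function(u) eed_tensor_2d(u, sigma, lambda))
}

#' Directional coherence-enhancing smoothing (morphological)
#'
#' An orientation bank of grayscale closing-then-opening with a line segment:
#' for each of `n_orientations` equally spaced directions the image is closed
#' (bridging gaps in bright lines along that direction) and then opened
#' (removing isolated bright specks); the output takes, per voxel, the maximum
#' response over orientations, preserving ridge continuity along the locally
#' best direction. Planewise by construction.
#'
#' @param im 2D/3D intensity array.
#' @param params List: `dirced_line_length` (voxels, >= 3, default 9),
#'   `dirced_n_orientations` (>= 4, default 8).
#' @return Smoothed array, bounded by `[min(im), max(im)]`.
#' @export
smooth_dirced <- function(im, params = list()) {
  len <- params$dirced_line_length %||% 9
  nor <- params$dirced_n_orientations %||% 8
  if (len < 3) stop("dirced line length must be >= 3 voxels")
  if (nor < 4) stop("dirced needs >= 4 orientations")
  im <- as_volume(im)
  r <- range(im)
  if (r[2] == r[1]) return(im)
  work <- (im - r[1]) / (r[2] - r[1])   # grayscale morphology needs [0, 1]
  angles <- seq(0, 180, length.out = nor + 1)[seq_len(nor)]
  out <- array(-Inf, dim(im))
  for (ang in angles) {
    brush <- line_brush(as.integer(len), ang)
    resp <- EBImage::opening(EBImage::closing(work, brush), brush)
    out <- pmax(out, as_volume(as.array(resp)))
  }
  out * (r[2] - r[1]) + r[1]
}

# Line structuring element at an arbitrary angle in [0, 180); angles above 90
# are obtained by mirroring the supplementary angle.
line_brush <- function(len, angle) {
  angle <- angle %% 180
  if (angle <= 90) return(EBImage::makeBrush(len, shape = "line", angle = angle))
  b <- EBImage::makeBrush(len, shape = "line", angle = 180 - angle)
  b[rev(seq_len(nrow(b))), , drop = FALSE]
}

#' Smoothing dispatcher
#'
#' Runs one of the smoothing operators, selected by name; `"off"` returns the
#' input unchanged. The default method is `"dirced"`, the morphological
#' directional filter suited to surface-stained cells.
#'
#' @param im 2D/3D intensity array.
#' @param method One of `"ced"`, `"dirced"`, `"eed"`, `"gaussian"`, `"off"`.
#' @param params Method parameters (see the individual operators).
#' @return Smoothed array.
#' @export
smooth_image <- function(im, method = "dirced", params = list()) {
  switch(method,
    off = as_volume(im),
    gaussian = smooth_gaussian(im, radius = params$gaussian_radius %||% 4,
                               sd = params$gaussian_sd %||% 1,
                               planewise = (params$planewise %||% 1) != 0),
    ced = smooth_ced(im, params),
    eed = smooth_eed(im, params),
    dirced = smooth_dirced(im, params),
    stop("unknown smoothing method: '", method, "'")
  )
}

#' Subtract the nucleus channel from the surface-stain channel
#'
#' Nucleus-stain emission can bleed into the surface-stain channel when both
#' are imaged simultaneously; without correction the nucleus may be segmented
#' as the whole cell. Both channels are Gaussian-smoothed (to keep noise from
#' dominating the difference) before subtraction; the result is clamped at 0.
#'
#' @param imsegm Surface-stain array.
#' @param imnucl Nucleus-stain array, same shape.
#' @param sd Gaussian sd in voxels (default 1).
#' @return Corrected surface-stain array.
#' @export
subtract_nucleus_channel <- function(imsegm, imnucl, sd = 1) {
  imsegm <- as_volume(imsegm); imnucl <- as_volume(imnucl)
  if (!identical(dim(imsegm), dim(imnucl)))
    stop("surface and nucleus channels must share dimensions")
  pmax(gauss_smooth(imsegm, sd) - gauss_smooth(imnucl, sd), 0)
}
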