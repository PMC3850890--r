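# Synthetic phantom of a confluent layer of surface-stained cells with a
# nucleus channel and exact ground-truth labels. Cell territories are a
# seeded Voronoi partition (physical-distance metric) clipped to a sheet, so
# adjacent cells share membranes -- the defining challenge of the surface
# pipeline. The surface channel is a bright shell along territory boundaries
# plus vesicle clutter, a slowly varying illumination ramp and additive
# noise; the nucleus channel holds one ellipsoidal blob per cell, a
# configured fraction of them touching across neighbouring cells.

#' Phantom specification
#'
#' Defaults describe a realistic confluent field at confocal scale: 9 cells
#' of 6--9 um radius on a 96 x 96 x 8 grid with 0.5 x 0.5 x 1.5 um voxels, a
#' 2-voxel membrane of peak intensity 1, nuclei at 45% of the cell radius,
#' mild vesicle clutter, a 15% illumination ramp and 3% Gaussian noise.
#'
#' @param grid Volume dimensions `c(nx, ny, nz)`; `nz = 1` gives a 2D phantom.
#' @param h Voxel size (um).
#' @param n_cells Number of cells.
#' @param radius_range Cell radius range (um).
#' @param membrane_width Membrane shell width (voxels).
#' @param membrane_peak Membrane peak intensity.
#' @param nucleus_fraction Nucleus radius as a fraction of the cell radius.
#' @param vesicle_density Expected vesicles per cell.
#' @param vesicle_intensity Vesicle peak intensity.
#' @param illumination Peak-to-trough amplitude of the illumination ramp
#'   (fraction of the membrane peak).
#' @param noise_sd Additive Gaussian noise sd.
#' @param poisson Apply Poisson resampling (photon noise) as well.
#' @param touching_fraction Fraction of cells whose nuclei are moved into
#'   touching pairs (pairs = `round(fraction * n_cells / 2)`).
#' @param seed RNG seed fixing the full sample path.
#' @return List of class `memseg_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(96, 96, 8), h = c(0.5, 0.5, 1.5),
                         n_cells = 9, radius_range = c(6, 9),
                         membrane_width = 2, membrane_peak = 1,
                         nucleus_fraction = 0.45,
                         vesicle_density = 3, vesicle_intensity = 0.5,
                         illumination = 0.15, noise_sd = 0.03,
                         poisson = FALSE, touching_fraction = 0,
                         seed = 1L) {
  spec <- as.list(environment())
  if (any(spec$grid[1:2] < 16) || spec$grid[3] < 1) stop("grid too small")
  if (spec$noise_sd < 0 || spec$illumination < 0) stop("intensities must be >= 0")
  structure(spec, class = "memseg_phantom_spec")
}

#' Generate a synthetic surface-stain + nucleus phantom
#'
#' @param spec A [phantom_spec()].
#' @return List (class `memseg_phantom`): `stack` (an [image_stack()] with
#'   channels `surface` and `nucleus`), `truth` (ground-truth label volume,
#'   background 0), `centers` (cell centres, voxel coordinates),
#'   `touching_pairs` (matrix of cell index pairs whose nuclei touch),
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dm <- as.integer(spec$grid)
  h <- spec$h
  n <- spec$n_cells
  ext <- dm * h                      # physical extents (um)
  rmax <- spec$radius_range[2]

  # --- seed points: dart throwing with a minimum pairwise distance ----------
  margin <- rmax * 1.1    # cells stay strictly interior; background is one sea
  if (2 * margin > min(ext[1:2]) * 0.8) margin <- min(ext[1:2]) * 0.2
  mindist <- 1.4 * rmax
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (try in seq_len(20000L)) {
    cand <- c(runif(1, margin, ext[1] - margin),
              runif(1, margin, ext[2] - margin),
              # cultured cells rest on the substrate: centres sit in the lower
              # part of the stack rather than mid-height
              if (dm[3] > 1L) ext[3] / 3 else ext[3] / 2)
    if (placed == 0L ||
        all(sqrt(colSums((t(centers[seq_len(placed), 1:2, drop = FALSE]) - cand[1:2])^2)) >= mindist)) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) break
    }
    # relax the spacing slightly under pressure, but never let cells
    # interpenetrate deeply
    if (try > 5000L && placed < n) mindist <- max(mindist * 0.999, 0.9 * rmax)
  }
  if (placed < n) stop("infeasible packing: could not place ", n, " cells")
  radii <- runif(n, spec$radius_range[1], spec$radius_range[2])

  # --- territories: nearest seed within its radius (physical metric) --------
  xs <- (seq_len(dm[1]) - 0.5) * h[1]
  ys <- (seq_len(dm[2]) - 0.5) * h[2]
  zs <- (seq_len(dm[3]) - 0.5) * h[3]
  co <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- matrix(Inf, nrow(co), n)
  for (k in seq_len(n)) {
    dz2 <- ((co$z - centers[k, 3]) / 0.9)^2   # slightly flattened in z
    d2[, k] <- (co$x - centers[k, 1])^2 + (co$y - centers[k, 2])^2 + dz2
  }
  nearest <- max.col(-d2, ties.method = "first")
  nd <- sqrt(d2[cbind(seq_len(nrow(co)), nearest)])
  truth <- array(0L, dm)
  truth[nd <= radii[nearest]] <- nearest[nd <= radii[nearest]]
  # confluent sheet: background corridors narrower than the membrane and
  # interstitial pockets enclosed between cells do not occur in a confluent
  # layer -- close the sheet by the membrane width and assign enclosed
  # pockets, plane by plane, to the nearest territory (the sea touching the
  # in-plane image border remains)
  nearest3 <- array(nearest, dm)
  nclose <- max(1L, as.integer(spec$membrane_width))
  for (z in seq_len(dm[3])) {
    pz <- truth[, , z]
    if (!any(pz > 0L)) next
    sheet <- pz > 0L
    for (i in seq_len(nclose)) sheet <- binary_dilate1(sheet)[, , 1]
    for (i in seq_len(nclose)) sheet <- binary_erode1(sheet)[, , 1]
    add <- sheet & pz == 0L
    pz[add] <- nearest3[, , z][add]
    truth[, , z] <- pz
  }
  for (z in seq_len(dm[3])) {
    pz <- truth[, , z]
    if (!any(pz > 0L)) next
    bgcomp <- label_components(pz == 0L)[, , 1]
    edge <- matrix(FALSE, dm[1], dm[2])
    edge[c(1, dm[1]), ] <- TRUE; edge[, c(1, dm[2])] <- TRUE
    sea <- unique(bgcomp[edge & bgcomp > 0L])
    lagoon <- bgcomp > 0L & !(bgcomp %in% sea)
    if (any(lagoon)) {
      pz[lagoon] <- nearest3[, , z][lagoon]
      truth[, , z] <- pz
    }
  }

  # --- surface channel ------------------------------------------------------
  # membrane centred on the cell outline: the stain straddles the territory
  # boundary symmetrically (between adjacent cells and on the outer rim), as
  # a surface stain marks the membrane itself, not a band inside the cell
  shell <- boundary_shell(truth, include_bg = TRUE)
  outer_rim <- truth == 0L & binary_dilate1(truth > 0L)
  memb <- shell | outer_rim
  for (i in seq_len(max(0L, as.integer(spec$membrane_width) - 2L)))
    memb <- binary_dilate1(memb)
  surface <- array(0, dm)
  surface[truth > 0L] <- 0.12 * spec$membrane_peak      # faint cytoplasmic haze
  surface[memb] <- spec$membrane_peak
  surface <- gauss_smooth(surface, 0.6)

  # vesicle clutter: bright specks inside cells
  nves <- rpois(1, spec$vesicle_density * n)
  if (nves > 0 && any(truth > 0L)) {
    inside <- which(truth > 0L & !memb)
    if (length(inside)) {
      pick <- sample(inside, min(nves, length(inside)))
      ves <- array(0, dm); ves[pick] <- spec$vesicle_intensity
      surface <- surface + gauss_smooth(ves, 0.8)
    }
  }

  # --- nucleus channel ------------------------------------------------------
  nuc_centers <- centers
  npairs <- round(spec$touching_fraction * n / 2)
  touching <- matrix(integer(0), 0, 2)
  if (npairs > 0) {
    # pick mutually nearest pairs and pull both nuclei to the shared boundary
    dmat <- as.matrix(dist(centers[, 1:2]))
    diag(dmat) <- Inf
    used <- logical(n)
    while (nrow(touching) < npairs && any(!used)) {
      ij <- which(dmat == min(dmat[!used, !used, drop = FALSE]), arr.ind = TRUE)[1, ]
      i <- ij[1]; j <- ij[2]
      if (used[i] || used[j]) { dmat[i, j] <- dmat[j, i] <- Inf; next }
      mid <- (centers[i, ] + centers[j, ]) / 2
      rn_i <- spec$nucleus_fraction * radii[i]
      rn_j <- spec$nucleus_fraction * radii[j]
      dir_i <- mid - centers[i, ]; dir_j <- mid - centers[j, ]
      pull <- function(cen, dir, rn) {
        # move the nucleus until its surface reaches the shared midpoint:
        # adjacent nuclei touch without interpenetrating
        len <- sqrt(sum(dir^2))
        if (len < 1e-9) return(cen)
        cen + dir / len * max(0, len - rn)
      }
      nuc_centers[i, ] <- pull(centers[i, ], dir_i, rn_i)
      nuc_centers[j, ] <- pull(centers[j, ], dir_j, rn_j)
      used[i] <- used[j] <- TRUE
      touching <- rbind(touching, c(i, j))
      dmat[i, ] <- dmat[, i] <- dmat[j, ] <- dmat[, j] <- Inf
    }
  }
  nucleus <- array(0, dm)
  for (k in seq_len(n)) {
    rn <- spec$nucleus_fraction * radii[k]
    dz2 <- ((co$z - nuc_centers[k, 3]) / 0.7)^2
    dd <- sqrt((co$x - nuc_centers[k, 1])^2 + (co$y - nuc_centers[k, 2])^2 + dz2)
    nucleus[dd <= rn] <- 1
  }
  nucleus <- gauss_smooth(nucleus, 0.6)

  # --- illumination ramp and noise -----------------------------------------
  if (spec$illumination > 0) {
    ramp <- outer(seq(0, 1, length.out = dm[1]), seq(0, 1, length.out = dm[2]), function(a, b) (a + b) / 2)
    ramp <- 1 - spec$illumination + spec$illumination * ramp
    surface <- surface * array(rep(ramp, dm[3]), dm)
    nucleus <- nucleus * array(rep(ramp, dm[3]), dm)
  }
  if (spec$poisson) {
    photons <- 200
    surface <- rpois(length(surface), pmax(surface, 0) * photons) / photons
    dim(surface) <- dm
    nucleus <- rpois(length(nucleus), pmax(nucleus, 0) * photons) / photons
    dim(nucleus) <- dm
  }
  if (spec$noise_sd > 0) {
    surface <- pmax(surface + rnorm(length(surface), 0, spec$noise_sd), 0)
    nucleus <- pmax(nucleus + rnorm(length(nucleus), 0, spec$noise_sd), 0)
    dim(surface) <- dm; dim(nucleus) <- dm
  }
  structure(list(
    stack = image_stack(list(surface = surface, nucleus = nucleus), h),
    truth = truth, centers = centers, radii = radii,
    touching_pairs = touching, spec = spec), class = "memseg_phantom")
}

#' Degrade a phantom stack with bleed-through and extra noise
#'
#' Emulates spectral cross-talk: a fraction of the nucleus channel leaks into
#' the surface channel, plus optional extra Gaussian noise. Used to exercise
#' [subtract_nucleus_channel()].
#'
#' @param stack An [image_stack()] with `surface` and `nucleus` channels.
#' @param extra_noise_sd Additional Gaussian noise sd (>= 0).
#' @param bleedthrough Fraction (>= 0) of nucleus intensity added to surface.
#' @param seed RNG seed for the noise.
#' @return The degraded stack.
#' @export
degrade_stack <- function(stack, extra_noise_sd = 0, bleedthrough = 0, seed = 1L) {
  if (bleedthrough < 0) stop("bleedthrough fraction must be >= 0")
  if (extra_noise_sd < 0) stop("extra_noise_sd must be >= 0")
  surface <- stack$channels$surface + bleedthrough * stack$channels$nucleus
  if (extra_noise_sd > 0) {
    surface <- with_seed(seed, {
      s <- pmax(surface + rnorm(length(surface), 0, extra_noise_sd), 0)
      dim(s) <- dim(surface); s
    })
  }
  image_stack(list(surface = surface, nucleus = stack$channels$nucleus), stack$h)
}
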