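# Synthetic pre-op / intra-op phantom pairs with known ground-truth
# deformation. Emulates the structure of clinical brain-shift MRI pairs at
# desk scale: an ellipsoidal "brain" with a low-intensity "ventricle", an
# optional "tumor" sphere, band-limited intensity texture (block matching
# needs local variability), a smooth Gaussian-bump deformation confined to
# the brain, an optional resection cavity in the intra-op image, and
# additive acquisition noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

shift_array <- function(arr, t, axis) {
  # zero-padded integer shift along one axis
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  if (abs(t) >= n) return(out)
  src <- if (t >= 0) 1:(n - t) else (1 - t):n
  dst <- if (t >= 0) (1 + t):n else 1:(n + t)
  ix_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_dst <- ix_src
  ix_src[[axis]] <- src; ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    arr[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

smooth_gaussian3 <- function(arr, sigma_vox) {
  k <- gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    acc <- array(0, dim(arr))
    for (t in seq_along(k))
      acc <- acc + k[t] * shift_array(arr, t - r - 1L, axis)
    arr <- acc
  }
  arr
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Phantom specification
#'
#' Defaults describe the package's standard desk-scale test world: a 64^3
#' grid at 1 mm spacing, an ellipsoidal brain with ventricle and tumor, a
#' single 3 mm Gaussian-bump deformation of width 20 mm (brain-scale, like
#' a gravity-induced sag), texture with about 2-voxel correlation length
#' and sd equal to 40% of parenchyma intensity (the local variability that
#' makes NCC blocks discriminative, as in real T1 images), and
#' 1 intensity-unit additive noise.
#'
#' @param grid_size voxel triple.
#' @param spacing mm triple.
#' @param brain list(center, semiaxes) of the brain ellipsoid (mm).
#' @param ventricle optional list(center, semiaxes); `NULL` disables.
#' @param tumor optional list(center, radius); `NULL` disables.
#' @param texture list(amplitude, correlation) — intensity sd and
#'   correlation length (voxels) of the band-limited texture.
#' @param structures list(n, intensity, min_axis, max_axis) — random
#'   internal ellipsoids with intensity offsets, emulating the sulci,
#'   gyri and deep-gray structures that give real brain MRI edges (and
#'   hence registration features) throughout the parenchyma rather than
#'   only at the cortical surface; `NULL` disables.
#' @param deform list of bumps, each list(center, amplitude, width,
#'   direction): displacement `amplitude * exp(-|x-c|^2 / (2 width^2))`
#'   along `direction`, tapered to zero at the brain surface.
#' @param resection `NULL`, or list(center, radius) of the cavity sphere
#'   zeroed in the intra-op image (defaults to the tumor sphere when
#'   `resection = TRUE`).
#' @param noise_sigma additive Gaussian intensity noise on the intra image.
#' @param seed integer; fully determines the output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         brain = list(center = c(32, 32, 32),
                                      semiaxes = c(26, 24, 22)),
                         ventricle = list(center = c(30, 30, 32),
                                          semiaxes = c(8, 5, 5)),
                         tumor = list(center = c(42, 36, 34), radius = 6),
                         texture = list(amplitude = 40, correlation = 2),
                         structures = list(n = 40, intensity = 35,
                                           min_axis = 2, max_axis = 6),
                         deform = list(list(center = c(36, 32, 32),
                                            amplitude = 3, width = 20,
                                            direction = c(1, 0.4, 0.2))),
                         resection = NULL,
                         noise_sigma = 1,
                         seed = 42L) {
  for (b in deform) {
    if (b$amplitude < 0 || b$width <= 0)
      stop("phantom_spec: bump amplitude must be >= 0 and width > 0")
  }
  if (isTRUE(resection)) {
    if (is.null(tumor)) stop("phantom_spec: resection=TRUE needs a tumor sphere")
    resection <- tumor
  }
  structure(list(grid_size = as.integer(grid_size), spacing = spacing,
                 brain = brain, ventricle = ventricle, tumor = tumor,
                 texture = texture, structures = structures,
                 deform = deform, resection = resection,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_rho <- function(pts, center, semiaxes) {
  rowSums(sweep(sweep(pts, 2, center, "-"), 2, semiaxes, "/")^2)
}

#' Generate a synthetic pre-op / intra-op pair
#'
#' Builds the textured pre-operative phantom, its tissue segmentation, a
#' fold-free ground-truth deformation field (pull convention), and the
#' intra-operative image `warp_image(pre, truth)` with optional resection
#' cavity and additive noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `pre`, `labels`, `truth`, `intra`.
#' @export
make_phantom <- function(spec) {
  gs <- spec$grid_size
  geom <- image_volume(array(0, gs), spec$spacing, origin = c(0, 0, 0))
  pts <- grid_world_points(geom)

  rho_brain <- ellipsoid_rho(pts, spec$brain$center, spec$brain$semiaxes)
  lab <- ifelse(rho_brain <= 1, 1L, 0L)
  if (!is.null(spec$ventricle)) {
    rho_v <- ellipsoid_rho(pts, spec$ventricle$center, spec$ventricle$semiaxes)
    lab[rho_v <= 1 & lab > 0L] <- 2L
  }
  if (!is.null(spec$tumor)) {
    d_t <- sqrt(rowSums(sweep(pts, 2, spec$tumor$center, "-")^2))
    lab[d_t <= spec$tumor$radius & lab > 0L] <- 3L
  }
  labels <- label_volume(array(lab, gs), spec$spacing, geom$origin)

  base <- c(0, 100, 60, 150)[lab + 1L]
  pre_arr <- array(base, gs)
  if (!is.null(spec$structures)) {
    st <- spec$structures
    sdraw <- with_seed(spec$seed + 2L, list(
      cen = matrix(stats::runif(3 * st$n), st$n, 3),
      ax = matrix(stats::runif(3 * st$n, st$min_axis, st$max_axis), st$n, 3),
      amp = stats::runif(st$n, -st$intensity, st$intensity)))
    off <- numeric(nrow(pts))
    for (s in seq_len(st$n)) {
      # centers drawn inside the brain ellipsoid (rho < 0.7)
      dirc <- sdraw$cen[s, ] * 2 - 1
      cen <- spec$brain$center + dirc * spec$brain$semiaxes * 0.7
      rho_s <- ellipsoid_rho(pts, cen, sdraw$ax[s, ])
      off[rho_s <= 1] <- off[rho_s <= 1] + sdraw$amp[s]
    }
    pre_arr[lab == 1L] <- pre_arr[lab == 1L] + off[lab == 1L]
  }
  tex <- with_seed(spec$seed, array(stats::rnorm(prod(gs)), gs))
  tex <- smooth_gaussian3(tex, spec$texture$correlation)
  tex <- tex / stats::sd(tex) * spec$texture$amplitude
  # texture scales with tissue brightness (amplitude = sd at intensity 100),
  # so dark tissue stays clearly above the image background
  pre_arr[lab > 0L] <- pre_arr[lab > 0L] +
    tex[lab > 0L] * base[lab > 0L] / 100
  # tissue never reaches air intensity: texture and structure offsets can
  # stack, so clamp the parenchyma to a floor well above background
  pre_arr[lab > 0L] <- pmin(pmax(pre_arr[lab > 0L], 25), 250)
  pre <- image_volume(pre_arr, spec$spacing, geom$origin)

  # ground-truth field: Gaussian bumps at full strength throughout the
  # brain (the cortical surface is what shifts), decaying smoothly to zero
  # in a shell outside the brain mask (rho in [1, 1.5])
  u <- matrix(0, nrow(pts), 3)
  taper <- smoothstep((1.5 - rho_brain) / 0.5)
  for (b in spec$deform) {
    dirn <- b$direction / sqrt(sum(b$direction^2))
    r2 <- rowSums(sweep(pts, 2, b$center, "-")^2)
    mag <- b$amplitude * exp(-r2 / (2 * b$width^2)) * taper
    u <- u + outer(mag, dirn)
  }
  truth <- deformation_field(array(u, c(gs, 3)), spec$spacing, geom$origin)
  check_fold_free(truth)

  intra <- warp_image(pre, truth)
  if (!is.null(spec$resection))
    intra <- apply_resection(intra, spec$resection)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed + 1L,
                       array(stats::rnorm(prod(gs), sd = spec$noise_sigma), gs))
    intra <- image_volume(intra$data + noise, spec$spacing, geom$origin)
  }
  list(pre = pre, labels = labels, truth = truth, intra = intra)
}

check_fold_free <- function(field) {
  v <- field$vectors
  sp <- field$spacing
  d <- dim(v)[1:3]
  # central-difference Jacobian of the displacement, det(I + grad u) > 0
  g <- array(0, c(d, 3, 3))
  for (comp in 1:3) for (axis in 1:3) {
    a <- array(v[, , , comp], d)
    g[, , , comp, axis] <-
      (shift_array(a, -1L, axis) - shift_array(a, 1L, axis)) / (2 * sp[axis])
  }
  J <- (1 + g[, , , 1, 1]) * ((1 + g[, , , 2, 2]) * (1 + g[, , , 3, 3]) -
                              g[, , , 2, 3] * g[, , , 3, 2]) -
       g[, , , 1, 2] * (g[, , , 2, 1] * (1 + g[, , , 3, 3]) -
                        g[, , , 2, 3] * g[, , , 3, 1]) +
       g[, , , 1, 3] * (g[, , , 2, 1] * g[, , , 3, 2] -
                        (1 + g[, , , 2, 2]) * g[, , , 3, 1])
  # boundary voxels see one-sided zero padding; restrict to the interior
  interior <- J[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  if (any(interior <= 0))
    stop("phantom deformation folds (Jacobian <= 0); reduce bump amplitude ",
         "or increase width")
  invisible(TRUE)
}

#' Zero out a resection region
#'
#' Sets voxels inside a sphere (`list(center, radius)` in mm) or inside the
#' nonzero support of a [label_volume()] mask to background intensity 0.
#'
#' @param vol an [image_volume()].
#' @param region sphere list or label mask.
#' @return the modified [image_volume()].
#' @export
apply_resection <- function(vol, region) {
  arr <- vol$data
  if (inherits(region, "label_volume")) {
    if (!grid_geometry_equal(vol, region))
      stop("apply_resection: mask geometry mismatch")
    arr[region$data > 0] <- 0
  } else {
    pts <- grid_world_points(vol)
    inside <- rowSums(sweep(pts, 2, region$center, "-")^2) <= region$radius^2
    arr[array(inside, dim(arr))] <- 0
  }
  image_volume(arr, vol$spacing, vol$origin)
}
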