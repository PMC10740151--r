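#' Image volume
#'
#' A 3D scalar grid with voxel spacing and world origin. The voxel-to-world
#' map is the diagonal affine `world = origin + v * spacing` with 0-based
#' voxel indices; oblique orientations are not supported.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: data must have exactly 3 axes")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Label volume
#'
#' Integer tissue labels on the same grid conventions as [image_volume()].
#' Label 0 is reserved for background.
#'
#' @inheritParams image_volume
#' @return An object of class `label_volume` (also `image_volume`).
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (any(data < 0) || any(data != round(data)))
    stop("label_volume: labels must be non-negative integers")
  vol <- image_volume(data, spacing, origin)
  class(vol) <- c("label_volume", class(vol))
  vol
}

#' Dense deformation field
#'
#' Per-voxel 3-vectors in mm stored on an image grid. Fields use the
#' backward (pull) convention of [warp_image()]: the warped image reads
#' `out(v) = in(world(v) + field(v))`.
#'
#' @param vectors 4D numeric array `nx x ny x nz x 3` of mm displacements.
#' @inheritParams image_volume
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation_field: vectors must be an nx x ny x nz x 3 array")
  if (any(!is.finite(vectors)))
    stop("deformation_field: vectors must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("deformation_field: spacing must be 3 positive values")
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "deformation_field")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %s grid, max |u| = %.3g mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              sqrt(max(rowSums(matrix(x$vectors, ncol = 3)^2)))))
  invisible(x)
}

grid_geometry_equal <- function(a, b, tol = 1e-9) {
  da <- if (inherits(a, "deformation_field")) dim(a$vectors)[1:3] else dim(a$data)
  db <- if (inherits(b, "deformation_field")) dim(b$vectors)[1:3] else dim(b$data)
  all(da == db) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must have 3 columns (x y z in mm)")
  storage.mode(p) <- "double"
  p
}

#' Voxel/world coordinate maps
#'
#' 0-based voxel indices map to world mm by `origin + v * spacing`
#' (componentwise); `world_to_voxel` is the exact inverse. Out-of-grid
#' coordinates are permitted and returned unchanged by the round trip.
#'
#' @param v,p n x 3 matrix (or length-3 vector) of voxel indices / mm points.
#' @param vol an [image_volume()] or [deformation_field()].
#' @return n x 3 numeric matrix.
#' @export
voxel_to_world <- function(v, vol) {
  v <- as_points(v)
  sweep(sweep(v, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(p, vol) {
  p <- as_points(p)
  sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Trilinear sampling at world points
#'
#' Samples a volume (or a deformation field, componentwise) at arbitrary
#' world points by trilinear interpolation. Points outside the voxel-center
#' bounding box get `background`.
#'
#' @param vol an [image_volume()] or [deformation_field()].
#' @param p n x 3 matrix of world points (mm).
#' @param background fill value outside the grid (default 0).
#' @return numeric vector length n (volume) or n x 3 matrix (field).
#' @export
sample_trilinear <- function(vol, p, background = 0) {
  p <- as_points(p)
  if (inherits(vol, "deformation_field")) {
    d <- dim(vol$vectors)
    out <- matrix(background, nrow(p), 3)
    for (c in 1:3) {
      comp <- image_volume(array(vol$vectors[, , , c], d[1:3]),
                           vol$spacing, vol$origin)
      out[, c] <- sample_trilinear(comp, p, background)
    }
    return(out)
  }
  arr <- vol$data
  dm <- dim(arr)
  v <- world_to_voxel(p, vol)
  inside <- v[, 1] >= 0 & v[, 1] <= dm[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= dm[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= dm[3] - 1
  out <- rep(as.numeric(background), nrow(p))
  if (!any(inside)) return(out)
  v <- v[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(v[, 1]), 0), dm[1] - 2); fx <- v[, 1] - i0
  j0 <- pmin(pmax(floor(v[, 2]), 0), dm[2] - 2); fy <- v[, 2] - j0
  k0 <- pmin(pmax(floor(v[, 3]), 0), dm[3] - 2); fz <- v[, 3] - k0
  # handle exact upper-edge points (frac can be exactly 1 after clamping)
  base <- 1 + i0 + dm[1] * (j0 + dm[2] * k0)
  sx <- 1; sy <- dm[1]; sz <- dm[1] * dm[2]
  c000 <- arr[base];           c100 <- arr[base + sx]
  c010 <- arr[base + sy];      c110 <- arr[base + sx + sy]
  c001 <- arr[base + sz];      c101 <- arr[base + sx + sz]
  c011 <- arr[base + sy + sz]; c111 <- arr[base + sx + sy + sz]
  w <- (c000 * (1 - fx) + c100 * fx) * (1 - fy) +
       (c010 * (1 - fx) + c110 * fx) * fy
  w2 <- (c001 * (1 - fx) + c101 * fx) * (1 - fy) +
        (c011 * (1 - fx) + c111 * fx) * fy
  out[inside] <- w * (1 - fz) + w2 * fz
  out
}

#' Nearest-neighbour sampling at world points
#'
#' Used for warping label volumes, where interpolation would invent labels.
#'
#' @inheritParams sample_trilinear
#' @return numeric vector length n.
#' @export
sample_nearest <- function(vol, p, background = 0) {
  p <- as_points(p)
  dm <- dim(vol$data)
  v <- round(world_to_voxel(p, vol))
  inside <- v[, 1] >= 0 & v[, 1] <= dm[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= dm[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= dm[3] - 1
  out <- rep(as.numeric(background), nrow(p))
  if (!any(inside)) return(out)
  vv <- v[inside, , drop = FALSE]
  out[inside] <- vol$data[1 + vv[, 1] + dm[1] * (vv[, 2] + dm[2] * vv[, 3])]
  out
}

grid_world_points <- function(vol) {
  dm <- if (inherits(vol, "deformation_field")) dim(vol$vectors)[1:3] else dim(vol$data)
  idx <- cbind(
    rep.int(0:(dm[1] - 1), dm[2] * dm[3]),
    rep.int(rep(0:(dm[2] - 1), each = dm[1]), dm[3]),
    rep(0:(dm[3] - 1), each = dm[1] * dm[2]))
  voxel_to_world(idx, vol)
}

#' Warp a volume with a dense deformation field
#'
#' Backward (pull) warping: `out(v) = vol(world(v) + field(v))`, sampled
#' trilinearly (or nearest-neighbour for label volumes). The output grid is
#' the field's grid.
#'
#' @param vol the floating [image_volume()] to resample.
#' @param field a [deformation_field()] defining the output grid and the
#'   pull vectors in mm.
#' @param interp `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   label volumes.
#' @param background fill value for samples outside `vol`.
#' @return an [image_volume()] (or [label_volume()]) on the field's grid.
#' @export
warp_image <- function(vol, field,
                       interp = if (inherits(vol, "label_volume")) "nearest" else "linear",
                       background = 0) {
  if (!inherits(field, "deformation_field"))
    stop("warp_image: field must be a deformation_field")
  dm <- dim(field$vectors)[1:3]
  pts <- grid_world_points(field) + matrix(field$vectors, ncol = 3)
  vals <- if (interp == "nearest") sample_nearest(vol, pts, background)
          else sample_trilinear(vol, pts, background)
  out <- array(vals, dm)
  if (inherits(vol, "label_volume"))
    label_volume(out, field$spacing, field$origin)
  else image_volume(out, field$spacing, field$origin)
}

#' Invert a displacement field
#'
#' Given a displacement field `T` (pull convention), computes `T'` with
#' `T'(x) = -T(x + T'(x))` by damped fixed-point iteration, so that the two
#' fields compose to (approximately) the identity. Used to convert between
#' the forward vertex displacements solved by the FEM and the pull fields
#' used for image warping.
#'
#' @param field a [deformation_field()].
#' @param iters fixed-point iterations (default 10; the iteration
#'   contracts like the field's displacement-gradient norm, so brain-shift
#'   scale fields converge to well below voxel precision).
#' @return a [deformation_field()] on the same grid.
#' @export
invert_field <- function(field, iters = 10L) {
  dm <- dim(field$vectors)[1:3]
  x <- grid_world_points(field)
  tp <- matrix(0, nrow(x), 3)
  for (i in seq_len(iters)) {
    tp <- -sample_trilinear(field, x + tp)
  }
  deformation_field(array(tp, c(dm, 3)), field$spacing, field$origin)
}

#' Compose two pull deformation fields
#'
#' Returns the field equivalent to warping first with `f_outer` applied to
#' an image already warped by `f_inner`:
#' `T(v) = f_outer(v) + f_inner(world(v) + f_outer(v))`.
#'
#' @param f_inner,f_outer [deformation_field()]s on the same grid.
#' @return a [deformation_field()].
#' @export
compose_fields <- function(f_inner, f_outer) {
  if (!grid_geometry_equal(f_inner, f_outer))
    stop("compose_fields: geometry mismatch")
  x <- grid_world_points(f_outer)
  outer_v <- matrix(f_outer$vectors, ncol = 3)
  inner_at <- sample_trilinear(f_inner, x + outer_v)
  deformation_field(array(outer_v + inner_at, dim(f_outer$vectors)),
                    f_outer$spacing, f_outer$origin)
}

#' A zero deformation field matching a volume's grid
#' @param vol an [image_volume()].
#' @return a [deformation_field()] of zeros.
#' @export
zero_field <- function(vol) {
  deformation_field(array(0, c(dim(vol$data), 3)), vol$spacing, vol$origin)
}
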