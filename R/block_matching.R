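# Exhaustive NCC block matching. The block (half-width B) is taken from
# the floating image around each registration point; all integer-voxel
# offsets with |o| <= W per axis are scored against the fixed image, an
# O(BxByBz x WxWyWz) search per point.

#' Block-matching configuration
#'
#' @param block_radius voxel triple B (default `[1,1,1]`).
#' @param window_radius voxel triple W (default `[5,5,5]`).
#' @return a `block_match_config` list.
#' @export
block_match_config <- function(block_radius = c(1, 1, 1),
                               window_radius = c(5, 5, 5)) {
  if (any(block_radius < 1) || any(window_radius < 1))
    stop("block_match_config: radii must be >= 1")
  structure(list(block_radius = as.integer(block_radius),
                 window_radius = as.integer(window_radius)),
            class = "block_match_config")
}

#' Sparse displacement field
#'
#' Registration points with their block-matching displacements (entries of
#' the match vector D) and confidence weights (the diagonal of the match
#' stiffness S, `max(0, best NCC)` per point).
#'
#' @param points n x 3 matrix of mm registration points (floating image).
#' @param displacements n x 3 matrix of mm displacements.
#' @param confidences numeric in `[0, 1]` per point.
#' @return a `sparse_field` object.
#' @export
sparse_field <- function(points, displacements, confidences) {
  points <- as_points(points); displacements <- as_points(displacements)
  confidences <- as.numeric(confidences)
  if (nrow(points) != nrow(displacements) ||
      nrow(points) != length(confidences))
    stop("sparse_field: length mismatch")
  if (any(!is.finite(displacements)))
    stop("sparse_field: displacements must be finite")
  if (length(confidences) && (min(confidences) < 0 || max(confidences) > 1))
    stop("sparse_field: confidences must lie in [0, 1]")
  structure(list(points = points, displacements = displacements,
                 confidences = confidences), class = "sparse_field")
}

#' @export
print.sparse_field <- function(x, ...) {
  cat(sprintf("<sparse_field> %d matches, mean confidence %.3f\n",
              nrow(x$points),
              if (nrow(x$points)) mean(x$confidences) else NA_real_))
  invisible(x)
}

#' Normalized cross-correlation of two intensity blocks
#'
#' Pearson-style NCC in `[-1, 1]`. Returns `NA` (the "undefined" sentinel)
#' when either block has zero variance.
#'
#' @param block_a,block_b numeric arrays of identical shape, >= 2 voxels.
#' @return scalar in `[-1, 1]`, or `NA`.
#' @export
ncc <- function(block_a, block_b) {
  if (!identical(dim(block_a), dim(block_b)) ||
      length(block_a) != length(block_b))
    stop("ncc: block shapes differ")
  if (length(block_a) < 2) stop("ncc: blocks need >= 2 voxels")
  a <- as.numeric(block_a) - mean(block_a)
  b <- as.numeric(block_b) - mean(block_b)
  sa <- sqrt(sum(a * a)); sb <- sqrt(sum(b * b))
  if (sa == 0 || sb == 0) return(NA_real_)
  max(-1, min(1, sum(a * b) / (sa * sb)))
}

block_offsets <- function(radius) {
  as.matrix(expand.grid(dx = -radius[1]:radius[1],
                        dy = -radius[2]:radius[2],
                        dz = -radius[3]:radius[3]))
}

extract_block <- function(arr, v, radius) {
  arr[(v[1] - radius[1]):(v[1] + radius[1]) + 1L,
      (v[2] - radius[2]):(v[2] + radius[2]) + 1L,
      (v[3] - radius[3]):(v[3] + radius[3]) + 1L]
}

#' Match a single registration point
#'
#' Exhaustive search over all `prod(2W + 1)` integer-voxel offsets; the
#' displacement is the argmax-NCC offset converted to mm and the
#' confidence is `max(0, best NCC)`. Ties break toward the smallest
#' displacement norm, then lexicographic offset.
#'
#' @param floating,fixed [image_volume()]s on the same grid.
#' @param s length-3 world point (mm) at a voxel center of `floating`.
#' @param cfg a [block_match_config()].
#' @return list(displacement, confidence, ok, reason).
#' @export
match_point <- function(floating, fixed, s, cfg = block_match_config()) {
  sdf <- block_match_all(floating, fixed, matrix(s, 1, 3), cfg)
  if (nrow(sdf$points) == 0)
    return(list(displacement = c(NA, NA, NA), confidence = 0,
                ok = FALSE, reason = "block or window out of bounds"))
  list(displacement = sdf$displacements[1, ], confidence = sdf$confidences[1],
       ok = TRUE, reason = NULL)
}

#' Block matching at every registration point
#'
#' Vectorized exhaustive NCC search (all points scored per candidate
#' offset). Points whose block or window leaves either grid are skipped;
#' flat (zero-variance) blocks and undefined-NCC points get confidence 0
#' with zero displacement.
#'
#' @param floating,fixed [image_volume()]s with identical geometry.
#' @param points n x 3 matrix of world points at voxel centers of
#'   `floating`.
#' @param cfg a [block_match_config()].
#' @return a [sparse_field()] over the retained (in-bounds) points.
#' @export
block_match_all <- function(floating, fixed, points,
                            cfg = block_match_config()) {
  if (!grid_geometry_equal(floating, fixed))
    stop("block_match_all: floating/fixed geometry mismatch")
  points <- as_points(points)
  if (nrow(points) == 0)
    return(sparse_field(points, points, numeric(0)))
  dm <- dim(floating$data)
  B <- cfg$block_radius; W <- cfg$window_radius
  v <- round(world_to_voxel(points, floating))
  in_f <- v[, 1] >= B[1] & v[, 1] <= dm[1] - 1 - B[1] &
          v[, 2] >= B[2] & v[, 2] <= dm[2] - 1 - B[2] &
          v[, 3] >= B[3] & v[, 3] <= dm[3] - 1 - B[3]
  m <- B + W
  in_w <- v[, 1] >= m[1] & v[, 1] <= dm[1] - 1 - m[1] &
          v[, 2] >= m[2] & v[, 2] <= dm[2] - 1 - m[2] &
          v[, 3] >= m[3] & v[, 3] <= dm[3] - 1 - m[3]
  keep <- in_f & in_w
  v <- v[keep, , drop = FALSE]
  pts <- points[keep, , drop = FALSE]
  n <- nrow(v)
  if (n == 0) return(sparse_field(pts, pts, numeric(0)))

  boff <- block_offsets(B)
  nb <- nrow(boff)
  # linear indices of each point's block voxels (n x nb)
  lin <- function(ix) 1 + ix[, 1] + dm[1] * (ix[, 2] + dm[2] * ix[, 3])
  base <- lin(v)
  bshift <- boff[, 1] + dm[1] * (boff[, 2] + dm[2] * boff[, 3])
  idx <- outer(base, bshift, "+")
  fblocks <- matrix(floating$data[idx], n, nb)
  fmu <- rowMeans(fblocks)
  fc <- fblocks - fmu
  fss <- sqrt(rowSums(fc * fc))
  flat <- fss == 0

  woff <- block_offsets(W)
  # tie-break order: smallest offset norm first, then lexicographic
  ord <- order(rowSums(woff^2),  woff[, 3], woff[, 2], woff[, 1])
  woff <- woff[ord, , drop = FALSE]
  best <- rep(-Inf, n)
  besti <- rep(1L, n)
  fixed_arr <- fixed$data
  for (t in seq_len(nrow(woff))) {
    shift <- woff[t, 1] + dm[1] * (woff[t, 2] + dm[2] * woff[t, 3])
    gb <- matrix(fixed_arr[idx + shift], n, nb)
    gc <- gb - rowMeans(gb)
    gss2 <- rowSums(gc * gc)
    score <- rowSums(fc * gc) / (fss * sqrt(gss2))
    score[!is.finite(score)] <- -Inf
    better <- score > best + 1e-12   # strict: earlier (smaller) offsets win ties
    best[better] <- score[better]
    besti[better] <- t
  }
  disp <- woff[besti, , drop = FALSE] *
    matrix(floating$spacing, n, 3, byrow = TRUE)
  conf <- pmax(0, pmin(1, best))
  nomatch <- flat | !is.finite(best)
  disp[nomatch, ] <- 0
  conf[nomatch] <- 0
  sparse_field(pts, disp, conf)
}
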