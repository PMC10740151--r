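# Registration-point selection by local intensity variance, and Canny edge
# point sets used both as NEMNRR correspondence targets and by the
# Hausdorff evaluation protocol.

#' Feature-selection configuration
#'
#' @param selection_fraction fraction of candidate voxels kept (0, 1].
#' @param block_radius voxel triple; the variance neighbourhood half-width.
#' @param window_radius voxel triple; block-matching search half-width.
#'   Candidates are restricted to voxels whose block *and* window fit in
#'   the grid so block matching never needs boundary handling.
#' @param mask optional [label_volume()]; only in-mask voxels are candidates.
#' @param min_spacing optional mm pruning distance between selected points.
#' @return a `feature_config` list.
#' @export
feature_config <- function(selection_fraction = 0.05,
                           block_radius = c(1, 1, 1),
                           window_radius = c(5, 5, 5),
                           mask = NULL, min_spacing = NULL) {
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop("feature_config: selection_fraction must be in (0, 1]")
  if (any(block_radius < 1)) stop("feature_config: block_radius must be >= 1")
  structure(list(selection_fraction = selection_fraction,
                 block_radius = as.integer(block_radius),
                 window_radius = as.integer(window_radius),
                 mask = mask, min_spacing = min_spacing),
            class = "feature_config")
}

local_variance <- function(arr, radius) {
  n <- prod(2L * radius + 1L)
  s1 <- array(0, dim(arr)); s2 <- array(0, dim(arr))
  for (dx in -radius[1]:radius[1])
    for (dy in -radius[2]:radius[2])
      for (dz in -radius[3]:radius[3]) {
        sh <- shift_array(arr, dx, 1L)
        if (dy != 0) sh <- shift_array(sh, dy, 2L)
        if (dz != 0) sh <- shift_array(sh, dz, 3L)
        s1 <- s1 + sh; s2 <- s2 + sh * sh
      }
  pmax(s2 / n - (s1 / n)^2, 0)
}

#' Select registration points by local intensity variability
#'
#' Ranks every candidate voxel (in-mask, block and search window inside the
#' grid) by the intensity variance of its block neighbourhood and returns
#' the top `floor(selection_fraction * N_candidates)` as world points.
#' Zero-variance voxels are never selected; ties break on voxel index.
#'
#' @param vol the floating [image_volume()].
#' @param cfg a [feature_config()].
#' @return n x 3 matrix of world points (mm), variance-descending order.
#' @export
select_registration_points <- function(vol, cfg = feature_config()) {
  dm <- dim(vol$data)
  margin <- cfg$block_radius + cfg$window_radius
  if (any(dm <= 2 * margin))
    stop("select_registration_points: grid smaller than block+window margins")
  varr <- local_variance(vol$data, cfg$block_radius)
  ok <- array(FALSE, dm)
  ok[(margin[1] + 1):(dm[1] - margin[1]),
     (margin[2] + 1):(dm[2] - margin[2]),
     (margin[3] + 1):(dm[3] - margin[3])] <- TRUE
  if (!is.null(cfg$mask)) {
    if (!grid_geometry_equal(vol, cfg$mask))
      stop("select_registration_points: mask geometry mismatch")
    if (!any(cfg$mask$data > 0)) stop("select_registration_points: empty mask")
    ok <- ok & (cfg$mask$data > 0)
  }
  cand <- which(ok)
  n_keep <- floor(cfg$selection_fraction * length(cand))
  v <- varr[cand]
  pos <- v > 0
  cand <- cand[pos]; v <- v[pos]
  if (length(cand) == 0) return(as_points(matrix(numeric(0), 0, 3)))
  ord <- order(-v, cand)
  take <- ord[seq_len(min(n_keep, length(ord)))]
  sel <- cand[take] - 1L
  idx <- cbind(sel %% dm[1],
               (sel %/% dm[1]) %% dm[2],
               sel %/% (dm[1] * dm[2]))
  pts <- voxel_to_world(idx, vol)
  if (!is.null(cfg$min_spacing)) pts <- prune_min_spacing(pts, cfg$min_spacing)
  pts
}

prune_min_spacing <- function(pts, min_spacing) {
  kept <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    d2 <- rowSums(sweep(pts[kept, , drop = FALSE], 2, pts[i, ], "-")^2)
    if (min(d2) >= min_spacing^2) kept[i] <- TRUE
  }
  pts[kept, , drop = FALSE]
}

shift_mat <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); rj <- seq_len(ncol(m))
  si <- ri - di; sj <- rj - dj
  keep_i <- si >= 1 & si <= nrow(m); keep_j <- sj >= 1 & sj <= ncol(m)
  out[ri[keep_i], rj[keep_j]] <- m[si[keep_i], sj[keep_j]]
  out
}

canny_slice <- function(img, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  # renormalized smoothing: dividing by the blurred indicator avoids the
  # intensity ramp zero padding would create at the slice border
  ones <- matrix(1, nrow(img), ncol(img))
  blur <- function(m) {
    sm <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) sm <- sm + k[t] * shift_mat(m, t - r - 1L, 0L)
    sm2 <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) sm2 <- sm2 + k[t] * shift_mat(sm, 0L, t - r - 1L)
    sm2
  }
  sm <- blur(img) / blur(ones)
  gx <- shift_mat(sm, -1, -1) + 2 * shift_mat(sm, -1, 0) + shift_mat(sm, -1, 1) -
        shift_mat(sm,  1, -1) - 2 * shift_mat(sm,  1, 0) - shift_mat(sm,  1, 1)
  gy <- shift_mat(sm, -1, -1) + 2 * shift_mat(sm, 0, -1) + shift_mat(sm, 1, -1) -
        shift_mat(sm, -1,  1) - 2 * shift_mat(sm, 0,  1) - shift_mat(sm, 1,  1)
  mag <- sqrt(gx^2 + gy^2)
  # the outermost 2 pixels see out-of-grid zeros in the Sobel stencil
  mag[c(1, 2, nrow(mag) - 1, nrow(mag)), ] <- 0
  mag[, c(1, 2, ncol(mag) - 1, ncol(mag))] <- 0
  list(gx = gx, gy = gy, mag = mag)
}

canny_nms <- function(g) {
  ang <- atan2(g$gy, g$gx)
  # quantize to 4 directions: 0, 45, 90, 135 degrees
  q <- round(ang / (pi / 4)) %% 4
  m <- g$mag
  keep <- matrix(FALSE, nrow(m), ncol(m))
  dirs <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  for (b in 0:3) {
    d <- dirs[[b + 1]]
    nb1 <- shift_mat(m,  d[1],  d[2])
    nb2 <- shift_mat(m, -d[1], -d[2])
    keep <- keep | (q == b & m >= nb1 & m >= nb2)
  }
  keep & m > 0
}

canny_hysteresis <- function(strong, weak, max_iter = 10000L) {
  edges <- strong
  for (i in seq_len(max_iter)) {
    grow <- matrix(FALSE, nrow(edges), ncol(edges))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      grow <- grow | shift_mat(edges, di, dj) > 0
    }
    newe <- edges | (weak & grow)
    if (identical(newe, edges)) break
    edges <- newe
  }
  edges
}

#' Canny edge point sets
#'
#' Runs the classical 2D Canny detector on every axial (k-index) slice:
#' Gaussian smoothing, Sobel gradients, 4-direction non-maximum
#' suppression, and double-threshold hysteresis. Thresholds are fractions
#' of the volume-wide maximum gradient magnitude, which keeps the detector
#' deterministic and intensity-scale-free.
#'
#' @param vol an [image_volume()].
#' @param low,high hysteresis thresholds as fractions of max magnitude.
#' @param sigma Gaussian smoothing sigma in voxels.
#' @return n x 3 matrix of world edge points (mm).
#' @export
canny_edge_points <- function(vol, low = 0.10, high = 0.20, sigma = 1.4) {
  dm <- dim(vol$data)
  grads <- lapply(seq_len(dm[3]), function(k)
    canny_slice(matrix(vol$data[, , k], dm[1], dm[2]), sigma))
  gmax <- max(vapply(grads, function(g) max(g$mag), numeric(1)))
  # relative thresholds need an absolute floor: round-off dust on a
  # featureless image must not count as gradient
  if (gmax <= 1e-9 * max(abs(vol$data), 1))
    return(as_points(matrix(numeric(0), 0, 3)))
  th_low <- low * gmax; th_high <- high * gmax
  pts <- vector("list", dm[3])
  for (k in seq_len(dm[3])) {
    g <- grads[[k]]
    nms <- canny_nms(g)
    strong <- nms & g$mag >= th_high
    weak <- nms & g$mag >= th_low
    if (!any(strong)) next
    edges <- canny_hysteresis(strong, weak)
    ij <- which(edges, arr.ind = TRUE)
    if (nrow(ij)) pts[[k]] <- cbind(ij[, 1] - 1L, ij[, 2] - 1L, k - 1L)
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) return(as_points(matrix(numeric(0), 0, 3)))
  voxel_to_world(pts, vol)
}
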