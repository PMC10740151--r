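# Hausdorff-distance evaluation on Canny edge point sets: the first set
# comes from the (warped) pre-operative volume, the second from the
# intra-operative volume; the symmetric HD upper-bounds the remaining
# misalignment, without assuming point correspondence.

min_dists <- function(A, B, chunk = 256L) {
  n <- nrow(A)
  out <- numeric(n)
  bb <- rowSums(B^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    q <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(q)), bb) - 2 * q %*% t(B)
    # the expanded form suffers cancellation (~1e-8); recompute the
    # winning pair's distance exactly
    j <- apply(d2, 1, which.min)
    out[s:e] <- sqrt(rowSums((q - B[j, , drop = FALSE])^2))
  }
  out
}

#' Directed and symmetric Hausdorff distance
#'
#' `directed_hausdorff(A, B) = max_a min_b ||a - b||`;
#' `hausdorff(A, B) = max(directed(A, B), directed(B, A))`. Computed on
#' world-coordinate (mm) point sets.
#'
#' @param A,B nonempty n x 3 point matrices (mm).
#' @return distance in mm.
#' @export
directed_hausdorff <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  if (!nrow(A) || !nrow(B)) stop("directed_hausdorff: empty point set")
  max(min_dists(A, B))
}

#' @rdname directed_hausdorff
#' @export
hausdorff <- function(A, B) {
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Hausdorff-distance improvement ratio
#'
#' `(before - after) / before`, reported to 3 decimals.
#'
#' @param before,after HD in mm; `before` must be > 0.
#' @return dimensionless ratio.
#' @export
hd_improvement <- function(before, after) {
  if (before <= 0) stop("hd_improvement: before must be > 0")
  round((before - after) / before, 3)
}

#' Evaluate a registration with the Canny/Hausdorff protocol
#'
#' HD before = `hausdorff(canny(pre), canny(intra))`; HD after =
#' `hausdorff(canny(warp(pre, field)), canny(intra))`; plus the
#' improvement ratio and optional paired-landmark error summaries.
#'
#' @param pre,intra [image_volume()]s.
#' @param field a pull-convention [deformation_field()] on the intra grid.
#' @param low,high,sigma Canny parameters (see [canny_edge_points()]).
#' @param landmarks optional n x 6 matrix of paired landmarks
#'   (x y z x' y' z' in mm); per-pair Euclidean errors are summarized.
#' @return an `eval_report` list: `hd_before`, `hd_after`, `improvement`,
#'   the four directed distances, and optional landmark `min/max/mean`.
#' @export
evaluate_registration <- function(pre, intra, field,
                                  low = 0.10, high = 0.20, sigma = 1.4,
                                  landmarks = NULL) {
  if (!grid_geometry_equal(intra, field))
    stop("evaluate_registration: field/intra geometry mismatch")
  e_pre <- canny_edge_points(pre, low, high, sigma)
  e_intra <- canny_edge_points(intra, low, high, sigma)
  warped <- warp_image(pre, field)
  e_warp <- canny_edge_points(warped, low, high, sigma)
  if (!nrow(e_pre) || !nrow(e_intra) || !nrow(e_warp))
    stop("evaluate_registration: empty edge set; lower the Canny thresholds")
  rep <- list(
    hd_before = hausdorff(e_pre, e_intra),
    hd_after = hausdorff(e_warp, e_intra),
    directed = c(pre_to_intra = directed_hausdorff(e_pre, e_intra),
                 intra_to_pre = directed_hausdorff(e_intra, e_pre),
                 warped_to_intra = directed_hausdorff(e_warp, e_intra),
                 intra_to_warped = directed_hausdorff(e_intra, e_warp)),
    n_edges = c(pre = nrow(e_pre), intra = nrow(e_intra),
                warped = nrow(e_warp)))
  rep$improvement <- if (rep$hd_before > 0)
    hd_improvement(rep$hd_before, rep$hd_after) else 0
  if (!is.null(landmarks)) {
    landmarks <- as.matrix(landmarks)
    if (ncol(landmarks) != 6) stop("landmarks must have 6 columns")
    err <- sqrt(rowSums((landmarks[, 1:3, drop = FALSE] -
                         landmarks[, 4:6, drop = FALSE])^2))
    rep$landmark <- c(min = min(err), max = max(err), mean = mean(err))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> HD before %.3f mm, after %.3f mm, improvement %.3f\n",
              x$hd_before, x$hd_after, x$improvement))
  invisible(x)
}
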