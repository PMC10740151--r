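# Hybrid approximation -> interpolation solver with iterative point-outlier
# rejection. Solves [K + H'SH] U = H'S D + F, where F = K U_i relaxes the
# internal mesh stress toward the interpolation solution, rejecting the
# worst-fitting fraction of matches over n_R iterations.

#' PBNRR configuration
#'
#' Defaults follow the standard clinical parameter set: rejection fraction
#' 0.25 over 10 rejection steps plus 10 approximation (relaxation) steps.
#'
#' @param f_R total fraction of matches to reject in `[0, 1)`.
#' @param n_R number of rejection iterations (>= 1).
#' @param n_A cap on post-rejection relaxation steps.
#' @param tol convergence threshold on the max vertex-displacement change (mm).
#' @param max_iter hard cap on relaxation iterations (>= n_A).
#' @param k_scale global stiffness scale balancing K against H'SH.
#'   `"auto"` sets `100 * trace(H'SH) / trace(K)`: stiff enough that
#'   outlier matches cannot bend the model locally during the rejection
#'   phase (which is what makes the block-error ranking discriminative),
#'   while the relaxation loop (`F = K U`) restores data fidelity
#'   afterwards regardless of the scale.
#' @return a `pbnrr_config` list.
#' @export
pbnrr_config <- function(f_R = 0.25, n_R = 10L, n_A = 10L, tol = 1e-3,
                         max_iter = 50L, k_scale = "auto") {
  if (f_R < 0 || f_R >= 1) stop("pbnrr_config: f_R must be in [0, 1)")
  if (n_R < 1) stop("pbnrr_config: n_R must be >= 1")
  if (tol <= 0) stop("pbnrr_config: tol must be > 0")
  structure(list(f_R = f_R, n_R = as.integer(n_R), n_A = as.integer(n_A),
                 tol = tol, max_iter = as.integer(max_iter),
                 k_scale = k_scale),
            class = "pbnrr_config")
}

#' Matches rejected per rejection iteration
#'
#' `floor(N * f_R / n_R)` with N fixed at the initial located-match count,
#' so the total over n_R iterations is `n_R * floor(N * f_R / n_R)`.
#'
#' @param N initial number of active matches.
#' @param f_R total rejection fraction.
#' @param n_R number of rejection iterations.
#' @return integer count per iteration.
#' @export
rejection_count <- function(N, f_R, n_R) {
  as.integer(floor(N * f_R / n_R))
}

#' Solve the hybrid registration system
#'
#' `[K + H'SH] U = H'S D + F` by sparse Cholesky. `K` is passed already
#' scaled (see `k_scale`). Errors out, citing missing rigid-mode
#' constraints, if the operator is rank deficient.
#'
#' @param K sparse `3n x 3n` stiffness matrix (scaled).
#' @param H sparse `3m x 3n` interpolation matrix.
#' @param S length-m match weights (diagonal of S, one per match) or
#'   length-3m per-dof weights.
#' @param D length-3m displacement vector (x,y,z per match).
#' @param F length-3n external force vector (default zero).
#' @return length-3n solution U.
#' @export
solve_hybrid <- function(K, H, S, D, F = NULL) {
  n3 <- nrow(K)
  if (is.null(F)) F <- numeric(n3)
  s3 <- if (length(S) * 3 == nrow(H)) rep(S, each = 3) else S
  if (length(s3) != nrow(H)) stop("solve_hybrid: S length mismatch")
  Sd <- Matrix::Diagonal(x = s3)
  A <- Matrix::forceSymmetric(K + Matrix::crossprod(H, Sd %*% H))
  b <- as.numeric(Matrix::crossprod(H, s3 * D)) + F
  U <- tryCatch({
    fac <- Matrix::Cholesky(A, LDL = TRUE, super = FALSE)
    piv <- Matrix::diag(fac)
    if (min(piv) <= 1e-10 * max(piv))
      stop("near-zero pivot")
    as.numeric(Matrix::solve(fac, b))
  }, error = function(e)
    stop("solve_hybrid: operator is singular - matches do not ",
         "constrain all rigid modes (", conditionMessage(e), ")"))
  res <- sqrt(sum((as.numeric(A %*% U) - b)^2))
  if (res > 1e-8 * max(sqrt(sum(b^2)), 1e-300))
    stop("solve_hybrid: residual ", signif(res, 3), " exceeds tolerance")
  U
}

#' Per-match block errors
#'
#' `xi_k = || (H U)_k - d_k ||_2` for each active match: the distance
#' between the displacement the deformed mesh implies at the match point
#' and the matching target.
#'
#' @param H sparse interpolation matrix over the active matches.
#' @param U length-3n vertex displacement vector.
#' @param D length-3m active match displacement vector.
#' @return numeric vector of m errors (mm).
#' @export
compute_block_errors <- function(H, U, D) {
  r <- as.numeric(H %*% U) - D
  sqrt(colSums(matrix(r * r, nrow = 3)))
}

interleave_disp <- function(disp) as.numeric(t(disp))

#' Physics-based non-rigid registration with point-outlier rejection
#'
#' Runs feature selection and block matching (unless `matches` is
#' supplied), builds H/S/D over the located matches, then performs `n_R`
#' rejection iterations of the hybrid solve (each discarding the
#' `floor(N f_R / n_R)` matches with the largest block error) followed by
#' relaxation iterations until the max vertex change drops below `tol`.
#'
#' @param floating,fixed pre- and intra-operative [image_volume()]s.
#' @param mesh a [tet_mesh()] of the floating-image brain.
#' @param materials a [material_table()].
#' @param feature_cfg a [feature_config()].
#' @param match_cfg a [block_match_config()].
#' @param cfg a [pbnrr_config()].
#' @param matches optional precomputed [sparse_field()] (skips feature
#'   selection and block matching).
#' @param dense rasterize and invert the dense fields (set `FALSE` when
#'   only the vertex displacements are needed, e.g. inside ANRR).
#' @return a `registration_result`: vertex displacements `U` (n x 3,
#'   forward), active/rejected match index sets, per-iteration
#'   diagnostics, the pull-convention `dense_field` for [warp_image()],
#'   and the forward-rasterized `forward_field`.
#' @export
pbnrr_register <- function(floating, fixed, mesh,
                           materials = material_table(),
                           feature_cfg = feature_config(),
                           match_cfg = block_match_config(),
                           cfg = pbnrr_config(),
                           matches = NULL, dense = TRUE) {
  if (is.null(matches)) {
    pts <- select_registration_points(floating, feature_cfg)
    matches <- block_match_all(floating, fixed, pts, match_cfg)
  }
  bi <- build_interpolation(mesh, matches$points)
  located <- which(!is.na(bi$located))
  if (length(located) < 12)
    stop("pbnrr_register: fewer than 12 located matches")
  matches <- sparse_field(matches$points[located, , drop = FALSE],
                          matches$displacements[located, , drop = FALSE],
                          matches$confidences[located])
  bi <- build_interpolation(mesh, matches$points, bi$hash)
  H_all <- bi$H
  D_all <- interleave_disp(matches$displacements)
  w_all <- matches$confidences
  N <- nrow(matches$points)

  K0 <- assemble_stiffness(mesh, materials)
  k_scale <- cfg$k_scale
  if (identical(k_scale, "auto")) {
    tr_match <- sum(rep(w_all, each = 3) * Matrix::rowSums(H_all^2))
    tr_K <- sum(Matrix::diag(K0))
    k_scale <- if (tr_K > 0 && tr_match > 0) 100 * tr_match / tr_K else 1
  }
  K <- k_scale * K0

  active <- seq_len(N)
  rejected <- integer(0)
  per_iter <- rejection_count(N, cfg$f_R, cfg$n_R)
  U <- numeric(nrow(K))
  diag_rows <- list()

  sub_rows <- function(idx) as.vector(rbind(3 * (idx - 1) + 1,
                                            3 * (idx - 1) + 2, 3 * idx))
  for (i in seq_len(cfg$n_R)) {
    r <- sub_rows(active)
    Ha <- H_all[r, , drop = FALSE]
    U <- solve_hybrid(K, Ha, w_all[active], D_all[r],
                      as.numeric(K %*% U))
    xi <- compute_block_errors(Ha, U, D_all[r])
    n_rej <- min(per_iter, length(active))
    drop_pos <- if (n_rej > 0) order(-xi, active)[seq_len(n_rej)] else integer(0)
    diag_rows[[length(diag_rows) + 1]] <-
      data.frame(phase = "reject", iter = i, active = length(active),
                 rejected = n_rej, max_xi = if (length(xi)) max(xi) else NA,
                 delta_u = NA)
    rejected <- c(rejected, active[drop_pos])
    if (length(drop_pos)) active <- active[-drop_pos]
  }

  r <- sub_rows(active)
  Ha <- H_all[r, , drop = FALSE]
  Da <- D_all[r]; wa <- w_all[active]
  converged <- FALSE
  for (j in seq_len(min(cfg$n_A, cfg$max_iter))) {
    U_new <- solve_hybrid(K, Ha, wa, Da, as.numeric(K %*% U))
    delta <- max(abs(U_new - U))
    U <- U_new
    diag_rows[[length(diag_rows) + 1]] <-
      data.frame(phase = "relax", iter = j, active = length(active),
                 rejected = 0L,
                 max_xi = max(compute_block_errors(Ha, U, Da)),
                 delta_u = delta)
    if (delta < cfg$tol) { converged <- TRUE; break }
  }

  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  fwd <- if (dense) rasterize_mesh_field(mesh, Umat, fixed) else NULL
  structure(list(U = Umat, active_matches = active,
                 rejected_matches = rejected,
                 matches = matches, mesh = mesh,
                 iterations = do.call(rbind, diag_rows),
                 k_scale = k_scale, converged = converged,
                 forward_field = fwd,
                 dense_field = if (dense) invert_field(fwd) else NULL),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> %d vertices, %d active / %d ",
                     "rejected matches, max |U| = %.3f mm, converged: %s\n"),
              nrow(x$U), length(x$active_matches), length(x$rejected_matches),
              sqrt(max(rowSums(x$U^2))), x$converged))
  invisible(x)
}
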