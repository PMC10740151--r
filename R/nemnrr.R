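# Nested expectation-maximization registration: fuzzy correspondence
# between displaced source features and fixed-image edge points (inner E),
# a regularized displacement solve on M \ M_Rem (inner M), and outer
# growth of the face-connected resection submesh M_Rem from tetrahedra
# whose displaced centroids land in the background of the fixed image.

#' NEMNRR configuration
#'
#' @param lambda1 weight of the correspondence data term (>= 0).
#' @param lambda2 weight of the resection-volume term (>= 0).
#' @param bgi_threshold fixed-image intensity below which a voxel counts as
#'   background; `NULL` selects the two-level recursive Otsu threshold of
#'   the fixed image (see [otsu_threshold()]).
#' @param candidate_radius mm radius of the target-candidate neighbourhood
#'   per source point (defaults to the block-matching window extent).
#' @param corr_temperature mm softness of the Gaussian fuzzy assignment.
#' @param inner_tol,inner_max inner-EM stop rule (max vertex change / cap).
#'   The default cap is deliberately small: with dense edge clouds the
#'   fuzzy-correspondence flow behaves like mean shift toward edge-density
#'   modes, so the inner EM is run as a short refinement of the
#'   block-matching initialization rather than to a fixed point.
#' @param outer_max cap on outer (resection-growth) iterations.
#' @param min_seed_volume mm^3; the largest candidate component must reach
#'   this volume before it seeds M_Rem. Surgical cavities are cm^3-scale,
#'   so sub-element speckle (single dark tets from noise or local
#'   displacement error) never starts a bogus resection region.
#' @param k_scale stiffness scale as in [pbnrr_config()].
#' @return a `nemnrr_config` list.
#' @export
nemnrr_config <- function(lambda1 = 1, lambda2 = 1, bgi_threshold = NULL,
                          candidate_radius = 5, corr_temperature = 2,
                          inner_tol = 1e-2, inner_max = 3L, outer_max = 10L,
                          min_seed_volume = 500, k_scale = "auto") {
  if (lambda1 < 0 || lambda2 < 0)
    stop("nemnrr_config: lambda weights must be >= 0")
  if (corr_temperature <= 0)
    stop("nemnrr_config: corr_temperature must be > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 bgi_threshold = bgi_threshold,
                 candidate_radius = candidate_radius,
                 corr_temperature = corr_temperature,
                 inner_tol = inner_tol, inner_max = as.integer(inner_max),
                 outer_max = as.integer(outer_max),
                 min_seed_volume = min_seed_volume, k_scale = k_scale),
            class = "nemnrr_config")
}

#' Otsu intensity threshold
#'
#' Maximizes between-class variance on a 256-bin histogram. With
#' `levels = 2` (the default used for background segmentation) the
#' threshold is re-estimated recursively on the sub-threshold voxels:
#' in head MRI the first cut lands inside the tissue distribution
#' (the air peak dominates the histogram), while the second cut
#' separates air from the darkest tissue, which is the boundary of the
#' background image (BGI) region.
#'
#' @param vol an [image_volume()] or numeric array.
#' @param levels number of recursive Otsu refinements (>= 1).
#' @return scalar threshold on the intensity scale of `vol`.
#' @export
otsu_threshold <- function(vol, levels = 1L) {
  x <- if (inherits(vol, "image_volume")) as.numeric(vol$data) else as.numeric(vol)
  t <- otsu_1d(x)
  while (levels > 1L) {
    x <- x[x < t]
    if (length(unique(x)) < 2) break
    t <- otsu_1d(x)
    levels <- levels - 1L
  }
  t
}

otsu_1d <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

# spatial hash over target points for radius queries
build_point_hash <- function(targets, cell) {
  lo <- apply(targets, 2, min) - 1e-9
  key <- floor(sweep(targets, 2, lo, "-") / cell)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  list(lo = lo, cell = cell, tab = split(seq_len(nrow(targets)), kstr))
}

radius_candidates <- function(hash, p) {
  cc <- floor((p - hash$lo) / hash$cell)
  keys <- as.character(outer(
    outer(paste(cc[1] + (-1:1)), paste(cc[2] + (-1:1)), paste),
    paste(cc[3] + (-1:1)), paste))
  unlist(hash$tab[keys], use.names = FALSE)
}

#' Fuzzy correspondence update (inner E-step)
#'
#' Gaussian soft assignment of each displaced source point to target
#' candidates within `candidate_radius`:
#' `c_ij \propto exp(-||s_i + (HU)_i - t_j||^2 / temperature^2)`, rows
#' normalized to 1. Sources with no candidate get an empty row.
#'
#' @param displaced n x 3 matrix of displaced source positions (mm).
#' @param targets m x 3 matrix of target points (mm).
#' @param cfg a [nemnrr_config()].
#' @return list(i, j, w) sparse row-normalized triplets, plus `barycenter`
#'   (n x 3, NA rows where empty).
#' @export
update_correspondence <- function(displaced, targets, cfg = nemnrr_config()) {
  displaced <- as_points(displaced); targets <- as_points(targets)
  n <- nrow(displaced)
  hash <- build_point_hash(targets, cfg$candidate_radius)
  ii <- vector("list", n); jj <- vector("list", n); ww <- vector("list", n)
  bary <- matrix(NA_real_, n, 3)
  r2max <- cfg$candidate_radius^2
  for (i in seq_len(n)) {
    cand <- radius_candidates(hash, displaced[i, ])
    if (is.null(cand) || !length(cand)) next
    d2 <- rowSums(sweep(targets[cand, , drop = FALSE], 2, displaced[i, ], "-")^2)
    keep <- d2 <= r2max
    if (!any(keep)) next
    cand <- cand[keep]; d2 <- d2[keep]
    w <- exp(-(d2 - min(d2)) / cfg$corr_temperature^2)
    w <- w / sum(w)
    ii[[i]] <- rep.int(i, length(cand)); jj[[i]] <- cand; ww[[i]] <- w
    bary[i, ] <- colSums(targets[cand, , drop = FALSE] * w)
  }
  list(i = unlist(ii), j = unlist(jj), w = unlist(ww), barycenter = bary)
}

#' Displacement update (inner M-step)
#'
#' Minimizes the strain-energy + correspondence terms in U with C and
#' M_Rem fixed: solves
#' `[K_{M \ M_Rem} + lambda1 H'WH] U = lambda1 H'W D(C)` where
#' `D(C)_i = sum_j c_ij t_j - s_i`.
#'
#' @param D_C n_src x 3 matrix of fuzzy target displacements (NA rows are
#'   excluded).
#' @param H sparse interpolation matrix over all source points.
#' @param K scaled stiffness matrix assembled on M \ M_Rem.
#' @param W per-source weights (default 1).
#' @param lambda1 data-term weight.
#' @param F optional length-3n stress-relaxation force (`K U_prev`), the
#'   same device as PBNRR's Eq.-3 relaxation: it makes the EM fixed point
#'   data-consistent instead of biased toward zero by the stiffness scale.
#' @return length-3n displacement vector U.
#' @export
update_displacement <- function(D_C, H, K, W = NULL, lambda1 = 1, F = NULL) {
  ok <- which(stats::complete.cases(D_C))
  if (length(ok) < 4) stop("update_displacement: too few correspondences")
  if (is.null(W)) W <- rep(1, nrow(D_C))
  r <- as.vector(rbind(3 * (ok - 1) + 1, 3 * (ok - 1) + 2, 3 * ok))
  solve_hybrid(K, H[r, , drop = FALSE], lambda1 * W[ok],
               interleave_disp(D_C[ok, , drop = FALSE]), F)
}

#' Evaluate the NEMNRR cost
#'
#' `J = sum_{e not in M_Rem} U' K_e U + lambda1 sum_i w_i ||(HU)_i - D(C)_i||^2
#'    + lambda2 sum_{e in M_Rem} V_e`, returned with the three terms.
#'
#' @param U length-3n displacement vector.
#' @param D_C n_src x 3 fuzzy displacements (NA rows excluded).
#' @param H interpolation matrix over all sources.
#' @param K_excl *unscaled* stiffness on M \ M_Rem.
#' @param mesh the [tet_mesh()].
#' @param m_rem integer tet ids in M_Rem.
#' @param W per-source weights.
#' @param lambda1,lambda2 trade-off weights.
#' @return list(J, strain, data, volume).
#' @export
eval_cost_J <- function(U, D_C, H, K_excl, mesh, m_rem = integer(0),
                        W = NULL, lambda1 = 1, lambda2 = 1) {
  strain <- as.numeric(U %*% (K_excl %*% U))
  ok <- which(stats::complete.cases(D_C))
  if (is.null(W)) W <- rep(1, nrow(D_C))
  data_term <- 0
  if (length(ok)) {
    r <- as.vector(rbind(3 * (ok - 1) + 1, 3 * (ok - 1) + 2, 3 * ok))
    res <- matrix(as.numeric(H[r, , drop = FALSE] %*% U) -
                  interleave_disp(D_C[ok, , drop = FALSE]), nrow = 3)
    data_term <- sum(W[ok] * colSums(res^2))
  }
  vol <- if (length(m_rem))
    sum(tet_signed_volumes(mesh$vertices, mesh$tets[m_rem, , drop = FALSE]))
  else 0
  list(J = strain + lambda1 * data_term + lambda2 * vol,
       strain = strain, data = lambda1 * data_term, volume = lambda2 * vol)
}

#' Tetrahedra whose displaced interior lands in background
#'
#' A tetrahedron falls in the background image (BGI) when most of its
#' displaced volume is dark, not when a single noisy sample is: the fixed
#' image is read at five interior sample points (the displaced centroid
#' plus four points pulled 55% toward each vertex, displaced by the
#' linear interpolant of U) and the element is a candidate when the
#' majority of samples lie below `bgi_threshold` (points outside the grid
#' sample as 0). The majority vote is robust to texture dips yet unbiased
#' at the cavity boundary, where an averaged intensity would erode the
#' detected region by half an element.
#'
#' @param mesh a [tet_mesh()].
#' @param U n_vert x 3 displacement matrix.
#' @param fixed the intra-operative [image_volume()].
#' @param bgi_threshold background intensity threshold.
#' @return integer vector of candidate tet ids.
#' @export
detect_background_tets <- function(mesh, U, fixed, bgi_threshold) {
  t4 <- mesh$tets
  acc <- 0
  # 15-point barycentric quadrature-style layout (centroid, near-vertex,
  # edge and face points) so the dark-volume fraction is estimated across
  # the whole element, not just its center
  perms4 <- function(w) unique(t(apply(
    as.matrix(expand.grid(rep(list(1:4), 4))), 1, function(ix) {
      if (length(unique(ix)) == 4) w[order(ix)] else rep(NA_real_, 4)
    })))
  wsets <- rbind(c(0.25, 0.25, 0.25, 0.25),
                 perms4(c(0.70, 0.10, 0.10, 0.10)),
                 perms4(c(0.40, 0.40, 0.10, 0.10)),
                 perms4(c(0.30, 0.30, 0.30, 0.10)))
  wsets <- wsets[stats::complete.cases(wsets), , drop = FALSE]
  for (r in seq_len(nrow(wsets))) {
    w <- wsets[r, ]
    p <- w[1] * mesh$vertices[t4[, 1], , drop = FALSE] +
         w[2] * mesh$vertices[t4[, 2], , drop = FALSE] +
         w[3] * mesh$vertices[t4[, 3], , drop = FALSE] +
         w[4] * mesh$vertices[t4[, 4], , drop = FALSE]
    up <- w[1] * U[t4[, 1], , drop = FALSE] + w[2] * U[t4[, 2], , drop = FALSE] +
          w[3] * U[t4[, 3], , drop = FALSE] + w[4] * U[t4[, 4], , drop = FALSE]
    # nearest-neighbour: trilinear blending at the cavity wall would read
    # half-tissue intensities and erode the detected region
    acc <- acc + (sample_nearest(fixed, p + up) < bgi_threshold)
  }
  which(2 * acc > nrow(wsets))
}

tet_face_adjacency <- function(tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  owner <- rep(seq_len(m), 4)
  pairs <- split(owner, key)
  pairs <- pairs[lengths(pairs) == 2]
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  matrix(unlist(pairs), ncol = 2, byrow = TRUE)
}

face_components <- function(members, adj) {
  # connected components of `members` under face adjacency (BFS)
  in_set <- logical(max(c(adj, members, 1L)))
  in_set[members] <- TRUE
  nbr <- vector("list", length(in_set))
  keep <- in_set[adj[, 1]] & in_set[adj[, 2]]
  a <- adj[keep, , drop = FALSE]
  for (r in seq_len(nrow(a))) {
    nbr[[a[r, 1]]] <- c(nbr[[a[r, 1]]], a[r, 2])
    nbr[[a[r, 2]]] <- c(nbr[[a[r, 2]]], a[r, 1])
  }
  seen <- logical(length(in_set))
  comps <- list()
  for (s in members) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      comp <- c(comp, x)
      for (y in nbr[[x]]) if (!seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Grow the resection submesh
#'
#' Empty `current`: seed with the largest face-connected component of
#' `candidates`, provided its volume reaches `min_seed_volume`. Otherwise
#' add every candidate connected (transitively, through candidates) to
#' the current submesh. Growth is monotone and the result stays a single
#' face-connected component.
#'
#' @param current integer tet ids currently in M_Rem.
#' @param candidates integer candidate tet ids.
#' @param mesh a [tet_mesh()].
#' @param adj optional precomputed face-adjacency pair matrix.
#' @param min_seed_volume mm^3 threshold for seeding (see
#'   [nemnrr_config()]).
#' @return integer tet ids of the grown M_Rem.
#' @export
grow_resection <- function(current, candidates, mesh, adj = NULL,
                           min_seed_volume = 0) {
  candidates <- sort(unique(as.integer(candidates)))
  current <- sort(unique(as.integer(current)))
  if (!length(candidates)) return(current)
  if (is.null(adj)) adj <- tet_face_adjacency(mesh$tets)
  if (!length(current)) {
    comps <- face_components(candidates, adj)
    sizes <- lengths(comps)
    best <- comps[[which.max(sizes)]]   # first maximal component: determinism
    vol <- sum(tet_signed_volumes(mesh$vertices,
                                  mesh$tets[best, , drop = FALSE]))
    if (vol < min_seed_volume) return(current)
    return(best)
  }
  comps <- face_components(union(current, candidates), adj)
  touches <- vapply(comps, function(cp) any(cp %in% current), logical(1))
  sort(unique(unlist(comps[touches])))
}

#' Nested-EM registration with resection-cavity recovery
#'
#' Outer loop over M_Rem: inner EM alternates [update_correspondence()]
#' (fuzzy assignment of displaced registration points to fixed-image Canny
#' edge points) and [update_displacement()] until the vertex displacements
#' settle; then background tetrahedra are detected under the current
#' deformation and M_Rem grows by face-connectivity. Stops when M_Rem
#' stops growing.
#'
#' @inheritParams pbnrr_register
#' @param cfg a [nemnrr_config()].
#' @param match_cfg a [block_match_config()]; block matching provides the
#'   source points, their confidence weights W, and the initial
#'   displacement estimate the nested EM refines.
#' @param matches optional precomputed [sparse_field()].
#' @param targets optional m x 3 target points (defaults to
#'   [canny_edge_points()] on the fixed image at anatomical scale).
#' @return a `registration_result` with extra elements `m_rem` (tet ids),
#'   `m_rem_history`, `correspondence`, and `cost_history`.
#' @export
nemnrr_register <- function(floating, fixed, mesh,
                            materials = material_table(),
                            feature_cfg = feature_config(),
                            match_cfg = block_match_config(),
                            cfg = nemnrr_config(),
                            matches = NULL, targets = NULL) {
  if (is.null(matches)) {
    pts <- select_registration_points(floating, feature_cfg)
    matches <- block_match_all(floating, fixed, pts, match_cfg)
  }
  if (is.null(targets))
    targets <- canny_edge_points(fixed)
  if (!nrow(targets)) stop("nemnrr_register: no target edge points detected")
  bgi <- if (is.null(cfg$bgi_threshold)) otsu_threshold(fixed, levels = 2L)
         else cfg$bgi_threshold

  bi <- build_interpolation(mesh, matches$points)
  located <- which(!is.na(bi$located))
  if (length(located) < 12) stop("nemnrr_register: fewer than 12 located sources")
  matches <- sparse_field(matches$points[located, , drop = FALSE],
                          matches$displacements[located, , drop = FALSE],
                          matches$confidences[located])
  sources <- matches$points
  bi <- build_interpolation(mesh, sources, bi$hash)
  H <- bi$H
  n_src <- nrow(sources)
  W <- matches$confidences

  K0_full <- assemble_stiffness(mesh, materials)
  k_scale <- cfg$k_scale
  if (identical(k_scale, "auto")) {
    tr_match <- cfg$lambda1 * sum(rep(W, each = 3) * Matrix::rowSums(H^2))
    tr_K <- sum(Matrix::diag(K0_full))
    # the EM itself runs with the strain and correspondence terms
    # comparable (trace-balanced); only the initialization solve is stiff
    k_scale <- if (tr_K > 0 && tr_match > 0) tr_match / tr_K else 1
  }

  adj <- tet_face_adjacency(mesh$tets)
  m_rem <- integer(0)
  m_rem_history <- list()
  cost_history <- list()
  # initialize from the block-matching displacements with a stiff
  # approximation solve (outliers averaged away elastically); the inner
  # EM then refines correspondence and deformation around it
  U <- solve_hybrid(100 * k_scale * K0_full, H, W,
                    interleave_disp(matches$displacements))
  C <- NULL

  for (outer in seq_len(cfg$outer_max)) {
    K_raw <- assemble_stiffness(mesh, materials, exclude = m_rem)
    K <- k_scale * K_raw
    for (inner in seq_len(cfg$inner_max)) {
      HU <- matrix(as.numeric(H %*% U), ncol = 3, byrow = TRUE)
      C <- update_correspondence(sources + HU, targets, cfg)
      D_C <- C$barycenter - sources
      U_new <- update_displacement(D_C, H, K, W, cfg$lambda1)
      cost_history[[length(cost_history) + 1]] <- c(
        outer = outer, inner = inner,
        J = eval_cost_J(U_new, D_C, H, K, mesh, m_rem, W,
                        cfg$lambda1, cfg$lambda2)$J)
      delta <- max(abs(U_new - U))
      U <- U_new
      if (delta < cfg$inner_tol) break
    }
    Umat <- matrix(U, ncol = 3, byrow = TRUE)
    cand <- detect_background_tets(mesh, Umat, fixed, bgi)
    grown <- grow_resection(m_rem, cand, mesh, adj, cfg$min_seed_volume)
    m_rem_history[[outer]] <- grown
    if (length(grown) == length(m_rem)) break
    m_rem <- grown
  }

  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  fwd <- rasterize_mesh_field(mesh, Umat, fixed)
  structure(list(U = Umat, active_matches = seq_len(n_src),
                 rejected_matches = integer(0),
                 m_rem = m_rem, m_rem_history = m_rem_history,
                 correspondence = C,
                 cost_history = do.call(rbind, cost_history),
                 mesh = mesh, k_scale = k_scale, converged = TRUE,
                 forward_field = fwd,
                 dense_field = invert_field(fwd)),
            class = "registration_result")
}
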