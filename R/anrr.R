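# Adaptive non-rigid registration: incremental warping with remeshing to
# avoid geometric element outliers (slivers / inverted tets), plus the
# registration-point-aware isotropic and anisotropic mesh sizing metrics
# (k-th-closest-point spacing; minimum-volume enclosing ellipsoids of
# reflected neighbours with an inflation constant).

#' ANRR configuration
#'
#' @param n_inc number of deformation increments (>= 1).
#' @param sliver_dihedral_deg minimum acceptable dihedral angle (degrees).
#' @param k neighbour count for the sizing metrics.
#' @param inflation ellipsoid enlargement constant a (>= 1).
#' @param edge_length BCC lattice edge length (mm) per increment.
#' @param max_remesh retries with a finer lattice when quality fails.
#' @param pbnrr inner [pbnrr_config()] per increment.
#' @param feature_cfg,match_cfg inner feature/matching configs.
#' @return an `anrr_config` list.
#' @export
anrr_config <- function(n_inc = 5L, sliver_dihedral_deg = 5, k = 5L,
                        inflation = 1.2, edge_length = 6,
                        max_remesh = 2L,
                        pbnrr = pbnrr_config(),
                        feature_cfg = feature_config(),
                        match_cfg = block_match_config()) {
  if (n_inc < 1) stop("anrr_config: n_inc must be >= 1")
  if (k < 1) stop("anrr_config: k must be >= 1")
  if (inflation < 1) stop("anrr_config: inflation must be >= 1")
  structure(list(n_inc = as.integer(n_inc),
                 sliver_dihedral_deg = sliver_dihedral_deg,
                 k = as.integer(k), inflation = inflation,
                 edge_length = edge_length, max_remesh = as.integer(max_remesh),
                 pbnrr = pbnrr, feature_cfg = feature_cfg,
                 match_cfg = match_cfg),
            class = "anrr_config")
}

#' Signed volume and minimum dihedral angle of a tetrahedron
#'
#' The dihedral at an edge is the angle between the in-face directions
#' perpendicular to that edge; a regular tetrahedron has
#' `acos(1/3) = 70.53` degrees at all six edges.
#'
#' @param verts 4 x 3 vertex matrix (mm).
#' @return list(volume mm^3 signed, min_dihedral_deg).
#' @export
element_quality <- function(verts) {
  verts <- as_points(verts)
  vol <- tet_signed_volumes(verts, matrix(1:4, 1))
  edges <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3),
                 c(2, 3, 1, 4), c(2, 4, 1, 3), c(3, 4, 1, 2))
  angs <- apply(edges, 1, function(e) {
    a <- verts[e[1], ]; b <- verts[e[2], ]
    c1 <- verts[e[3], ]; d1 <- verts[e[4], ]
    ab <- b - a; ab <- ab / sqrt(sum(ab^2))
    t1 <- (c1 - a) - sum((c1 - a) * ab) * ab
    t2 <- (d1 - a) - sum((d1 - a) * ab) * ab
    cosang <- sum(t1 * t2) / sqrt(sum(t1^2) * sum(t2^2))
    acos(max(-1, min(1, cosang))) * 180 / pi
  })
  list(volume = as.numeric(vol), min_dihedral_deg = min(angs))
}

#' Correct a warped segmentation
#'
#' Nearest-neighbour warping leaves ragged single-voxel protrusions on the
#' label boundary; meshed, these become poorly constrained appendages that
#' destabilize the FEM solve. A 6-neighbourhood majority filter removes
#' foreground voxels with fewer than 3 foreground face-neighbours.
#'
#' @param labels a [label_volume()].
#' @return the cleaned [label_volume()].
#' @export
correct_segmentation <- function(labels) {
  fg <- (labels$data > 0) * 1
  nb <- shift_array(fg, 1L, 1L) + shift_array(fg, -1L, 1L) +
        shift_array(fg, 1L, 2L) + shift_array(fg, -1L, 2L) +
        shift_array(fg, 1L, 3L) + shift_array(fg, -1L, 3L)
  out <- labels$data
  out[fg > 0 & nb < 3] <- 0L
  label_volume(out, labels$spacing, labels$origin)
}

mesh_quality_ok <- function(vertices, tets, min_dihedral) {
  vols <- tet_signed_volumes(vertices, tets)
  if (any(vols <= 0)) return(FALSE)
  for (e in seq_len(nrow(tets))) {
    q <- element_quality(vertices[tets[e, ], ])
    if (q$min_dihedral_deg < min_dihedral) return(FALSE)
  }
  TRUE
}

#' Adaptive incremental registration
#'
#' Splits the deformation into `n_inc` increments. Each increment meshes
#' the current warped segmentation with the BCC mesher, runs one PBNRR
#' pass against the fixed image, accepts `1/(remaining increments)` of the
#' solved field, verifies the deformed mesh contains no inverted or sliver
#' elements (remeshing with a finer lattice otherwise), and composes the
#' accepted field into the cumulative pull field used to warp the image
#' and labels for the next increment.
#'
#' @param floating,fixed [image_volume()]s.
#' @param labels [label_volume()] segmenting the floating image.
#' @param materials a [material_table()].
#' @param cfg an [anrr_config()].
#' @return a `registration_result` with extra elements `increments`
#'   (per-increment diagnostics) and `final_mesh`.
#' @export
anrr_register <- function(floating, fixed, labels,
                          materials = material_table(),
                          cfg = anrr_config()) {
  cum <- zero_field(fixed)
  cur_pre <- floating
  cur_labels <- labels
  inc_diag <- list()
  mesh <- NULL
  for (i in seq_len(cfg$n_inc)) {
    h <- cfg$edge_length
    ok <- FALSE
    for (try in 0:cfg$max_remesh) {
      mesh <- bcc_mesh_from_labels(cur_labels, h)
      res <- pbnrr_register(cur_pre, fixed, mesh, materials,
                            cfg$feature_cfg, cfg$match_cfg, cfg$pbnrr,
                            dense = FALSE)
      # block matching cannot measure beyond the search window, so vertex
      # displacements past the window extent are interpolation artifacts;
      # cap them before accepting any of the field
      cap <- max(cfg$match_cfg$window_radius * fixed$spacing)
      umag <- sqrt(rowSums(res$U^2))
      scale <- pmin(1, cap / pmax(umag, 1e-12))
      U_inc <- res$U * scale
      # keeping the per-increment deformation small relative to the
      # elements is the point of incremental warping: accept less of the
      # field before resorting to a finer lattice
      for (damp in c(1, 0.5, 0.25)) {
        frac <- damp / (cfg$n_inc - i + 1)
        U_acc <- frac * U_inc
        if (mesh_quality_ok(mesh$vertices + U_acc, mesh$tets,
                            cfg$sliver_dihedral_deg)) { ok <- TRUE; break }
      }
      if (ok) break
      h <- h * 0.75
    }
    if (!ok)
      stop("anrr_register: element quality failure persisted after ",
           cfg$max_remesh, " remeshes at increment ", i)
    fwd_i <- rasterize_mesh_field(mesh, U_acc, fixed)
    pull_i <- invert_field(fwd_i)
    cum <- compose_fields(cum, pull_i)
    cur_pre <- warp_image(floating, cum)
    cur_labels <- correct_segmentation(warp_image(labels, cum))
    inc_diag[[i]] <- data.frame(
      increment = i, edge_length = h, n_tets = nrow(mesh$tets),
      accepted_fraction = frac,
      max_u = sqrt(max(rowSums(U_acc^2))),
      active = length(res$active_matches),
      rejected = length(res$rejected_matches))
  }
  fwd_total <- invert_field(cum)
  U_final <- sample_trilinear(fwd_total, mesh$vertices)
  structure(list(U = U_final, active_matches = res$active_matches,
                 rejected_matches = res$rejected_matches,
                 iterations = res$iterations,
                 increments = do.call(rbind, inc_diag),
                 mesh = mesh, final_mesh = mesh,
                 k_scale = res$k_scale, converged = res$converged,
                 forward_field = fwd_total,
                 dense_field = cum),
            class = "registration_result")
}

# --- sizing metrics ---------------------------------------------------------

knn_distances <- function(query, points, k, chunk = 512L) {
  n <- nrow(query)
  out <- matrix(NA_real_, n, k)
  idx <- matrix(NA_integer_, n, k)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(points))) +
          outer(rep(1, nrow(q)), rowSums(points^2)) -
          2 * q %*% t(points)
    for (r in seq_len(nrow(q))) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[s + r - 1, ] <- o
      out[s + r - 1, ] <- sqrt(pmax(d2[r, o], 0))
    }
  }
  list(dist = out, index = idx)
}

#' Isotropic sizing field
#'
#' Sets the local spacing at each mesh vertex to the Euclidean distance to
#' its k-th closest registration point, so an ideally conforming mesh puts
#' about k registration points in each vertex cell complex.
#'
#' @param vertices n x 3 mesh vertex matrix (mm).
#' @param reg_points m x 3 registration points (m >= k).
#' @param k neighbour rank.
#' @param eps lower clamp for coincident points.
#' @return a `sizing_field` list with `type = "scalar"` and `values`
#'   (length n, mm).
#' @export
isotropic_sizing <- function(vertices, reg_points, k, eps = 1e-6) {
  vertices <- as_points(vertices); reg_points <- as_points(reg_points)
  if (nrow(reg_points) < k)
    stop("isotropic_sizing: need at least k registration points")
  nn <- knn_distances(vertices, reg_points, k)
  structure(list(type = "scalar", values = pmax(nn$dist[, k], eps)),
            class = "sizing_field")
}

#' Minimum-volume enclosing ellipsoid (Khachiyan algorithm)
#'
#' Iterates Khachiyan's barycentric coordinate ascent until
#' `max_j (p_j - c)' A (p_j - c) <= 1 + tol`. The ellipsoid is
#' `{x : (x - c)' A (x - c) <= 1}` with SPD shape matrix A.
#'
#' @param points n x 3 matrix, n >= 4 affinely independent rows.
#' @param tol Khachiyan tolerance (default 1e-4).
#' @param max_iter iteration cap (default 10000).
#' @return list(center, A).
#' @export
min_enclosing_ellipsoid <- function(points, tol = 1e-4, max_iter = 10000L) {
  P <- t(as_points(points))          # 3 x n
  n <- ncol(P); d <- 3
  if (n < d + 1) stop("min_enclosing_ellipsoid: need >= 4 points")
  Q <- rbind(P, 1)
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    Xi <- tryCatch(solve(X), error = function(e)
      stop("min_enclosing_ellipsoid: degenerate (non-spanning) input"))
    M <- colSums(Q * (Xi %*% Q))
    j <- which.max(M)
    maxM <- M[j]
    if (maxM <= (d + 1) * (1 + tol)) break
    step <- (maxM - d - 1) / ((d + 1) * (maxM - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- as.numeric(P %*% u)
  S <- P %*% (u * t(P)) - tcrossprod(c0)
  A <- tryCatch(solve(S) / d, error = function(e)
    stop("min_enclosing_ellipsoid: degenerate (coplanar) input"))
  list(center = c0, A = (A + t(A)) / 2)
}

central_mvee <- function(points0, tol = 1e-6, max_iter = 10000L) {
  P <- t(as_points(points0))   # 3 x n, centered at the origin
  n <- ncol(P); d <- 3
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- P %*% (u * t(P))
    Xi <- solve(X)
    M <- colSums(P * (Xi %*% P))
    j <- which.max(M)
    if (M[j] <= d * (1 + tol)) break
    step <- (M[j] - d) / (d * (M[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  A <- solve(P %*% (u * t(P))) / d
  (A + t(A)) / 2
}

#' Anisotropic sizing metric at one vertex
#'
#' Reflects the k nearest registration points through the vertex, encloses
#' the 2k points in a minimum-volume ellipsoid (centered at the vertex by
#' symmetry), inflates every semi-axis by the constant `a`, and returns
#' the SPD metric tensor of the inflated ellipsoid. Degenerate neighbour
#' configurations fall back to the isotropic spacing (recorded).
#'
#' @param vertex length-3 mm point.
#' @param reg_points m x 3 registration points (m >= k).
#' @param k neighbour count.
#' @param a inflation constant (>= 1); semi-axes scale exactly by `a`.
#' @param tol Khachiyan tolerance.
#' @return list(center, A, fallback).
#' @export
anisotropic_metric <- function(vertex, reg_points, k, a = 1.0, tol = 1e-6) {
  vertex <- as.numeric(vertex)
  reg_points <- as_points(reg_points)
  if (nrow(reg_points) < k)
    stop("anisotropic_metric: need at least k registration points")
  nn <- knn_distances(matrix(vertex, 1), reg_points, k)
  nbrs <- reg_points[nn$index[1, ], , drop = FALSE]
  refl <- sweep(-nbrs, 2, 2 * vertex, "+")
  # the reflected set is centrally symmetric about the vertex, so its MVEE
  # is centered there; solve the origin-centered Khachiyan variant exactly
  A <- tryCatch(central_mvee(rbind(nbrs, refl) -
                               matrix(vertex, 2 * k, 3, byrow = TRUE), tol),
                error = function(e) NULL)
  if (is.null(A)) {
    r <- max(nn$dist[1, k], 1e-6)
    return(list(center = vertex, A = diag(3) / (a * r)^2, fallback = TRUE))
  }
  list(center = vertex, A = A / a^2, fallback = FALSE)
}

#' Anisotropic sizing field over a mesh
#'
#' [anisotropic_metric()] at every mesh vertex; vertices with degenerate
#' neighbourhoods fall back to isotropic spacing and are listed in
#' `fallback_vertices`.
#'
#' @param mesh a [tet_mesh()].
#' @param reg_points registration points.
#' @inheritParams anisotropic_metric
#' @return a `sizing_field` with `type = "tensor"`, `values` (n x 6 rows
#'   xx, xy, yy, xz, yz, zz), and `fallback_vertices`.
#' @export
anisotropic_sizing <- function(mesh, reg_points, k, a = 1.0) {
  nv <- nrow(mesh$vertices)
  vals <- matrix(NA_real_, nv, 6)
  fb <- logical(nv)
  for (v in seq_len(nv)) {
    m <- anisotropic_metric(mesh$vertices[v, ], reg_points, k, a)
    A <- m$A
    vals[v, ] <- c(A[1, 1], A[1, 2], A[2, 2], A[1, 3], A[2, 3], A[3, 3])
    fb[v] <- m$fallback
  }
  structure(list(type = "tensor", values = vals,
                 fallback_vertices = which(fb)),
            class = "sizing_field")
}

sizing_spd_ok <- function(row6) {
  A <- matrix(c(row6[1], row6[2], row6[4],
                row6[2], row6[3], row6[5],
                row6[4], row6[5], row6[6]), 3, 3)
  all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0)
}

#' Export / read a per-vertex metric field (MEDIT .sol dialect)
#'
#' Scalar spacings as `SolAtVertices` type 1; symmetric tensors as type 3
#' with rows `xx xy yy xz yz zz`, consumable by external anisotropic
#' meshers. Non-SPD tensors are refused at write time.
#'
#' @param mesh the [tet_mesh()] the field lives on.
#' @param field a `sizing_field`.
#' @param path output file path.
#' @return [read_metric_field()] returns a `sizing_field`.
#' @export
export_metric_field <- function(mesh, field, path) {
  nv <- nrow(mesh$vertices)
  if (field$type == "scalar") {
    if (length(field$values) != nv)
      stop("export_metric_field: field/mesh size mismatch")
    if (any(field$values <= 0))
      stop("export_metric_field: non-positive scalar spacing")
    body <- format(field$values, digits = 17, trim = TRUE, scientific = FALSE)
    kind <- "1 1"
  } else {
    if (nrow(field$values) != nv)
      stop("export_metric_field: field/mesh size mismatch")
    for (r in seq_len(nv))
      if (!sizing_spd_ok(field$values[r, ]))
        stop("export_metric_field: non-SPD tensor at vertex ", r)
    body <- apply(format(field$values, digits = 17, trim = TRUE,
                         scientific = FALSE), 1, paste, collapse = " ")
    kind <- "1 3"
  }
  writeLines(c("MeshVersionFormatted 2", "Dimension 3", "",
               "SolAtVertices", as.character(nv), kind, body, "", "End"),
             path)
  invisible(path)
}

#' @rdname export_metric_field
#' @export
read_metric_field <- function(path) {
  if (!file.exists(path)) stop("cannot read metric field: no such file: ", path)
  lines <- readLines(path)
  i <- match("SolAtVertices", lines)
  if (is.na(i)) stop("metric field parse error: missing SolAtVertices in ", path)
  nv <- as.integer(lines[i + 1])
  kind <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
  vals <- lines[(i + 3):(i + 2 + nv)]
  if (kind[2] == "1") {
    structure(list(type = "scalar", values = as.numeric(vals)),
              class = "sizing_field")
  } else {
    m <- do.call(rbind, lapply(strsplit(trimws(vals), "\\s+"), as.numeric))
    structure(list(type = "tensor", values = m), class = "sizing_field")
  }
}

#' Registration points per vertex cell complex
#'
#' Counts, for every mesh vertex, the located registration points falling
#' in the union of its incident tetrahedra — the equidistribution unit of
#' the isotropic sizing construction.
#'
#' @param mesh a [tet_mesh()].
#' @param points registration points (mm).
#' @return integer vector, one count per vertex.
#' @export
vertex_cell_counts <- function(mesh, points) {
  loc <- locate_points(mesh, as_points(points))
  counts <- integer(nrow(mesh$vertices))
  ok <- which(!is.na(loc$tet))
  if (!length(ok)) return(counts)
  tet_pts <- table(loc$tet[ok])
  for (nm in names(tet_pts)) {
    vids <- mesh$tets[as.integer(nm), ]
    counts[vids] <- counts[vids] + tet_pts[[nm]]
  }
  counts
}
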