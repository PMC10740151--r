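# Linear tetrahedral (P1) elasticity: BCC image-to-mesh conversion,
# element/global stiffness assembly, and barycentric match-to-vertex
# interpolation. Units: mm for geometry, Pa for Young's modulus; the
# absolute stiffness scale is balanced against the match weights by the
# solver's k_scale (see solve_hybrid).

#' Material table
#'
#' Tissue label to isotropic linear-elastic parameters. The defaults follow
#' the two-tissue brain model: parenchyma (and tumor) E = 3000 Pa,
#' nu = 0.45; ventricle E = 10 Pa, nu = 0.1.
#'
#' @param labels integer tissue labels.
#' @param E Young's moduli (Pa), one per label.
#' @param nu Poisson ratios in `[0, 0.5)`, one per label.
#' @return a `material_table` data frame.
#' @export
material_table <- function(labels = c(1L, 2L, 3L),
                           E = c(3000, 10, 3000),
                           nu = c(0.45, 0.1, 0.45)) {
  if (any(E <= 0)) stop("material_table: E must be > 0")
  if (any(nu < 0 | nu >= 0.5)) stop("material_table: nu must be in [0, 0.5)")
  structure(data.frame(label = as.integer(labels), E = E, nu = nu),
            class = c("material_table", "data.frame"))
}

#' Body-centered-cubic tetrahedral mesh from a label volume
#'
#' Lays a BCC lattice of edge length `edge_length` over the bounding box of
#' the non-background labels (plus one cell of padding), splits each pair of
#' adjacent cell centers into 4 tetrahedra through their shared face, and
#' keeps the tetrahedra whose centroid falls on a non-background label.
#' Element labels are the centroid labels. With `connected = TRUE` (the
#' default) only the largest face-connected component is kept: the brain
#' is one body, and stray components (e.g. speckle in a warped
#' segmentation) would contribute unconstrained rigid modes to the FEM
#' operator.
#'
#' @param labels a [label_volume()].
#' @param edge_length lattice cell size in mm.
#' @param connected keep only the largest face-connected component.
#' @return a [tet_mesh()].
#' @export
bcc_mesh_from_labels <- function(labels, edge_length, connected = TRUE) {
  fg <- which(labels$data > 0)
  if (!length(fg)) stop("bcc_mesh_from_labels: empty foreground")
  dm <- dim(labels$data)
  fg0 <- fg - 1L
  idx <- cbind(fg0 %% dm[1], (fg0 %/% dm[1]) %% dm[2], fg0 %/% (dm[1] * dm[2]))
  w <- voxel_to_world(idx, labels)
  h <- edge_length
  lo <- apply(w, 2, min) - h
  hi <- apply(w, 2, max) + h
  nc <- pmax(1L, ceiling((hi - lo) / h))       # cells per axis
  np <- nc + 1L                                # corner points per axis
  corner_id <- function(i, j, k) 1L + i + np[1] * (j + np[2] * k)
  n_corner <- prod(np)
  center_id <- function(i, j, k) n_corner + 1L + i + nc[1] * (j + nc[2] * k)

  ci <- expand.grid(i = 0:(np[1] - 1), j = 0:(np[2] - 1), k = 0:(np[3] - 1))
  corners <- sweep(as.matrix(ci) * h, 2, lo, "+")
  li <- expand.grid(i = 0:(nc[1] - 1), j = 0:(nc[2] - 1), k = 0:(nc[3] - 1))
  centers <- sweep((as.matrix(li) + 0.5) * h, 2, lo, "+")
  verts <- rbind(corners, centers)

  tets <- vector("list", 3)
  for (axis in 1:3) {
    # faces between cells adjacent along `axis`
    rng <- list(0:(nc[1] - 1), 0:(nc[2] - 1), 0:(nc[3] - 1))
    rng[[axis]] <- 0:(nc[axis] - 2)
    if (length(rng[[axis]]) < 1) next
    g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
    c1 <- center_id(g$i, g$j, g$k)
    step <- c(0L, 0L, 0L); step[axis] <- 1L
    c2 <- center_id(g$i + step[1], g$j + step[2], g$k + step[3])
    # shared face corners, cyclic order; face lies at cell index +1 on axis
    o <- cbind(g$i, g$j, g$k); o[, axis] <- o[, axis] + 1L
    ax1 <- (axis %% 3) + 1L; ax2 <- (ax1 %% 3) + 1L
    fc <- vector("list", 4)
    offs <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
    for (t in 1:4) {
      oo <- o
      oo[, ax1] <- oo[, ax1] + offs[[t]][1]
      oo[, ax2] <- oo[, ax2] + offs[[t]][2]
      fc[[t]] <- corner_id(oo[, 1], oo[, 2], oo[, 3])
    }
    tets[[axis]] <- rbind(cbind(c1, c2, fc[[1]], fc[[2]]),
                          cbind(c1, c2, fc[[2]], fc[[3]]),
                          cbind(c1, c2, fc[[3]], fc[[4]]),
                          cbind(c1, c2, fc[[4]], fc[[1]]))
  }
  tets <- do.call(rbind, tets)
  cent <- (verts[tets[, 1], ] + verts[tets[, 2], ] +
           verts[tets[, 3], ] + verts[tets[, 4], ]) / 4
  lab <- sample_nearest(labels, cent, background = 0)
  keep <- lab > 0
  if (!any(keep)) stop("bcc_mesh_from_labels: no tetrahedron centroid on foreground")
  tets <- tets[keep, , drop = FALSE]
  lab <- as.integer(lab[keep])
  if (connected && nrow(tets) > 1) {
    comps <- face_components(seq_len(nrow(tets)), tet_face_adjacency(tets))
    main <- comps[[which.max(lengths(comps))]]
    tets <- tets[main, , drop = FALSE]
    lab <- lab[main]
  }
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  tet_mesh(verts[used, , drop = FALSE],
           matrix(remap[tets], ncol = 4), lab)
}

isotropic_elasticity_C <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' `K_e = V_e * t(B) %*% C %*% B` with the constant strain-displacement
#' operator B of P1 shape functions and the isotropic elasticity matrix
#' C(E, nu) in engineering (Voigt) notation. Symmetric positive
#' semidefinite with a 6-dimensional rigid-body null space.
#'
#' @param verts 4 x 3 matrix of vertex coordinates (mm), positive volume.
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @return 12 x 12 matrix (dof order x1 y1 z1 x2 ...).
#' @export
element_stiffness <- function(verts, E, nu) {
  verts <- as_points(verts)
  Jm <- t(verts[2:4, , drop = FALSE]) -
        matrix(verts[1, ], 3, 3)        # columns x2-x1, x3-x1, x4-x1
  V <- det(Jm) / 6
  if (V <= 0) stop("element_stiffness: degenerate tet (volume <= 0)")
  g234 <- solve(Jm)                      # rows: grad lambda_2..4
  grads <- rbind(-colSums(g234), g234)   # 4 x 3
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    bx <- grads[i, 1]; by <- grads[i, 2]; bz <- grads[i, 3]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  V * t(B) %*% isotropic_elasticity_C(E, nu) %*% B
}

#' Assemble the global stiffness matrix
#'
#' Sums element stiffness matrices scattered to global vertex dofs,
#' skipping elements in `exclude` (the resection submesh M_Rem).
#'
#' @param mesh a [tet_mesh()].
#' @param materials a [material_table()] covering every tet label.
#' @param exclude integer vector of tet ids to skip.
#' @return sparse symmetric `3n x 3n` [Matrix::Matrix].
#' @export
assemble_stiffness <- function(mesh, materials = material_table(),
                               exclude = integer(0)) {
  missing_lab <- setdiff(unique(mesh$tet_labels), materials$label)
  if (length(missing_lab))
    stop("assemble_stiffness: no material for label(s) ",
         paste(missing_lab, collapse = ", "))
  n <- nrow(mesh$vertices)
  active <- setdiff(seq_len(nrow(mesh$tets)), exclude)
  if (!length(active))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(3 * n, 3 * n)))
  nt <- length(active)
  ii <- integer(144 * nt); jj <- integer(144 * nt); xx <- numeric(144 * nt)
  pos <- 0L
  Elut <- materials$E[match(mesh$tet_labels, materials$label)]
  nulut <- materials$nu[match(mesh$tet_labels, materials$label)]
  for (e in active) {
    vid <- mesh$tets[e, ]
    Ke <- element_stiffness(mesh$vertices[vid, ], Elut[e], nulut[e])
    dof <- as.vector(rbind(3 * (vid - 1) + 1, 3 * (vid - 1) + 2, 3 * vid))
    ii[pos + 1:144] <- rep(dof, times = 12)
    jj[pos + 1:144] <- rep(dof, each = 12)
    xx[pos + 1:144] <- as.vector(Ke)
    pos <- pos + 144L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n, 3 * n))
}

# --- point location ---------------------------------------------------------

build_tet_hash <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  m <- nrow(t4)
  bmin <- pmin(v[t4[, 1], ], v[t4[, 2], ], v[t4[, 3], ], v[t4[, 4], ])
  bmax <- pmax(v[t4[, 1], ], v[t4[, 2], ], v[t4[, 3], ], v[t4[, 4], ])
  bmin <- matrix(bmin, m, 3); bmax <- matrix(bmax, m, 3)
  cell <- max(stats::median(bmax[, 1] - bmin[, 1]),
              stats::median(bmax[, 2] - bmin[, 2]),
              stats::median(bmax[, 3] - bmin[, 3]), 1e-6)
  lo <- apply(v, 2, min) - 1e-9
  dims <- pmax(1L, as.integer(ceiling((apply(v, 2, max) - lo) / cell)) + 1L)
  key <- function(c3) 1 + c3[, 1] + dims[1] * (c3[, 2] + dims[2] * c3[, 3])
  # tets can span several cells; enumerate covered cell ranges
  cmin <- matrix(pmax(0L, as.integer(floor(sweep(bmin, 2, lo, "-") / cell))), m, 3)
  cmax <- matrix(pmin(rep(dims - 1L, each = m),
                      as.integer(floor(sweep(bmax, 2, lo, "-") / cell))), m, 3)
  keys <- vector("list", m)
  for (e in seq_len(m)) {
    g <- expand.grid(i = cmin[e, 1]:cmax[e, 1], j = cmin[e, 2]:cmax[e, 2],
                     k = cmin[e, 3]:cmax[e, 3])
    keys[[e]] <- key(as.matrix(g))
  }
  lens <- lengths(keys)
  tab <- split(rep(seq_len(m), lens), unlist(keys))
  # per-tet barycentric solve data
  x1 <- v[t4[, 1], , drop = FALSE]
  Tinv <- matrix(0, m, 9)
  for (e in seq_len(m)) {
    Jm <- t(v[t4[e, 2:4], , drop = FALSE]) - matrix(x1[e, ], 3, 3)
    Tinv[e, ] <- as.vector(solve(Jm))
  }
  list(cell = cell, lo = lo, dims = dims, tab = tab, x1 = x1, Tinv = Tinv)
}

locate_points <- function(mesh, pts, hash = NULL, tol = 1e-9) {
  pts <- as_points(pts)
  if (is.null(hash)) hash <- build_tet_hash(mesh)
  n <- nrow(pts)
  cc <- floor(sweep(pts, 2, hash$lo, "-") / hash$cell)
  inside_grid <- cc[, 1] >= 0 & cc[, 1] < hash$dims[1] &
                 cc[, 2] >= 0 & cc[, 2] < hash$dims[2] &
                 cc[, 3] >= 0 & cc[, 3] < hash$dims[3]
  keyv <- rep(NA_character_, n)
  keyv[inside_grid] <- as.character(
    1 + cc[inside_grid, 1] +
      hash$dims[1] * (cc[inside_grid, 2] + hash$dims[2] * cc[inside_grid, 3]))
  cand <- hash$tab[keyv]
  lens <- vapply(cand, function(x) if (is.null(x)) 0L else length(x), integer(1))
  tet_of <- rep(NA_integer_, n)
  bary <- matrix(NA_real_, n, 4)
  if (sum(lens) == 0) return(list(tet = tet_of, bary = bary, hash = hash))
  pidx <- rep(seq_len(n), lens)
  tidx <- unlist(cand[lens > 0], use.names = FALSE)
  d <- pts[pidx, , drop = FALSE] - hash$x1[tidx, , drop = FALSE]
  Ti <- hash$Tinv[tidx, , drop = FALSE]
  l2 <- Ti[, 1] * d[, 1] + Ti[, 4] * d[, 2] + Ti[, 7] * d[, 3]
  l3 <- Ti[, 2] * d[, 1] + Ti[, 5] * d[, 2] + Ti[, 8] * d[, 3]
  l4 <- Ti[, 3] * d[, 1] + Ti[, 6] * d[, 2] + Ti[, 9] * d[, 3]
  l1 <- 1 - l2 - l3 - l4
  contained <- l1 >= -tol & l2 >= -tol & l3 >= -tol & l4 >= -tol
  if (any(contained)) {
    # lowest containing tet id per point, deterministically
    ordc <- order(pidx[contained], tidx[contained])
    pc <- pidx[contained][ordc]; tc <- tidx[contained][ordc]
    first <- !duplicated(pc)
    sel <- which(contained)[ordc][first]
    tet_of[pc[first]] <- tc[first]
    bary[pc[first], ] <- cbind(l1[sel], l2[sel], l3[sel], l4[sel])
  }
  list(tet = tet_of, bary = bary, hash = hash)
}

#' Barycentric interpolation matrix H
#'
#' Locates each point in a containing tetrahedron (spatial hash over tet
#' bounding boxes; ties at shared faces go to the lowest tet id) and emits
#' 3 rows per located point whose entries are the barycentric weights on
#' the vertex coordinate blocks. Unlocated points get no rows.
#'
#' @param mesh a [tet_mesh()].
#' @param points n x 3 matrix of world points.
#' @param hash optional precomputed spatial hash (reused across calls).
#' @return list(H = sparse `3n_located x 3n_vert` matrix, located = integer
#'   tet id or NA per input point).
#' @export
build_interpolation <- function(mesh, points, hash = NULL) {
  points <- as_points(points)
  loc <- locate_points(mesh, points, hash)
  ok <- which(!is.na(loc$tet))
  n_loc <- length(ok)
  nv <- nrow(mesh$vertices)
  if (n_loc == 0) {
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 3 * nv))
    return(list(H = H, located = loc$tet, hash = loc$hash))
  }
  vid <- mesh$tets[loc$tet[ok], , drop = FALSE]       # n_loc x 4
  wts <- loc$bary[ok, , drop = FALSE]
  rows <- integer(12 * n_loc); cols <- integer(12 * n_loc)
  vals <- numeric(12 * n_loc)
  p <- 0L
  for (c in 1:3) {
    for (a in 1:4) {
      rows[p + seq_len(n_loc)] <- 3 * (seq_len(n_loc) - 1) + c
      cols[p + seq_len(n_loc)] <- 3 * (vid[, a] - 1) + c
      vals[p + seq_len(n_loc)] <- wts[, a]
      p <- p + n_loc
    }
  }
  H <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(3 * n_loc, 3 * nv))
  list(H = H, located = loc$tet, hash = loc$hash)
}

#' Rasterize vertex displacements to a dense field
#'
#' Barycentric interpolation of per-vertex displacements U over every voxel
#' inside the mesh; zero outside. Iterates elements in decreasing id so
#' voxels on shared faces deterministically take the lowest containing tet.
#'
#' @param mesh a [tet_mesh()].
#' @param U n_vert x 3 matrix of mm displacements.
#' @param geom an [image_volume()] or [deformation_field()] defining the
#'   output grid.
#' @return a [deformation_field()].
#' @export
rasterize_mesh_field <- function(mesh, U, geom) {
  dm <- if (inherits(geom, "deformation_field")) dim(geom$vectors)[1:3]
        else dim(geom$data)
  out <- matrix(0, prod(dm), 3)
  v <- mesh$vertices; t4 <- mesh$tets
  sp <- geom$spacing; or <- geom$origin
  for (e in rev(seq_len(nrow(t4)))) {
    vx <- v[t4[e, ], , drop = FALSE]
    lo <- pmax(ceiling((apply(vx, 2, min) - or) / sp), 0)
    hi <- pmin(floor((apply(vx, 2, max) - or) / sp), dm - 1)
    if (any(hi < lo)) next
    g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    pw <- sweep(sweep(as.matrix(g), 2, sp, "*"), 2, or, "+")
    Jm <- t(vx[2:4, ]) - matrix(vx[1, ], 3, 3)
    lam234 <- t(solve(Jm, t(sweep(pw, 2, vx[1, ], "-"))))
    l1 <- 1 - rowSums(lam234)
    inside <- l1 >= -1e-9 & lam234[, 1] >= -1e-9 &
              lam234[, 2] >= -1e-9 & lam234[, 3] >= -1e-9
    if (!any(inside)) next
    lin <- 1 + g$i[inside] + dm[1] * (g$j[inside] + dm[2] * g$k[inside])
    W <- cbind(l1, lam234)[inside, , drop = FALSE]
    out[lin, ] <- W %*% U[t4[e, ], , drop = FALSE]
  }
  deformation_field(array(out, c(dm, 3)), sp, or)
}
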