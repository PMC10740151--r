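#' Tetrahedral mesh
#'
#' Vertices in world mm and 4-column tetrahedron connectivity with a tissue
#' label per element. On construction every tetrahedron is re-oriented (by
#' swapping two vertices) to have positive signed volume.
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param tets m x 4 integer matrix of 1-based vertex indices.
#' @param tet_labels integer vector length m (defaults to 1).
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(vertices, tets, tet_labels = NULL) {
  vertices <- as_points(vertices)
  tets <- as.matrix(tets)
  if (ncol(tets) != 4L) stop("tet_mesh: tets must have 4 columns")
  storage.mode(tets) <- "integer"
  if (nrow(tets) > 0 && (min(tets) < 1L || max(tets) > nrow(vertices)))
    stop("tet_mesh: vertex index out of range")
  if (is.null(tet_labels)) tet_labels <- rep(1L, nrow(tets))
  if (length(tet_labels) != nrow(tets))
    stop("tet_mesh: tet_labels length must equal number of tets")
  v <- tet_signed_volumes(vertices, tets)
  flip <- which(v < 0)
  if (length(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (nrow(tets) > 0 && any(tet_signed_volumes(vertices, tets) <= 0))
    stop("tet_mesh: degenerate (zero-volume) tetrahedron")
  structure(list(vertices = vertices, tets = tets,
                 tet_labels = as.integer(tet_labels)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tets, labels {%s}\n",
              nrow(x$vertices), nrow(x$tets),
              paste(sort(unique(x$tet_labels)), collapse = ",")))
  invisible(x)
}

#' Signed volumes of tetrahedra
#'
#' Signed volume `det([b-a, c-a, d-a]) / 6` for each row of `tets`;
#' positive under the package's orientation convention.
#'
#' @param vertices n x 3 matrix.
#' @param tets m x 4 index matrix.
#' @return numeric vector of length m.
#' @export
tet_signed_volumes <- function(vertices, tets) {
  if (nrow(tets) == 0) return(numeric(0))
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

tet_centroids <- function(mesh) {
  (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Read / write tetrahedral meshes (VTK legacy ASCII)
#'
#' Unstructured-grid VTK legacy files with an integer `tissue_label`
#' cell-data array; connectivity round-trips exactly, coordinates to
#' printed precision.
#'
#' @param mesh a [tet_mesh()].
#' @param path file path.
#' @return [read_mesh()] returns a [tet_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "brainshiftr tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$vertices))), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$tet_labels), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("mesh parse error: missing POINTS section in ", path)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pt_tokens <- scan(text = lines[(ip + 1):length(lines)], what = numeric(),
                    n = 3 * np, quiet = TRUE)
  vertices <- matrix(pt_tokens, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  if (!length(ic)) stop("mesh parse error: missing CELLS section in ", path)
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_tokens <- scan(text = lines[(ic + 1):length(lines)], what = integer(),
                      n = 5 * nc, quiet = TRUE)
  cells <- matrix(cell_tokens, ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4L))
    stop("mesh parse error: non-tetrahedral cell in CELLS of ", path)
  il <- grep("^SCALARS tissue_label", lines)
  labels <- if (length(il)) {
    scan(text = lines[(il + 2):length(lines)], what = integer(), n = nc,
         quiet = TRUE)
  } else rep(1L, nc)
  tet_mesh(vertices, cells[, 2:5] + 1L, labels)
}

#' Read / write point sets as plain text
#'
#' One `x y z` (mm) triple per line, whitespace separated.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param path file path.
#' @return [read_points()] returns an n x 3 matrix.
#' @export
write_points <- function(points, path) {
  points <- as_points(points)
  utils::write.table(format(points, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("cannot read points: no such file: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  as_points(m)
}

#' Read / write sparse displacement fields as TSV
#'
#' Tab-separated with header `x y z dx dy dz confidence`; the on-disk form
#' of block-matching output.
#'
#' @param sdf a sparse displacement field (see [block_match_all()]).
#' @param path file path.
#' @return [read_sparse_field()] returns a `sparse_field` object.
#' @export
write_sparse_field <- function(sdf, path) {
  df <- data.frame(x = sdf$points[, 1], y = sdf$points[, 2], z = sdf$points[, 3],
                   dx = sdf$displacements[, 1], dy = sdf$displacements[, 2],
                   dz = sdf$displacements[, 3], confidence = sdf$confidences)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_sparse_field
#' @export
read_sparse_field <- function(path) {
  if (!file.exists(path)) stop("cannot read sparse field: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("x", "y", "z", "dx", "dy", "dz", "confidence")
  if (!all(need %in% names(df)))
    stop("sparse field parse error: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  sparse_field(as.matrix(df[, c("x", "y", "z")]),
               as.matrix(df[, c("dx", "dy", "dz")]),
               df$confidence)
}
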