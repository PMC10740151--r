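test_that("element quality: closed forms for regular, inverted and sliver tets", {
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  q <- element_quality(reg)
  expect_equal(q$min_dihedral_deg, acos(1 / 3) * 180 / pi, tolerance = 1e-6)
  expect_equal(abs(q$volume), 8 / 3, tolerance = 1e-9)
  # reflection flips the signed volume
  refl <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  expect_lt(element_quality(refl)$volume, 0)
  # constructed sliver
  sliver <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0.01))
  expect_lt(element_quality(sliver)$min_dihedral_deg, 5)
})

test_that("isotropic sizing equals the brute-force k-NN oracle", {
  set.seed(15)
  verts <- matrix(runif(60, 0, 12), 20, 3)
  pts <- matrix(runif(300, 0, 12), 100, 3)
  sz <- isotropic_sizing(verts, pts, k = 5)
  oracle <- apply(verts, 1, function(v)
    sort(sqrt(colSums((t(pts) - v)^2)))[5])
  expect_equal(sz$values, oracle, tolerance = 1e-9)
  # k = 1 with a single point at distance 2
  one <- isotropic_sizing(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1), 1)
  expect_equal(one$values, 2)
  # coincident points clamp to eps instead of zero
  co <- isotropic_sizing(matrix(c(1, 1, 1), 1),
                         matrix(rep(c(1, 1, 1), 3), 3, byrow = TRUE), 2)
  expect_gt(co$values, 0)
  expect_error(isotropic_sizing(verts, pts[1:3, ], k = 5), "at least k")
})

test_that("minimum enclosing ellipsoid: symmetry closed forms + containment", {
  oct <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
               c(0, -2, 0), c(0, 0, 2), c(0, 0, -2))
  mv <- min_enclosing_ellipsoid(oct)
  expect_lt(max(abs(mv$center)), 1e-6)
  expect_equal_mat(mv$A, diag(3) / 4, 1e-3)

  cube <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  mv2 <- min_enclosing_ellipsoid(cube)
  expect_equal_mat(mv2$A, diag(3) * 4 / 3, 1e-3)   # ball radius sqrt(3)/2

  set.seed(16)
  for (i in 1:5) {
    P <- matrix(rnorm(30), 10, 3)
    mv3 <- min_enclosing_ellipsoid(P, tol = 1e-4)
    q <- apply(P, 1, function(p)
      t(p - mv3$center) %*% mv3$A %*% (p - mv3$center))
    expect_lte(max(q), 1 + 10 * 1e-4)
    # near-minimality: shrinking excludes at least one point
    expect_gt(max(q) / (1 - 10 * 1e-4), 1 - 1e-2)
  }
  expect_error(min_enclosing_ellipsoid(matrix(0, 3, 3)), ">= 4")
  flat <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(min_enclosing_ellipsoid(flat), "degenerate")
})

test_that("anisotropic metric is centered by reflection and inflates exactly", {
  v0 <- c(1, 2, 3)
  oct <- rbind(v0 + c(2, 0, 0), v0 - c(2, 0, 0), v0 + c(0, 2, 0),
               v0 - c(0, 2, 0), v0 + c(0, 0, 2), v0 - c(0, 0, 2))
  am <- anisotropic_metric(v0, oct, k = 6, a = 1)
  expect_equal(am$center, v0)
  expect_equal_mat(am$A, diag(3) / 4, 1e-3)   # sphere radius r -> ball
  for (a in c(1.0, 1.2, 1.5)) {
    ama <- anisotropic_metric(v0, oct, k = 6, a = a)
    expect_equal_mat(ama$A * a^2, am$A, 1e-12) # semi-axes scale exactly by a
  }
  set.seed(17)
  for (i in 1:5) {
    pts <- matrix(rnorm(60), 20, 3)
    am2 <- anisotropic_metric(c(0.3, -0.2, 0.1), pts, k = 7, a = 1.2)
    expect_equal(am2$center, c(0.3, -0.2, 0.1))
    expect_false(am2$fallback)
    expect_gt(min(eigen(am2$A, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # coplanar neighbours fall back to isotropic, recorded
  flat <- cbind(rnorm(6), rnorm(6), 0)
  amf <- anisotropic_metric(c(0, 0, 0), flat, k = 6, a = 1)
  expect_true(amf$fallback)
})

test_that("metric fields export and read back; non-SPD tensors are refused", {
  lab <- label_volume(array(1L, c(10, 10, 10)))
  mesh <- bcc_mesh_from_labels(lab, 4)
  set.seed(18)
  pts <- matrix(runif(90, 0, 10), 30, 3)
  iso <- isotropic_sizing(mesh$vertices, pts, k = 3)
  f <- tempfile(fileext = ".sol")
  export_metric_field(mesh, iso, f)
  iso2 <- read_metric_field(f)
  expect_equal(iso2$type, "scalar")
  expect_equal(iso2$values, iso$values, tolerance = 1e-12)

  ani <- anisotropic_sizing(mesh, pts, k = 3, a = 1.2)
  f2 <- tempfile(fileext = ".sol")
  export_metric_field(mesh, ani, f2)
  ani2 <- read_metric_field(f2)
  expect_equal(ani2$type, "tensor")
  expect_equal(nrow(ani2$values), nrow(mesh$vertices))
  expect_equal_mat(ani2$values, ani$values, 1e-9)

  bad <- ani
  bad$values[1, ] <- c(-1, 0, -1, 0, 0, -1)
  expect_error(export_metric_field(mesh, bad, tempfile()), "non-SPD")
  short <- iso; short$values <- short$values[-1]
  expect_error(export_metric_field(mesh, short, tempfile()), "mismatch")
})

test_that("a single increment reduces to PBNRR and meshes stay valid", {
  ph <- default_phantom()
  res1 <- anrr_register(ph$pre, ph$intra, ph$labels,
                        cfg = anrr_config(n_inc = 1))
  resP <- default_pbnrr()
  # same mesh, same matches, full acceptance: the dense fields agree
  expect_equal(dim(res1$dense_field$vectors), dim(resP$dense_field$vectors))
  diff <- sqrt(rowSums((matrix(res1$dense_field$vectors, ncol = 3) -
                        matrix(resP$dense_field$vectors, ncol = 3))^2))
  expect_lt(mean(diff), 0.05)
  expect_true(all(tet_signed_volumes(res1$final_mesh$vertices,
                                     res1$final_mesh$tets) > 0))
})

test_that("incremental warping beats single-pass PBNRR on a large bump", {
  # 6 mm bump, comparable to the element size: the regime ANRR targets.
  # About 3 minutes single-core at the default 5 increments.
  spec6 <- phantom_spec(seed = 13,
                        deform = list(list(center = c(36, 32, 32),
                                           amplitude = 6, width = 20,
                                           direction = c(1, 0.4, 0.2))))
  ph <- make_phantom(spec6)
  fwd_truth <- invert_field(ph$truth)
  mesh0 <- bcc_mesh_from_labels(ph$labels, 6)
  resP <- pbnrr_register(ph$pre, ph$intra, mesh0, dense = FALSE)
  tv0 <- sample_trilinear(fwd_truth, mesh0$vertices)
  errP <- mean(sqrt(rowSums((resP$U - tv0)^2)))

  resA <- anrr_register(ph$pre, ph$intra, ph$labels, cfg = anrr_config())
  tvA <- sample_trilinear(fwd_truth, resA$final_mesh$vertices)
  errA <- mean(sqrt(rowSums((resA$U - tvA)^2)))
  expect_lte(errA, errP)
  # loop contract: accepted meshes never contain non-positive elements
  expect_true(all(tet_signed_volumes(resA$final_mesh$vertices,
                                     resA$final_mesh$tets) > 0))
  expect_equal(nrow(resA$increments), 5)
})

test_that("uniform meshes near the ideal spacing equidistribute points", {
  # 2-D-like thin-slab case: points uniform in a slab, mesh built at the
  # median k-NN spacing; vertices whose cell complexes lie inside the
  # sampled slab should then hold about k points each (within factor 2)
  set.seed(19)
  lab <- label_volume(array(1L, c(64, 64, 6)))
  n_pts <- 200; k <- 5
  pts <- cbind(runif(n_pts, 2, 62), runif(n_pts, 2, 62), runif(n_pts, 0.5, 4.5))
  probe <- as.matrix(expand.grid(seq(10, 54, 8), seq(10, 54, 8), 2.5))
  h <- stats::median(isotropic_sizing(probe, pts, k)$values)
  mesh <- bcc_mesh_from_labels(lab, h)
  counts <- vertex_cell_counts(mesh, pts)
  inside <- mesh$vertices[, 1] > h + 2 & mesh$vertices[, 1] < 62 - h - 2 &
            mesh$vertices[, 2] > h + 2 & mesh$vertices[, 2] < 62 - h - 2 &
            mesh$vertices[, 3] > 1.5 & mesh$vertices[, 3] < 4
  med <- stats::median(counts[inside])
  expect_gte(med, k / 2)
  expect_lte(med, 2 * k)
})
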