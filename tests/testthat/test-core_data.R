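test_that("voxel/world maps are affine, handle anisotropic spacing, and round-trip", {
  vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(as.numeric(voxel_to_world(c(2, 3, 4), vol)), c(2, 3, 4))

  vol2 <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.488, 0.488, 1.00))
  expect_equal(as.numeric(voxel_to_world(c(1, 1, 1), vol2)),
               c(0.488, 0.488, 1.00))

  set.seed(1)
  vol3 <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.7, 1.3, 2.1),
                       origin = c(-5, 3, 0.5))
  v <- matrix(runif(300, -10, 30), 100, 3)
  expect_equal_mat(world_to_voxel(voxel_to_world(v, vol3), vol3), v, 1e-9)
})

test_that("trilinear sampling matches the 8-corner oracle and handles edges", {
  set.seed(2)
  vol <- image_volume(array(runif(10 * 11 * 12), c(10, 11, 12)),
                      spacing = c(1, 2, 0.5), origin = c(1, -1, 0))
  # voxel centers return exact values
  idx <- cbind(3, 4, 5)
  expect_equal(sample_trilinear(vol, voxel_to_world(idx, vol)),
               vol$data[4, 5, 6])
  # midpoint linearity
  mid <- (voxel_to_world(c(0, 0, 0), vol) + voxel_to_world(c(1, 0, 0), vol)) / 2
  expect_equal(sample_trilinear(vol, mid),
               (vol$data[1, 1, 1] + vol$data[2, 1, 1]) / 2)
  # 8-corner weighted-sum oracle at 50 random interior points
  p <- cbind(runif(50, 1, 8), runif(50, 0, 15), runif(50, 0.5, 5))
  oracle <- vapply(seq_len(50), function(i) {
    v <- (p[i, ] - vol$origin) / vol$spacing
    i0 <- floor(v); fr <- v - i0; acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * vol$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }, numeric(1))
  expect_equal_mat(sample_trilinear(vol, p), oracle, 1e-9)
  # outside the grid -> background
  expect_equal(sample_trilinear(vol, c(-100, 0, 0)), 0)
  expect_equal(sample_trilinear(vol, c(-100, 0, 0), background = -1), -1)
})

test_that("warp_image: identity, integer shift, and all-outside cases", {
  set.seed(3)
  vol <- image_volume(array(runif(10 * 11 * 12), c(10, 11, 12)))
  w0 <- warp_image(vol, zero_field(vol))
  expect_equal(w0$data, vol$data)

  sh <- deformation_field(array(rep(c(1, 0, 0), each = 10 * 11 * 12),
                                c(10, 11, 12, 3)), vol$spacing, vol$origin)
  w1 <- warp_image(vol, sh)
  expect_equal(w1$data[1:9, , ], vol$data[2:10, , ])

  far <- deformation_field(array(1000, c(10, 11, 12, 3)),
                           vol$spacing, vol$origin)
  expect_true(all(warp_image(vol, far)$data == 0))

  expect_error(warp_image(vol, vol), "deformation_field")
})

test_that("field inversion and composition are mutually consistent", {
  ph <- small_phantom(deform = list(list(center = c(16, 16, 16), amplitude = 2,
                                         width = 8, direction = c(1, 0, 0))))
  fwd <- invert_field(ph$truth)
  # composing the field with its inverse is near-identity away from edges
  comp <- compose_fields(ph$truth, fwd)
  core <- comp$vectors[8:24, 8:24, 8:24, ]
  expect_lt(max(abs(core)), 1e-6)
})

test_that("volume and field NIfTI I/O round-trips (plain and gzipped)", {
  set.seed(4)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)),
                      spacing = c(0.488, 0.488, 1), origin = c(-3, 2, 5))
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    v2 <- read_volume(f)
    expect_equal(v2$data, vol$data)
    expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, vol$origin, tolerance = 1e-6)
  }
  df <- deformation_field(array(rnorm(8^3 * 3), c(8, 8, 8, 3)),
                          c(1, 1, 2), c(0, 0, 0))
  f <- tempfile(fileext = ".nii.gz")
  write_field(df, f)
  expect_equal(read_field(f)$vectors, df$vectors)

  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")
  bad <- tempfile(fileext = ".nii")
  writeBin(raw(100), bad)
  expect_error(read_volume(bad), "parse error")
})

test_that("mesh and point-set I/O round-trips with labels", {
  m <- two_tet_mesh(c(1L, 2L))
  f <- tempfile(fileext = ".vtk")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(m2$tets, m$tets)
  expect_identical(m2$tet_labels, m$tet_labels)
  expect_equal_mat(m2$vertices, m$vertices, 1e-12)
  expect_error(read_mesh(tempfile()), "no such file")

  pts <- matrix(rnorm(30), 10, 3)
  fp <- tempfile(fileext = ".txt")
  write_points(pts, fp)
  expect_equal_mat(read_points(fp), pts, 1e-12)

  sdf <- sparse_field(pts, pts * 0.1, runif(10))
  ft <- tempfile(fileext = ".tsv")
  write_sparse_field(sdf, ft)
  s2 <- read_sparse_field(ft)
  expect_equal_mat(s2$displacements, sdf$displacements, 1e-9)
  expect_equal(s2$confidences, sdf$confidences, tolerance = 1e-9)
})

test_that("type constructors validate their invariants", {
  expect_error(image_volume(array(0, c(2, 2)), c(1, 1, 1)), "3 axes")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(label_volume(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(deformation_field(array(0, c(2, 2, 2))), "nx x ny x nz x 3")
  expect_error(tet_mesh(diag(3), matrix(1:4, 1)), "out of range")
  expect_error(sparse_field(matrix(0, 2, 3), matrix(0, 1, 3), c(1, 1)),
               "length mismatch")
  expect_error(sparse_field(matrix(0, 1, 3), matrix(0, 1, 3), 2), "\\[0, 1\\]")
})
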