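test_that("solve_hybrid agrees with a dense direct solve and its fixed point", {
  mesh <- two_tet_mesh()
  K <- assemble_stiffness(mesh)
  set.seed(8)
  # matches spread over both elements so every dof is data-constrained;
  # 4 points = 12 rows < 15 dofs, so the interpolation limit H U = D
  # is attainable
  pts <- rbind(matrix(runif(6, 0.05, 0.25), 2, 3),
               matrix(runif(6, 0.4, 0.55), 2, 3))
  bi <- build_interpolation(mesh, pts)
  H <- bi$H
  S <- runif(4, 0.5, 1)
  D <- rnorm(12, sd = 0.1)
  U <- solve_hybrid(K, H, S, D)
  A <- as.matrix(K) + t(as.matrix(H)) %*% diag(rep(S, each = 3)) %*% as.matrix(H)
  b <- t(as.matrix(H)) %*% (rep(S, each = 3) * D)
  expect_equal_mat(U, solve(A, b), 1e-8)
  # zero data
  expect_equal(max(abs(solve_hybrid(K, H, S, rep(0, 12)))), 0)
  # relaxation converges to the interpolation solution (HU -> D); the
  # contraction rate is the stiffness-to-data ratio, so use a soft K
  Kb <- K * (0.1 * sum(rep(S, each = 3) *
                       Matrix::rowSums(H^2)) / sum(Matrix::diag(K)))
  U2 <- solve_hybrid(Kb, H, S, D)
  for (i in 1:2000) {
    U_new <- solve_hybrid(Kb, H, S, D, F = as.numeric(Kb %*% U2))
    delta <- max(abs(U_new - U2)); U2 <- U_new
    if (delta < 1e-12) break
  }
  expect_lt(max(abs(as.numeric(H %*% U2) - D)), 1e-6)
  # fixed-point property: F = K U* reproduces U*
  Ufix <- solve_hybrid(Kb, H, S, D, F = as.numeric(Kb %*% U2))
  expect_equal_mat(Ufix, U2, 1e-6)
  # rank deficiency is reported, not silently regularized
  expect_error(solve_hybrid(K, H[1:3, , drop = FALSE], S[1], D[1:3]),
               "rigid modes")
})

test_that("block errors match a per-match loop oracle", {
  mesh <- two_tet_mesh()
  set.seed(9)
  pts <- matrix(runif(15, 0.05, 0.3), 5, 3)
  bi <- build_interpolation(mesh, pts)
  U <- rnorm(15, sd = 0.2)
  D <- rnorm(15, sd = 0.2)
  xi <- compute_block_errors(bi$H, U, D)
  HU <- as.numeric(bi$H %*% U)
  oracle <- vapply(1:5, function(k)
    sqrt(sum((HU[3 * k - 2:0] - D[3 * k - 2:0])^2)), numeric(1))
  expect_equal(xi, oracle, tolerance = 1e-12)
  # interpolating U gives zero errors
  expect_equal(compute_block_errors(bi$H, U, HU), rep(0, 5))
})

test_that("rejection counts reproduce the printed five-case arithmetic", {
  Ns <- c(69244, 76821, 68745, 84445, 68225)
  totals <- c(17310, 19200, 17180, 21110, 17050)
  per_iter <- vapply(Ns, rejection_count, integer(1), f_R = 0.25, n_R = 10)
  expect_equal(10L * per_iter, as.integer(totals))
  expect_equal(rejection_count(69244, 0.25, 10), 1731L)
  expect_equal(rejection_count(1000, 0, 10), 0L)
  expect_equal(mean(10 * per_iter), 18370)
})

test_that("pbnrr bookkeeping: totals, xi ordering, and determinism (small case)", {
  ph <- small_phantom(deform = list(list(center = c(16, 16, 16), amplitude = 2,
                                         width = 10, direction = c(1, 0, 0))),
                      noise = 0.5, seed = 23)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  cfg <- pbnrr_config(f_R = 0.2, n_R = 4, n_A = 3)
  res <- pbnrr_register(ph$pre, ph$intra, mesh, cfg = cfg)
  N <- length(res$active_matches) + length(res$rejected_matches)
  expect_equal(length(res$rejected_matches),
               4L * rejection_count(N, 0.2, 4))
  expect_setequal(c(res$active_matches, res$rejected_matches), seq_len(N))
  # per-iteration diagnostics track the schedule
  rej_rows <- res$iterations[res$iterations$phase == "reject", ]
  expect_equal(nrow(rej_rows), 4)
  expect_equal(unique(rej_rows$rejected), rejection_count(N, 0.2, 4))
  # determinism
  res2 <- pbnrr_register(ph$pre, ph$intra, mesh, cfg = cfg)
  expect_identical(res$U, res2$U)
  expect_identical(res$rejected_matches, res2$rejected_matches)
})

test_that("rejected matches have the largest block errors at their iteration", {
  # one rejection iteration makes the property exhaustively checkable
  ph <- small_phantom(deform = list(list(center = c(16, 16, 16), amplitude = 2,
                                         width = 10, direction = c(0, 1, 0))),
                      noise = 0.5, seed = 24)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  cfg <- pbnrr_config(f_R = 0.2, n_R = 1, n_A = 1)
  res <- pbnrr_register(ph$pre, ph$intra, mesh, cfg = cfg)
  # recompute xi of the first iteration from scratch
  m <- res$matches
  bi <- build_interpolation(mesh, m$points)
  K <- res$k_scale * assemble_stiffness(mesh)
  U1 <- solve_hybrid(K, bi$H, m$confidences,
                     as.numeric(t(m$displacements)))
  xi <- compute_block_errors(bi$H, U1, as.numeric(t(m$displacements)))
  expect_gte(min(xi[res$rejected_matches]), max(xi[res$active_matches]) - 1e-9)
})

test_that("registering a volume to itself yields (near) zero displacement", {
  ph <- small_phantom(seed = 25)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  res <- pbnrr_register(ph$pre, ph$pre, mesh,
                        cfg = pbnrr_config(n_R = 3, n_A = 3))
  expect_lt(max(abs(res$U)), 0.25)   # < 0.25 voxel at 1 mm spacing
})

test_that("insufficient matches raise an explicit error", {
  ph <- small_phantom(seed = 25)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  few <- sparse_field(matrix(rep(c(16, 16, 16), 3), 3, byrow = TRUE),
                      matrix(0, 3, 3), rep(1, 3))
  expect_error(pbnrr_register(ph$pre, ph$intra, mesh, matches = few),
               "fewer than 12")
})
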