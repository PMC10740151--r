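test_that("eval_cost_J equals an explicit three-term loop oracle", {
  mesh <- two_tet_mesh()
  K <- assemble_stiffness(mesh)
  set.seed(10)
  src <- matrix(runif(12, 0.05, 0.3), 4, 3)
  bi <- build_interpolation(mesh, src)
  U <- rnorm(15, sd = 0.1)
  D_C <- matrix(rnorm(12, sd = 0.1), 4, 3)
  W <- runif(4)
  out <- eval_cost_J(U, D_C, bi$H, K, mesh, m_rem = 2L, W = W,
                     lambda1 = 1.7, lambda2 = 2.3)
  # oracle
  strain <- as.numeric(U %*% (as.matrix(K) %*% U))
  HU <- matrix(as.numeric(bi$H %*% U), ncol = 3, byrow = TRUE)
  dat <- 1.7 * sum(W * rowSums((HU - D_C)^2))
  vol <- 2.3 * tet_signed_volumes(mesh$vertices, mesh$tets[2, , drop = FALSE])
  expect_equal(out$J, strain + dat + vol, tolerance = 1e-9)
  expect_equal(out$strain + out$data + out$volume, out$J)
  # trivial cases
  z <- eval_cost_J(numeric(15), matrix(0, 4, 3), bi$H, K, mesh,
                   W = W, lambda1 = 1, lambda2 = 1)
  expect_equal(z$J, 0)
  v2 <- eval_cost_J(numeric(15), matrix(0, 4, 3), bi$H, K, mesh,
                    m_rem = 1L, W = W, lambda1 = 1, lambda2 = 2)
  expect_equal(v2$J, 2 * tet_signed_volumes(mesh$vertices,
                                            mesh$tets[1, , drop = FALSE]))
})

test_that("fuzzy correspondence equals a direct softmax oracle", {
  set.seed(11)
  src <- matrix(runif(15, 0, 10), 5, 3)
  tgt <- matrix(runif(90, 0, 10), 30, 3)
  cfg <- nemnrr_config(candidate_radius = 4, corr_temperature = 1.5)
  C <- update_correspondence(src, tgt, cfg)
  for (i in 1:5) {
    d2 <- rowSums(sweep(tgt, 2, src[i, ], "-")^2)
    cand <- which(d2 <= 16)
    rows <- which(C$i == i)
    if (!length(cand)) { expect_equal(length(rows), 0); next }
    w <- exp(-d2[cand] / 1.5^2); w <- w / sum(w)
    expect_setequal(C$j[rows], cand)
    expect_equal(C$w[rows][order(C$j[rows])], w[order(cand)],
                 tolerance = 1e-9)
    expect_equal(sum(C$w[rows]), 1, tolerance = 1e-12)
    expect_equal(as.numeric(C$barycenter[i, ]),
                 colSums(tgt[cand, , drop = FALSE] * w), tolerance = 1e-9)
  }
  # single candidate -> weight 1; two equidistant -> 0.5/0.5
  C1 <- update_correspondence(matrix(c(0, 0, 0), 1),
                              matrix(c(1, 0, 0), 1), cfg)
  expect_equal(C1$w, 1)
  C2 <- update_correspondence(matrix(c(0, 0, 0), 1),
                              rbind(c(1, 0, 0), c(-1, 0, 0)), cfg)
  expect_equal(C2$w, c(0.5, 0.5))
})

test_that("M-step matches a dense solve and the translation limit", {
  mesh <- two_tet_mesh()
  K <- assemble_stiffness(mesh)
  set.seed(12)
  src <- matrix(runif(18, 0.05, 0.3), 6, 3)
  bi <- build_interpolation(mesh, src)
  D_C <- matrix(rnorm(18, sd = 0.05), 6, 3)
  W <- runif(6, 0.5, 1)
  U <- update_displacement(D_C, bi$H, K, W, lambda1 = 2)
  A <- as.matrix(K) +
    2 * t(as.matrix(bi$H)) %*% diag(rep(W, each = 3)) %*% as.matrix(bi$H)
  b <- 2 * t(as.matrix(bi$H)) %*% (rep(W, each = 3) * as.vector(t(D_C)))
  expect_equal_mat(U, solve(A, b), 1e-8)
  # zero correspondences -> zero displacement
  expect_equal(max(abs(update_displacement(matrix(0, 6, 3), bi$H, K, W))), 0)
  # rigid translation with dominant data weight
  tr <- matrix(rep(c(0.5, -0.2, 0.1), 6), 6, byrow = TRUE)
  U_tr <- update_displacement(tr, bi$H, K, W, lambda1 = 1e8)
  expect_equal_mat(matrix(U_tr, ncol = 3, byrow = TRUE),
                   matrix(rep(c(0.5, -0.2, 0.1), 5), 5, byrow = TRUE), 1e-4)
  # M-step does not increase the (strain + data) objective
  J_before <- eval_cost_J(numeric(15), D_C, bi$H, K, mesh, W = W, lambda1 = 2)
  J_after <- eval_cost_J(U, D_C, bi$H, K, mesh, W = W, lambda1 = 2)
  expect_lte(J_after$J, J_before$J + 1e-9 * abs(J_before$J))
})

test_that("background-tet detection flags cavity elements, not bright tissue", {
  ph <- small_phantom(seed = 14)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  U0 <- matrix(0, nrow(mesh$vertices), 3)
  # uniformly bright fixed image -> empty candidate set
  bright <- image_volume(array(100, c(32, 32, 32)))
  expect_equal(length(detect_background_tets(mesh, U0, bright, 20)), 0)
  # threshold 0 -> nothing is below it
  expect_equal(length(detect_background_tets(mesh, U0, ph$pre, 0)), 0)
  # zeroed sphere: every tet whose displaced samples are inside is flagged
  cav <- apply_resection(ph$pre, list(center = c(16, 16, 16), radius = 6))
  cand <- detect_background_tets(mesh, U0, cav, 20)
  cent <- (mesh$vertices[mesh$tets[, 1], ] + mesh$vertices[mesh$tets[, 2], ] +
           mesh$vertices[mesh$tets[, 3], ] + mesh$vertices[mesh$tets[, 4], ]) / 4
  deep <- which(rowSums(sweep(cent, 2, c(16, 16, 16), "-")^2) <= 3^2)
  expect_true(all(deep %in% cand))
  expect_gt(length(cand), 0)
})

test_that("resection growth follows face connectivity on a hand-built mesh", {
  # strip of tets sharing faces: vertices along a line of cubes
  ph <- small_phantom(seed = 14)
  mesh <- bcc_mesh_from_labels(ph$labels, 5)
  adj <- brainshiftr:::tet_face_adjacency(mesh$tets)
  # pick a seed tet and its face neighbours as one candidate component,
  # plus a far-away singleton
  nb1 <- unique(c(1L, adj[adj[, 1] == 1L, 2], adj[adj[, 2] == 1L, 1]))
  far <- setdiff(seq_len(nrow(mesh$tets)), unique(c(adj[adj[,1] %in% nb1 | adj[,2] %in% nb1, ])))
  far1 <- far[length(far)]
  grown <- grow_resection(integer(0), c(nb1, far1), mesh, adj)
  expect_setequal(grown, nb1)   # largest component wins the seeding
  # growth from an existing set adds only connected candidates
  grown2 <- grow_resection(nb1, c(nb1, far1), mesh, adj)
  expect_setequal(grown2, nb1)
  # empty candidates leave current unchanged; saturation reaches all tets
  expect_equal(grow_resection(nb1, integer(0), mesh, adj), sort(nb1))
  allt <- grow_resection(nb1, seq_len(nrow(mesh$tets)), mesh, adj)
  expect_equal(allt, seq_len(nrow(mesh$tets)))
  # monotone growth
  expect_true(all(nb1 %in% grown2))
  # minimum seed volume suppresses speckle seeding
  expect_equal(length(grow_resection(integer(0), far1, mesh, adj,
                                     min_seed_volume = 1e5)), 0)
})
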