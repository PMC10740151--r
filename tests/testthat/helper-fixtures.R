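# Shared fixtures. Heavy objects (64^3 phantom, full registrations) are
# built once per test run and cached, so the unit suites and the
# acceptance suite share them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small, fast phantom for unit tests (32^3, no ventricle/tumor clutter)
small_phantom <- function(deform = list(), noise = 0, seed = 5,
                          resection = NULL) {
  make_phantom(phantom_spec(
    grid_size = c(32, 32, 32), seed = seed, noise_sigma = noise,
    brain = list(center = c(16, 16, 16), semiaxes = c(13, 12, 11)),
    ventricle = NULL, tumor = NULL,
    structures = list(n = 10, intensity = 35, min_axis = 2, max_axis = 4),
    deform = deform, resection = resection))
}

default_phantom <- function() {
  fixture("default_phantom", function() make_phantom(phantom_spec(seed = 11)))
}

default_mesh <- function() {
  fixture("default_mesh", function()
    bcc_mesh_from_labels(default_phantom()$labels, 6))
}

default_matches <- function() {
  fixture("default_matches", function() {
    ph <- default_phantom()
    pts <- select_registration_points(ph$pre, feature_config())
    block_match_all(ph$pre, ph$intra, pts)
  })
}

default_pbnrr <- function() {
  fixture("default_pbnrr", function() {
    ph <- default_phantom()
    pbnrr_register(ph$pre, ph$intra, default_mesh(),
                   matches = default_matches())
  })
}

default_forward_truth <- function() {
  fixture("default_forward_truth", function()
    invert_field(default_phantom()$truth))
}

# two-tet mesh used across FEM tests
two_tet_mesh <- function(labels = c(1L, 1L)) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
           rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), labels)
}

expect_equal_mat <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
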