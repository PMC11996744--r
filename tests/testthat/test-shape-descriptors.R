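test_that("identity deformation gives unit descriptors and zero logs", {
  m <- make_template(generator_config(template_n_vertices = 150))
  id_field <- deformation_field(function(p) p)
  jf <- jacobian_fields(m, m$vertices, field = id_field)
  expect_equal(jf$surf, rep(1, nrow(m$vertices)), tolerance = 1e-12)
  expect_equal(jf$det, rep(1, nrow(m$vertices)), tolerance = 1e-12)
  expect_equal(jf$normal, rep(1, nrow(m$vertices)), tolerance = 1e-12)
  expect_equal(jf$log_surf, rep(0, nrow(m$vertices)), tolerance = 1e-12)
  expect_equal(jf$log_normal, rep(0, nrow(m$vertices)), tolerance = 1e-12)
})

test_that("uniform scaling obeys surf = s^2, det = s^3, normal = s", {
  m <- tetrahedron_mesh()
  for (s in c(0.5, 0.9, 1.1, 2)) {
    field <- deformation_field(function(p) p * s)
    jf <- jacobian_fields(m, m$vertices * s, field = field)
    expect_equal(jf$surf, rep(s^2, 4), tolerance = 1e-9)
    expect_equal(jf$det, rep(s^3, 4), tolerance = 1e-9)
    expect_equal(jf$normal, rep(s, 4), tolerance = 1e-9)
    expect_equal(jf$log_surf, rep(2 * log(s), 4), tolerance = 1e-9)
    expect_equal(jf$log_normal, rep(log(s), 4), tolerance = 1e-9)
  }
})

test_that("planar patch under diag(2,3,5) has surf 6, det 30, normal 5", {
  m <- grid_patch(5, 4)
  A <- diag(c(2, 3, 5))
  field <- deformation_field(function(p) p %*% A)
  jf <- jacobian_fields(m, m$vertices %*% A, field = field)
  n <- nrow(m$vertices)
  expect_equal(jf$surf, rep(6, n), tolerance = 1e-9)
  expect_equal(jf$det, rep(30, n), tolerance = 1e-9)
  expect_equal(jf$normal, rep(5, n), tolerance = 1e-9)
})

test_that("finite-difference determinant converges at second order to the analytic oracle", {
  withr::with_seed(3, pts <- matrix(runif(45, -2, 2), 15, 3))
  field <- radial_field(0.01)
  truth <- radial_det_oracle(pts, 0.01)
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    max(abs(det_jacobian(field, pts, step = h) - truth))
  }, numeric(1))
  expect_lt(err[3], 1e-4)
  # halving the step divides the error by about four
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("descriptors of composed commuting diagonal maps multiply", {
  m <- grid_patch(4, 4)
  A <- diag(c(2, 3, 5)); B <- diag(c(1.5, 0.5, 2))
  fA <- deformation_field(function(p) p %*% A)
  fB <- deformation_field(function(p) p %*% B)
  fAB <- deformation_field(function(p) p %*% (A %*% B))
  dA <- det_jacobian(fA, m$vertices)
  dB <- det_jacobian(fB, m$vertices)
  dAB <- det_jacobian(fAB, m$vertices)
  expect_equal(dAB, dA * dB, tolerance = 1e-8)
  sA <- surface_jacobian(m, m$vertices %*% A)
  sB <- surface_jacobian(m, m$vertices %*% B)
  sAB <- surface_jacobian(m, m$vertices %*% (A %*% B))
  expect_equal(sAB, sA * sB, tolerance = 1e-9)
})

test_that("normal x surf = det exactly by construction, on an irregular field", {
  m <- make_template(generator_config(template_n_vertices = 150))
  field <- radial_field(0.002)
  jf <- jacobian_fields(m, field$fun(m$vertices), field = field)
  expect_identical(jf$normal * jf$surf, jf$det)
})

test_that("degenerate and out-of-domain inputs raise descriptive errors", {
  m <- square_mesh()
  collapsed <- m$vertices
  collapsed[2, ] <- collapsed[1, ]  # face 1 area -> 0
  expect_error(surface_jacobian(m, collapsed), "degenerate")
  expect_error(surface_jacobian(m, m$vertices[1:3, ]), "template")
  expect_error(normal_jacobian(c(1, 2), c(1, -1)), "non-positive")
  jf <- jacobian_fields(m, m$vertices, det = rep(1, 4))
  jf$surf[1] <- -1
  expect_error(log_fields(jf), "non-positive")
  expect_error(det_jacobian(radial_field(0.01), diag(3), step = 0), "step")
})

test_that("descriptor CSV export carries all five fields per vertex", {
  m <- square_mesh()
  jf <- jacobian_fields(m, m$vertices * 2, det = rep(8, 4))
  p <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(jf, "S001", p)
  df <- read.csv(p)
  expect_equal(names(df), c("subject_id", "vertex_id", "surf_jac", "det_jac",
                            "normal_jac", "log_surf", "log_normal"))
  expect_equal(df$surf_jac, rep(4, 4), tolerance = 1e-12)
  expect_equal(df$normal_jac, rep(2, 4), tolerance = 1e-12)
})
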