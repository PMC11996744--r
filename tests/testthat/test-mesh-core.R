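test_that("one-ring areas match analytic values and the 3x total-area identity", {
  tet <- tetrahedron_mesh()
  expect_equal(one_ring_areas(tet), rep(3 * sqrt(3) / 4, 4), tolerance = 1e-12)

  sq <- square_mesh()
  expect_equal(one_ring_areas(sq), c(1, 0.5, 1, 0.5), tolerance = 1e-12)

  for (mesh in list(tet, sq, grid_patch(4, 4))) {
    total <- sum(ercshape:::triangle_areas(mesh))
    expect_equal(sum(one_ring_areas(mesh)), 3 * total, tolerance = 1e-12)
    # uniform scaling by 2 quadruples every one-ring area
    expect_equal(one_ring_areas(mesh, mesh$vertices * 2),
                 4 * one_ring_areas(mesh), tolerance = 1e-12)
  }
})

test_that("mesh validation rejects each structural defect with a named error", {
  v <- tetrahedron_mesh()$vertices
  f <- tetrahedron_mesh()$faces
  expect_error(triangle_mesh(v, rbind(f, c(1L, 2L, 9L))), "face-index")
  expect_error(triangle_mesh(v, rbind(f, c(2L, 2L, 3L))), "degenerate-face")
  expect_error(triangle_mesh(rbind(v, c(9, 9, 9)), f), "isolated-vertex")
  f_flip <- f; f_flip[1L, ] <- f[1L, c(1L, 3L, 2L)]
  expect_error(triangle_mesh(v, f_flip), "orientation|manifold")
  v_deg <- v; v_deg[4L, ] <- v[1L, ]  # face 2 collapses to zero area
  expect_error(triangle_mesh(v_deg, f), "area|degenerate")
})

test_that("rigid alignment recovers rigid motions exactly and excludes reflections", {
  m <- grid_patch(4, 3)$vertices
  R <- rot_z(pi / 6)
  moved <- m %*% t(R) + rep(c(1, 2, 3), each = nrow(m))
  fit <- rigid_align(moved, m)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # translation-only displacement: identity rotation to 1e-9
  fit_t <- rigid_align(m + rep(c(5, -2, 1), each = nrow(m)), m)
  expect_equal(fit_t$rotation, diag(3), tolerance = 1e-9)

  # self-alignment is the identity transform
  fit_id <- rigid_align(m, m)
  expect_equal(fit_id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit_id$translation, c(0, 0, 0), tolerance = 1e-9)

  # a mirrored copy of a chiral cloud cannot be matched: reflection excluded
  withr::with_seed(3, chiral <- matrix(rnorm(30), 10, 3))
  mirrored <- chiral %*% diag(c(-1, 1, 1))
  expect_gt(rigid_align(mirrored, chiral)$rmsd, 1e-3)
  expect_equal(det(rigid_align(mirrored, chiral)$rotation), 1, tolerance = 1e-9)

  expect_error(rigid_align(m[1:2, ], m[1:2, ]), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(rigid_align(line, line), "collinear")
})

test_that("rigid alignment never worsens the fit on random perturbed pairs", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      a <- matrix(rnorm(30), 10, 3)
      b <- a %*% t(rot_z(runif(1, -pi, pi))) + matrix(rnorm(30, sd = 0.1), 10, 3)
      pre <- sqrt(mean(rowSums((a - b)^2)))
      expect_lte(rigid_align(a, b)$rmsd, pre + 1e-12)
    }
  })
})

test_that("mean shape averages vertices and respects symmetry and idempotence", {
  base <- grid_patch(4, 3)
  d <- c(0.3, 0, 0)
  plus <- sweep(base$vertices, 2, d, "+")
  minus <- sweep(base$vertices, 2, d, "-")
  coh <- corresponded_cohort(base, list(a = plus, b = minus))
  expect_equal(mean_shape(coh, align = FALSE)$vertices, base$vertices,
               tolerance = 1e-12)

  one <- corresponded_cohort(base, list(only = base$vertices))
  expect_equal(mean_shape(one)$vertices, base$vertices, tolerance = 1e-12)

  same <- corresponded_cohort(base, rep(list(base$vertices), 5))
  expect_equal(mean_shape(same)$vertices, base$vertices, tolerance = 1e-12)

  # applying one common rigid motion to all subjects moves the mean shape
  # by that motion (after alignment to the first member)
  withr::with_seed(7, {
    subs <- lapply(1:4, function(i) base$vertices + matrix(rnorm(36, sd = 0.05), 12, 3))
  })
  R <- rot_z(0.4); t_vec <- c(1, -2, 0.5)
  moved <- lapply(subs, function(s) s %*% t(R) + rep(t_vec, each = nrow(s)))
  m1 <- mean_shape(corresponded_cohort(base, subs))$vertices
  m2 <- mean_shape(corresponded_cohort(base, moved))$vertices
  expect_equal(m2, m1 %*% t(R) + rep(t_vec, each = nrow(m1)), tolerance = 1e-8)

  expect_error(corresponded_cohort(base, list()), "empty")
})
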