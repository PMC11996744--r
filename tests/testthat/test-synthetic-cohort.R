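test_that("covariate sampling is reproducible and matches configured moments at large n", {
  cfg_big <- generator_config(n_subjects = 100000L, seed = 2024L)
  covs <- sample_covariates(cfg_big)
  covs2 <- sample_covariates(cfg_big)
  expect_identical(covs, covs2)

  se_ok <- function(x, target, sd_x = sd(x)) {
    abs(mean(x) - target) < 3 * sd_x / sqrt(length(x))
  }
  expect_true(se_ok(covs$age_years, 76.99))
  expect_true(se_ok(covs$icv, 1231.1))
  expect_true(se_ok(pmax(covs$cvemp_left, covs$cvemp_right), 1.32))
  expect_true(se_ok(pmax(covs$ovemp_left, covs$ovemp_right), 14.74))
  expect_true(se_ok((covs$vor_gain_left_eye + covs$vor_gain_right_eye) / 2, 0.98))
  expect_true(se_ok(covs$sex_female, 0.28))
  any_c <- covs$cvemp_present_left | covs$cvemp_present_right
  any_o <- covs$ovemp_present_left | covs$ovemp_present_right
  expect_true(se_ok(any_c, 0.5631))
  expect_true(se_ok(any_o, 0.62))
  # calibrated SDs of the analyzed quantities
  expect_equal(sd(pmax(covs$cvemp_left, covs$cvemp_right)), 0.68, tolerance = 0.02)
  expect_equal(sd((covs$vor_gain_left_eye + covs$vor_gain_right_eye) / 2), 0.15,
               tolerance = 0.005)
})

test_that("the banded template is a closed, labeled, well-sized surface", {
  tm <- make_template(generator_config())
  n_v <- nrow(tm$vertices); n_f <- nrow(tm$faces)
  n_e <- nrow(ercshape:::mesh_edge_list(tm))
  expect_equal(n_v - n_e + n_f, 2L)                    # Euler characteristic
  expect_lt(abs(n_v - 400) / 400, 0.05)
  expect_true(all(ercshape:::triangle_areas(tm) > 0))
  expect_equal(sort(unique(tm$labels)), 1:9)
  expect_true(all(table(tm$labels) > 0))
  expect_false(any(boundary_vertices(tm)))             # closed surface
  # every region owns exact-truth interior vertices
  intr <- ercshape:::interior_vertices(tm)
  expect_true(all(tapply(intr, tm$labels, any)))

  tm_r <- make_template(generator_config(), mirror = TRUE)
  validate_mesh(tm_r)
  expect_equal(sort(unique(tm_r$labels)), 1:9)
  expect_error(make_template(generator_config(template_n_vertices = 50)),
               ">= 100")
})

test_that("zero effects and zero noise leave the template unchanged", {
  tm <- make_template(generator_config(template_n_vertices = 200))
  ds <- deform_subject(tm, c(vest = 1, age = 0.5, sex = 1, icv = -1),
                       matrix(0, 9, 4), rep(0, 9), 0, seed = 1)
  expect_equal(ds$vertices, tm$vertices, tolerance = 1e-12)
  expect_equal(surface_jacobian(tm, ds$vertices), rep(1, nrow(tm$vertices)),
               tolerance = 1e-12)
  expect_equal(det_jacobian(ds$field, tm$vertices), rep(1, nrow(tm$vertices)),
               tolerance = 1e-12)
})

test_that("a single planted region scales its interior exactly (u = ln 1.05 -> surf 1.1025)", {
  tm <- make_template(generator_config())
  pe <- planted_effect(4, log(1.05))
  ds <- deform_subject(tm, c(vest = 1, age = 0, sex = 0, icv = 0),
                       pe$effect_map, pe$effect_baseline, 0, seed = 1)
  surf <- surface_jacobian(tm, ds$vertices)
  sel <- ds$truth$interior & ds$truth$region == 4
  expect_true(any(sel))
  expect_equal(surf[sel], rep(1.05^2, sum(sel)), tolerance = 1e-6)
  # untouched regions stay at unity
  far <- ds$truth$interior & !ds$truth$region %in% 3:5
  expect_equal(surf[far], rep(1, sum(far)), tolerance = 1e-9)
  expect_error(deform_subject(tm, c(vest = 1, age = 0, sex = 0),
                              pe$effect_map), "covariate_channels")
})

test_that("finite-difference determinants match the analytic truth at interior vertices", {
  cfg <- generator_config(n_subjects = 3, seed = 5,
                          effect_map = planted_effect(6, log(1.1))$effect_map,
                          noise_sd = 0.03)
  coh <- simulate_cohort(cfg)
  tm <- coh$template
  intr <- coh$truth$interior
  for (i in 1:3) {
    ds <- deform_subject(
      tm, c(vest = 0.7, age = 0, sex = 0, icv = 0), cfg$effect_map,
      cfg$effect_baseline, cfg$noise_sd,
      seed = ercshape:::derive_seed(cfg$seed, paste0("subject", i)))
    fd <- det_jacobian(ds$field, tm$vertices, use_analytic = FALSE)
    truth <- exp(3 * ds$u_regions[tm$labels])
    expect_lt(max(abs(fd[intr] - truth[intr])), 1e-4)
  }
})

test_that("simulated cohorts carry consistent truth: descriptors equal 2u and u at interior vertices", {
  pe <- planted_effect(2, log(1.08))
  cfg <- generator_config(n_subjects = 8, seed = 9, effect_map = pe$effect_map,
                          noise_sd = 0.02)
  coh <- simulate_cohort(cfg)
  lsurf <- descriptor_matrix(coh, "log_surf")
  lnorm <- descriptor_matrix(coh, "log_normal")
  intr <- coh$truth$interior
  reg <- coh$truth$region
  for (i in 1:8) {
    expect_equal(lsurf[i, intr], 2 * coh$truth$u[i, reg[intr]],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(lnorm[i, intr], coh$truth$u[i, reg[intr]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("dataset bundles round-trip and regenerate byte-identically", {
  cfg <- generator_config(n_subjects = 5, seed = 77,
                          template_n_vertices = 200,
                          effect_map = planted_effect(3, 0.05)$effect_map)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_equal(length(list.files(file.path(d1, "subjects"))), 5L)

  back <- load_bundle(d1)
  coh <- simulate_cohort(cfg)
  expect_equal(back$template$vertices, coh$template$vertices)
  expect_identical(back$template$labels, coh$template$labels)
  expect_equal(back$subject_vertices[[3]],
               unname(coh$subject_vertices[[3]]), tolerance = 1e-15)
  expect_equal(unname(back$det), unname(coh$det), tolerance = 1e-12)
  for (sv in back$subject_vertices) {
    validate_mesh(triangle_mesh(sv, back$template$faces))
  }
})

test_that("the default configuration generates the full 103-subject bundle", {
  d <- withr::local_tempdir()
  generate_dataset(generator_config(seed = 3), d)
  expect_equal(length(list.files(file.path(d, "subjects"))), 103L)
  expect_true(all(file.exists(file.path(
    d, c("template.ply", "parcels.csv", "covariates.csv",
         "jacobians.csv", "truth.json", "config.yaml")))))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(female_prob = 1.2), "probabilities")
  expect_error(generator_config(age_sd = -1), "SDs")
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(effect_map = matrix(0, 3, 4)), "9 x 4")
})
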