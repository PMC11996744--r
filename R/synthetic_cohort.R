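# Fully synthetic study cohort: covariates whose moments match the study
# sample, an ellipsoidal ~400-vertex closed template with nine contiguous
# subregion bands, and per-subject smooth radial deformations whose
# region-wise log-scale depends linearly on covariates plus noise -- with
# closed-form ground-truth Jacobians for every vertex whose one-ring stays
# inside a single region.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study-sample characteristics: n = 103 subjects,
#' age 76.99 (8.64) years, intracranial volume 1231.1 (118.38), 28% female,
#' cVEMP amplitude 1.32 (0.68) uV with a response present in either ear for
#' 56.31% of subjects, oVEMP amplitude 14.74 (9.63) uV with 62% presence,
#' VOR gain 0.98 (0.15), and a template of about 400 vertices.
#'
#' Amplitudes and gains are plain (untruncated) Gaussians so the sample
#' moments are unbiased; per-ear amplitude pairs are correlated draws
#' (correlation 0.7) calibrated so the max-over-ears has exactly the
#' configured mean and SD, and per-eye gains are correlated draws
#' (correlation 0.9) calibrated so the two-eye mean has exactly the
#' configured moments.
#'
#' @param n_subjects number of subjects (default 103).
#' @param seed master RNG seed.
#' @param age_mean,age_sd years.
#' @param icv_mean,icv_sd intracranial volume.
#' @param female_prob probability of sex = female.
#' @param cvemp_mean,cvemp_sd best-ear cVEMP amplitude moments (uV).
#' @param cvemp_present_prob probability of a response present in either ear.
#' @param ovemp_mean,ovemp_sd best-ear oVEMP amplitude moments (uV).
#' @param ovemp_present_prob probability of a response present in either ear.
#' @param vor_mean,vor_sd two-eye mean VOR gain moments.
#' @param template_n_vertices requested template vertex count (default 400).
#' @param effect_map 9 x 4 matrix of per-region log-scale coefficients on
#'   the covariate channels `vest`, `age`, `sex`, `icv` (continuous channels
#'   standardized within the cohort); default all zero (global null).
#' @param effect_baseline length-9 vector of constant per-region log-scales.
#' @param effect_variable which vestibular variable drives the `vest`
#'   channel (`"cvemp"`, `"ovemp"`, `"vor"`).
#' @param effect_form `"continuous"` or `"categorical"` form of that channel.
#' @param noise_sd SD of the per-region, per-subject log-scale noise.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 103L, seed = 1L,
                             age_mean = 76.99, age_sd = 8.64,
                             icv_mean = 1231.1, icv_sd = 118.38,
                             female_prob = 0.28,
                             cvemp_mean = 1.32, cvemp_sd = 0.68,
                             cvemp_present_prob = 0.5631,
                             ovemp_mean = 14.74, ovemp_sd = 9.63,
                             ovemp_present_prob = 0.62,
                             vor_mean = 0.98, vor_sd = 0.15,
                             template_n_vertices = 400L,
                             effect_map = NULL, effect_baseline = rep(0, 9L),
                             effect_variable = "vor",
                             effect_form = "continuous",
                             noise_sd = 0.02) {
  if (is.null(effect_map)) {
    effect_map <- matrix(0, 9L, 4L)
  }
  effect_map <- as.matrix(effect_map)
  colnames(effect_map) <- c("vest", "age", "sex", "icv")
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              age_mean = age_mean, age_sd = age_sd,
              icv_mean = icv_mean, icv_sd = icv_sd,
              female_prob = female_prob,
              cvemp_mean = cvemp_mean, cvemp_sd = cvemp_sd,
              cvemp_present_prob = cvemp_present_prob,
              ovemp_mean = ovemp_mean, ovemp_sd = ovemp_sd,
              ovemp_present_prob = ovemp_present_prob,
              vor_mean = vor_mean, vor_sd = vor_sd,
              template_n_vertices = as.integer(template_n_vertices),
              effect_map = effect_map,
              effect_baseline = as.numeric(effect_baseline),
              effect_variable = match.arg(effect_variable, c("cvemp", "ovemp", "vor")),
              effect_form = match.arg(effect_form, c("continuous", "categorical")),
              noise_sd = noise_sd)
  probs <- c(cfg$female_prob, cfg$cvemp_present_prob, cfg$ovemp_present_prob)
  if (any(probs < 0 | probs > 1)) stopf("generator_config: probabilities must lie in [0, 1]")
  sds <- c(cfg$age_sd, cfg$icv_sd, cfg$cvemp_sd, cfg$ovemp_sd, cfg$vor_sd, cfg$noise_sd)
  if (any(sds < 0)) stopf("generator_config: SDs must be >= 0")
  if (cfg$n_subjects < 1L) stopf("generator_config: n_subjects must be >= 1")
  if (nrow(cfg$effect_map) != 9L || ncol(cfg$effect_map) != 4L) {
    stopf("generator_config: effect_map must be 9 x 4 (regions x covariate channels)")
  }
  if (length(cfg$effect_baseline) != 9L) stopf("generator_config: effect_baseline must have length 9")
  structure(cfg, class = "generator_config")
}

#' Planted-effect shorthand
#'
#' Builds `effect_map` and `effect_baseline` arguments planting a vestibular
#' log-scale effect `vest_coef` (per 1 SD of the vestibular channel) in a
#' single region, optionally with a constant baseline log-scale making that
#' region the dominant signal of its cluster.
#'
#' @param region parcel id (1..9) receiving the effect.
#' @param vest_coef coefficient on the standardized vestibular channel.
#' @param baseline constant log-scale added to the region (default 0).
#' @return list with elements `effect_map` and `effect_baseline`.
#' @export
planted_effect <- function(region, vest_coef, baseline = 0) {
  em <- matrix(0, 9L, 4L)
  em[region, 1L] <- vest_coef
  bl <- rep(0, 9L)
  bl[region] <- baseline
  list(effect_map = em, effect_baseline = bl)
}

# Draw a correlated pair calibrated so that max(pair) has mean m and sd s.
# For equal-mean, equal-variance bivariate normals with correlation rho:
#   E[max] = mu0 + sigma0 * sqrt((1 - rho) / pi)
#   Var[max] = sigma0^2 * (1 - (1 - rho) / pi)
paired_max_calibrated <- function(n, m, s, rho) {
  sigma0 <- s / sqrt(1 - (1 - rho) / pi)
  mu0 <- m - sigma0 * sqrt((1 - rho) / pi)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(mu0 + sigma0 * z1,
        mu0 + sigma0 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# Correlated per-eye pair calibrated so that the two-eye mean has mean m, sd s.
paired_mean_calibrated <- function(n, m, s, rho) {
  sigma0 <- s / sqrt((1 + rho) / 2)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(m + sigma0 * z1,
        m + sigma0 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# Presence flags: a subject-level "any present" Bernoulli with the
# configured marginal; given any presence, both ears are present with
# probability 0.7, otherwise one ear chosen uniformly.
presence_flags <- function(n, p_any) {
  any_p <- stats::runif(n) < p_any
  both <- stats::runif(n) < 0.7
  left_single <- stats::runif(n) < 0.5
  left <- any_p & (both | left_single)
  right <- any_p & (both | !left_single)
  cbind(as.integer(left), as.integer(right))
}

#' Sample a synthetic covariate table
#'
#' Draws the raw per-ear / per-eye covariate table for `config$n_subjects`
#' subjects, deterministically under `config$seed`.
#'
#' @param config a `generator_config`.
#' @return data.frame with columns `subject_id`, `cvemp_left`,
#'   `cvemp_right`, `cvemp_present_left`, `cvemp_present_right`,
#'   `ovemp_left`, `ovemp_right`, `ovemp_present_left`,
#'   `ovemp_present_right`, `vor_gain_left_eye`, `vor_gain_right_eye`,
#'   `age_years`, `sex_female`, `icv`.
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  with_seed(derive_seed(config$seed, "covariates"), {
    cv <- paired_max_calibrated(n, config$cvemp_mean, config$cvemp_sd, 0.7)
    cp <- presence_flags(n, config$cvemp_present_prob)
    ov <- paired_max_calibrated(n, config$ovemp_mean, config$ovemp_sd, 0.7)
    op <- presence_flags(n, config$ovemp_present_prob)
    vg <- paired_mean_calibrated(n, config$vor_mean, config$vor_sd, 0.9)
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               cvemp_left = cv[, 1L], cvemp_right = cv[, 2L],
               cvemp_present_left = cp[, 1L], cvemp_present_right = cp[, 2L],
               ovemp_left = ov[, 1L], ovemp_right = ov[, 2L],
               ovemp_present_left = op[, 1L], ovemp_present_right = op[, 2L],
               vor_gain_left_eye = vg[, 1L], vor_gain_right_eye = vg[, 2L],
               age_years = stats::rnorm(n, config$age_mean, config$age_sd),
               sex_female = as.integer(stats::runif(n) < config$female_prob),
               icv = stats::rnorm(n, config$icv_mean, config$icv_sd),
               stringsAsFactors = FALSE)
  })
}

#' Build the banded ellipsoid template
#'
#' Closed, consistently oriented ellipsoid (semi-axes 12 x 6 x 4 mm, an
#' entorhinal-like elongation) triangulated as a UV sphere with poles on the
#' long axis; the vertex count is within 5% of the request.  Vertices are
#' labeled with nine contiguous bands along the long axis, named after the
#' Krimer subregions (ids 1..9, seven grouped as ERC and two as TEC).  The
#' band geometry (axis, boundary positions, transition half-widths) is
#' attached as the `band_geometry` attribute and drives [deform_subject()].
#'
#' @param config a `generator_config` (only `template_n_vertices` is used).
#' @param semi_axes ellipsoid semi-axes in mm (default `c(12, 6, 4)`).
#' @param mirror logical; mirror the long axis (for a contralateral-side
#'   template).  Mirroring flips face winding to keep orientation valid.
#' @return a labeled `triangle_mesh` with attribute `band_geometry`.
#' @export
make_template <- function(config = generator_config(), semi_axes = c(12, 6, 4),
                          mirror = FALSE) {
  V <- config$template_n_vertices
  if (V < 100L) stopf("make_template: template_n_vertices must be >= 100")
  # Favour axial resolution (rings ~ 3x longitudes) so that at the default
  # size each of the nine bands spans at least three axial levels and owns
  # interior vertices (vertices whose whole one-ring stays in one band).
  nlon <- max(6L, round(sqrt((V - 2L) / 2.8)))
  rings <- max(9L, round((V - 2L) / nlon))
  n <- rings * nlon + 2L
  if (abs(n - V) / V > 0.05) {
    stopf("make_template: achievable vertex count %d is more than 5%% from request %d", n, V)
  }
  a <- semi_axes[1L]; b <- semi_axes[2L]; c3 <- semi_axes[3L]
  theta <- pi * seq_len(rings) / (rings + 1L)
  phi <- 2 * pi * (seq_len(nlon) - 1L) / nlon
  verts <- matrix(NA_real_, n, 3L)
  verts[1L, ] <- c(-a, 0, 0)
  for (i in seq_len(rings)) {
    idx <- 1L + (i - 1L) * nlon + seq_len(nlon)
    verts[idx, ] <- cbind(-a * cos(theta[i]),
                          b * sin(theta[i]) * cos(phi),
                          c3 * sin(theta[i]) * sin(phi))
  }
  verts[n, ] <- c(a, 0, 0)
  vid <- function(i, j) 1L + (i - 1L) * nlon + (j - 1L) %% nlon + 1L
  faces <- matrix(NA_integer_, 2L * nlon * (rings - 1L) + 2L * nlon, 3L)
  r <- 1L
  for (j in seq_len(nlon)) {  # top fan around the -x pole
    faces[r, ] <- c(1L, vid(1L, j), vid(1L, j + 1L)); r <- r + 1L
  }
  for (i in seq_len(rings - 1L)) {
    for (j in seq_len(nlon)) {
      faces[r, ] <- c(vid(i, j + 1L), vid(i, j), vid(i + 1L, j)); r <- r + 1L
      faces[r, ] <- c(vid(i, j + 1L), vid(i + 1L, j), vid(i + 1L, j + 1L)); r <- r + 1L
    }
  }
  for (j in seq_len(nlon)) {  # bottom fan around the +x pole
    faces[r, ] <- c(n, vid(rings, j + 1L), vid(rings, j)); r <- r + 1L
  }
  if (mirror) {
    verts[, 1L] <- -verts[, 1L]
    faces <- faces[, c(1L, 3L, 2L)]
  }
  # Nine contiguous bands over the rings+2 axial levels, balanced by level.
  n_levels <- rings + 2L
  level <- integer(n)
  level[1L] <- 1L
  for (i in seq_len(rings)) level[1L + (i - 1L) * nlon + seq_len(nlon)] <- i + 1L
  level[n] <- n_levels
  band_of_level <- as.integer(floor((seq_len(n_levels) - 1L) * 9L / n_levels) + 1L)
  labels <- band_of_level[level]
  # Axial coordinate of each level (levels are ordered by increasing x for
  # the unmirrored template and decreasing x for the mirrored one).
  x_of_level <- vapply(seq_len(n_levels), function(l) verts[level == l, 1L][1L],
                       numeric(1))
  # Boundary between consecutive bands: midpoint of the adjacent level pair;
  # transition half-width is a quarter of that level gap, so no vertex ever
  # sits inside a transition zone.
  edges <- which(diff(band_of_level) != 0L)
  bounds <- (x_of_level[edges] + x_of_level[edges + 1L]) / 2
  widths <- abs(x_of_level[edges + 1L] - x_of_level[edges]) / 4
  ord <- order(bounds)
  mesh <- triangle_mesh(verts, faces, labels = labels)
  attr(mesh, "band_geometry") <- list(
    centroid = colMeans(verts),
    axis = c(1, 0, 0),
    boundaries = bounds[ord],
    widths = widths[ord],
    # band id sequence from the low-x side to the high-x side
    band_seq = if (mirror) 9:1 else 1:9)
  mesh
}

# Smoothstep and its derivative.
smoothstep <- function(t) ifelse(t <= 0, 0, ifelse(t >= 1, 1, 3 * t^2 - 2 * t^3))
smoothstep_d <- function(t) ifelse(t <= 0 | t >= 1, 0, 6 * t - 6 * t^2)

# Per-point log-scale u(s) and derivative du/ds for a banded template:
# piecewise constant per band, smoothstep-interpolated over
# [boundary - w, boundary + w].
band_log_scale <- function(s, u_regions, geom) {
  bs <- geom$boundaries; ws <- geom$widths
  useq <- u_regions[geom$band_seq]
  u <- rep(useq[1L], length(s))
  du <- numeric(length(s))
  for (e in seq_along(bs)) {
    t <- (s - (bs[e] - ws[e])) / (2 * ws[e])
    h <- smoothstep(t)
    step_u <- useq[e + 1L] - useq[e]
    u <- u + step_u * h
    du <- du + step_u * smoothstep_d(t) / (2 * ws[e])
  }
  list(u = u, du = du)
}

#' Region-wise radial deformation field of a banded template
#'
#' The map is `x -> centroid + exp(u(x)) * (x - centroid)` with `u` the
#' band log-scale, constant inside each band and smoothstep-blended across
#' band boundaries, so vertices away from boundaries undergo exact local
#' uniform scaling by `exp(u_r)`.  The analytic spatial gradient
#' `exp(u) (I + u'(s) (x - c) e^T)` is attached, so determinant evaluation
#' is exact.
#'
#' @param template a `triangle_mesh` from [make_template()].
#' @param u_regions length-9 vector of per-region log-scales.
#' @return a `deformation_field`.
#' @export
region_deformation <- function(template, u_regions) {
  geom <- attr(template, "band_geometry")
  if (is.null(geom)) stopf("region_deformation: template lacks band geometry (use make_template())")
  if (length(u_regions) != 9L) stopf("region_deformation: u_regions must have length 9")
  cen <- geom$centroid; ax <- geom$axis
  fun <- function(p) {
    p <- as.matrix(p)
    d <- sweep(p, 2L, cen)
    s <- as.numeric(d %*% ax)
    u <- band_log_scale(s, u_regions, geom)$u
    sweep(d * exp(u), 2L, cen, "+")
  }
  grad <- function(p) {
    p <- as.matrix(p)
    d <- sweep(p, 2L, cen)
    s <- as.numeric(d %*% ax)
    bl <- band_log_scale(s, u_regions, geom)
    G <- array(0, c(3L, 3L, nrow(p)))
    for (i in seq_len(nrow(p))) {
      G[, , i] <- exp(bl$u[i]) * (diag(3L) + bl$du[i] * outer(d[i, ], ax))
    }
    G
  }
  # det(e^u (I + u'(s) d e^T)) = e^{3u} (1 + u'(s) s), vectorised.
  detf <- function(p) {
    p <- as.matrix(p)
    s <- as.numeric(sweep(p, 2L, cen) %*% ax)
    bl <- band_log_scale(s, u_regions, geom)
    exp(3 * bl$u) * (1 + bl$du * s)
  }
  deformation_field(fun, grad, det = detf)
}

# Vertices whose full one-ring lies in a single region (exact-truth set).
interior_vertices <- function(template) {
  lab <- template$labels
  f <- template$faces
  ok <- rep(TRUE, nrow(template$vertices))
  mixed <- lab[f[, 1L]] != lab[f[, 2L]] | lab[f[, 2L]] != lab[f[, 3L]]
  bad <- unique(as.integer(f[mixed, ]))
  ok[bad] <- FALSE
  ok
}

#' Deform one subject and return analytic truth
#'
#' Computes per-region log-scales
#' `u_r = baseline_r + effect_map[r, ] . (vest, age, sex, icv) + eps_r`
#' with `eps_r ~ N(0, noise_sd^2)` drawn under `seed`, applies the radial
#' band deformation, and returns the deformed vertices, the evaluable field
#' with analytic gradient, and the per-vertex ground truth: for vertices
#' whose one-ring stays inside one region the construction is exact local
#' uniform scaling, so `log_surf = 2 u_r`, `log det = 3 u_r`,
#' `log_normal = u_r`.
#'
#' @param template a labeled `triangle_mesh` from [make_template()].
#' @param covariate_channels named numeric vector with entries `vest`,
#'   `age`, `sex`, `icv` (standardized channels; see [simulate_cohort()]).
#' @param effect_map 9 x 4 coefficient matrix.
#' @param effect_baseline length-9 constant log-scales.
#' @param noise_sd per-region noise SD on the log scale.
#' @param seed RNG seed for the noise draw.
#' @return list with `vertices` (deformed `n x 3`), `field`
#'   (`deformation_field`), `u_regions`, and `truth` (data.frame with
#'   `vertex_id`, `region`, `interior`, `log_surf`, `log_normal`).
#' @export
deform_subject <- function(template, covariate_channels, effect_map,
                           effect_baseline = rep(0, 9L), noise_sd = 0,
                           seed = 1L) {
  ch <- covariate_channels[c("vest", "age", "sex", "icv")]
  if (anyNA(ch)) stopf("deform_subject: covariate_channels must name vest, age, sex, icv")
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(9L, 0, noise_sd)) else rep(0, 9L)
  u_regions <- as.numeric(effect_baseline + effect_map %*% ch + eps)
  field <- region_deformation(template, u_regions)
  deformed <- field$fun(template$vertices)
  interior <- interior_vertices(template)
  truth <- data.frame(vertex_id = seq_len(nrow(template$vertices)) - 1L,
                      region = template$labels,
                      interior = interior,
                      log_surf = ifelse(interior, 2 * u_regions[template$labels], NA_real_),
                      log_normal = ifelse(interior, u_regions[template$labels], NA_real_))
  list(vertices = deformed, field = field, u_regions = u_regions, truth = truth)
}

#' Simulate a full in-memory cohort
#'
#' Draws covariates, builds the template, and deforms every subject.  The
#' `vest` covariate channel driving the planted effects is the prepared form
#' of `config$effect_variable` (standardized if continuous); subjects for
#' whom it is unmeasured (e.g. bilaterally absent responses) receive a zero
#' channel, carrying no vestibular-driven deformation.  Per-vertex Jacobian
#' determinants are evaluated from each subject's analytic field, mirroring
#' a registration pipeline that reports a determinant per vertex.
#'
#' @param config a `generator_config`.
#' @param mirror build the mirrored (contralateral) template.
#' @return object of class `synthetic_cohort`: list with `config`,
#'   `template`, `parcels` (a `parcellation`), `covariates` (raw table),
#'   `subject_vertices` (named list), `det` (subjects x vertices matrix of
#'   Jacobian determinants), and `truth` (list with `u` subjects x 9 matrix,
#'   `interior`, `region`, `effect_map`, `effect_baseline`).
#' @export
simulate_cohort <- function(config = generator_config(), mirror = FALSE) {
  covs <- sample_covariates(config)
  template <- make_template(config, mirror = mirror)
  parc <- parcellation(template$labels)
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  vest_prep <- tryCatch(
    prepare_covariates(covs, variable = config$effect_variable,
                       form = config$effect_form, standardize = FALSE),
    error = function(e) NULL)
  vest_ch <- rep(0, config$n_subjects)
  if (!is.null(vest_prep)) {
    idx <- match(vest_prep$subject_id, covs$subject_id)
    v <- vest_prep$vest
    if (config$effect_form == "continuous") v <- zs(v)
    vest_ch[idx] <- v
  }
  channels <- cbind(vest = vest_ch, age = zs(covs$age_years),
                    sex = covs$sex_female, icv = zs(covs$icv))
  n <- config$n_subjects
  nv <- nrow(template$vertices)
  # Region log-scales for all subjects (same draws as deform_subject).
  u_mat <- matrix(NA_real_, n, 9L)
  for (i in seq_len(n)) {
    eps <- if (config$noise_sd > 0) {
      with_seed(derive_seed(config$seed, paste0("subject", i)),
                stats::rnorm(9L, 0, config$noise_sd))
    } else rep(0, 9L)
    u_mat[i, ] <- config$effect_baseline + config$effect_map %*% channels[i, ] + eps
  }
  # The per-vertex log-scale u(s) and its derivative are linear in the
  # region log-scales, so one weight matrix serves all subjects.
  geom <- attr(template, "band_geometry")
  s_v <- as.numeric(sweep(template$vertices, 2L, geom$centroid) %*% geom$axis)
  W <- matrix(0, nv, 9L); D <- matrix(0, nv, 9L)
  for (r in 1:9) {
    e_r <- replace(numeric(9L), r, 1)
    bl <- band_log_scale(s_v, e_r, geom)
    W[, r] <- bl$u; D[, r] <- bl$du
  }
  u_vert <- tcrossprod(u_mat, W)      # subjects x vertices
  du_vert <- tcrossprod(u_mat, D)
  d0 <- sweep(template$vertices, 2L, geom$centroid)
  sv <- lapply(seq_len(n), function(i) {
    sweep(d0 * exp(u_vert[i, ]), 2L, geom$centroid, "+")
  })
  det_mat <- exp(3 * u_vert) * (1 + du_vert * rep(s_v, each = n))
  interior <- interior_vertices(template)
  truth0 <- list(interior = interior, region = template$labels)
  names(sv) <- covs$subject_id
  rownames(det_mat) <- covs$subject_id
  structure(list(config = config, template = template, parcels = parc,
                 covariates = covs, subject_vertices = sv, det = det_mat,
                 truth = list(u = u_mat, interior = truth0$interior,
                              region = truth0$region,
                              effect_map = config$effect_map,
                              effect_baseline = config$effect_baseline,
                              seed = config$seed)),
            class = "synthetic_cohort")
}

#' Write a simulated cohort as an on-disk bundle
#'
#' Layout: `template.ply` (with parcel labels), `parcels.csv`,
#' `subjects/<id>.ply`, `covariates.csv`, `jacobians.csv` (per-vertex
#' Jacobian determinants, the real-data-path det input), `truth.json`, and
#' `config.yaml`.  All writers are byte-stable, so re-running with the same
#' config yields an identical bundle.
#'
#' @param config a `generator_config` (or an already-simulated
#'   `synthetic_cohort`).
#' @param dir output directory (created; must not be a file).
#' @param mirror forwarded to [simulate_cohort()].
#' @return the bundle directory, invisibly.
#' @export
generate_dataset <- function(config, dir, mirror = FALSE) {
  cohort <- if (inherits(config, "synthetic_cohort")) config
            else simulate_cohort(config, mirror = mirror)
  cfg <- cohort$config
  if (file.exists(dir) && !dir.exists(dir)) stopf("generate_dataset: '%s' exists and is not a directory", dir)
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  write_mesh(cohort$template, file.path(dir, "template.ply"))
  write_parcellation(cohort$parcels, file.path(dir, "parcels.csv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  for (id in names(cohort$subject_vertices)) {
    m <- triangle_mesh(cohort$subject_vertices[[id]], cohort$template$faces,
                       validate = FALSE)
    write_mesh(m, file.path(dir, "subjects", paste0(id, ".ply")))
  }
  det_long <- data.frame(
    subject_id = rep(rownames(cohort$det), each = ncol(cohort$det)),
    vertex_id = rep(seq_len(ncol(cohort$det)) - 1L, times = nrow(cohort$det)),
    det_jac = as.vector(t(cohort$det)))
  utils::write.table(det_long, file.path(dir, "jacobians.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, noise_sd = cfg$noise_sd,
         effect_variable = cfg$effect_variable, effect_form = cfg$effect_form,
         effect_map = cohort$truth$effect_map,
         effect_baseline = cohort$truth$effect_baseline,
         region = cohort$truth$region, interior = cohort$truth$interior,
         u = cohort$truth$u),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(cfg[setdiff(names(cfg), c("effect_map", "effect_baseline"))],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a bundle written by [generate_dataset()]
#'
#' @param dir bundle directory.
#' @return a `synthetic_cohort`-like list with `template`, `parcels`,
#'   `covariates`, `subject_vertices`, `det`, and `truth` (NULL when absent).
#' @export
load_bundle <- function(dir) {
  template <- read_mesh(file.path(dir, "template.ply"))
  parc <- parcellation(template$labels)
  covs <- utils::read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  sv <- lapply(covs$subject_id, function(id) {
    read_mesh(file.path(dir, "subjects", paste0(id, ".ply")))$vertices
  })
  names(sv) <- covs$subject_id
  det_mat <- NULL
  jp <- file.path(dir, "jacobians.csv")
  if (file.exists(jp)) {
    dl <- utils::read.csv(jp, stringsAsFactors = FALSE)
    det_mat <- matrix(NA_real_, length(sv), nrow(template$vertices),
                      dimnames = list(covs$subject_id, NULL))
    det_mat[cbind(match(dl$subject_id, covs$subject_id), dl$vertex_id + 1L)] <- dl$det_jac
  }
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  structure(list(template = template, parcels = parc, covariates = covs,
                 subject_vertices = sv, det = det_mat, truth = truth),
            class = "synthetic_cohort")
}
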