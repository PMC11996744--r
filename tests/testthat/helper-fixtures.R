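# Fixtures and independent oracles shared across the test files.  All
# fixtures are built in code; the oracles deliberately use different
# algorithms than the implementation they check.

# Unit square in z = 0, split along the (0,0)-(1,1) diagonal.
square_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  triangle_mesh(v, f)
}

# Planar triangulated grid patch in z = 0, nx x ny vertices.
grid_patch <- function(nx = 5L, ny = 4L) {
  v <- as.matrix(expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1))
  v <- cbind(v, 0)
  vid <- function(i, j) (j - 1L) * nx + i
  faces <- NULL
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      faces <- rbind(faces,
                     c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                     c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
    }
  }
  triangle_mesh(v, faces)
}

rot_z <- function(th) {
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# Brute-force OLS oracle via the SVD pseudo-inverse (normal equations
# never formed in the implementation path, which uses QR through lm.fit).
ols_oracle <- function(X, y) {
  s <- svd(X)
  beta <- s$v %*% ((t(s$u) %*% y) / s$d)
  resid <- y - X %*% beta
  list(coef = as.numeric(beta), sse = sum(resid^2))
}

# Brute-force normalized-cut oracle: enumerate all 2-partitions of a small
# weighted graph and return the one minimizing Ncut(A, B).
ncut_oracle <- function(n, edges, weights) {
  W <- matrix(0, n, n)
  W[edges] <- weights; W[edges[, 2:1]] <- weights
  d <- rowSums(W)
  best <- NULL; best_val <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {  # vertex 1 fixed in A; avoid empty B
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1))))
    if (all(inA)) next
    cut <- sum(W[inA, !inA])
    val <- cut / sum(d[inA]) + cut / sum(d[!inA])
    if (val < best_val) { best_val <- val; best <- inA }
  }
  best
}

# Radial test field x -> (1 + a ||x||^2) x with closed-form gradient and
# determinant: grad = (1 + a r^2) I + 2 a x x^T,
# det = (1 + a r^2)^2 (1 + 3 a r^2).
radial_field <- function(a = 0.01) {
  fun <- function(p) {
    r2 <- rowSums(p^2)
    p * (1 + a * r2)
  }
  deformation_field(fun)
}
radial_det_oracle <- function(p, a = 0.01) {
  r2 <- rowSums(p^2)
  (1 + a * r2)^2 * (1 + 3 * a * r2)
}

# Raw covariate table with exactly controllable fields.
raw_cov_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               cvemp_left = rnorm(n, 1.3, 0.5), cvemp_right = rnorm(n, 1.3, 0.5),
               cvemp_present_left = rbinom(n, 1, 0.7),
               cvemp_present_right = rbinom(n, 1, 0.7),
               ovemp_left = rnorm(n, 14, 5), ovemp_right = rnorm(n, 14, 5),
               ovemp_present_left = rbinom(n, 1, 0.8),
               ovemp_present_right = rbinom(n, 1, 0.8),
               vor_gain_left_eye = rnorm(n, 0.98, 0.1),
               vor_gain_right_eye = rnorm(n, 0.98, 0.1),
               age_years = rnorm(n, 77, 8), sex_female = rbinom(n, 1, 0.3),
               icv = rnorm(n, 1231, 118))
  })
}

# Naive permutation test that refits every alternate model with
# fit_cluster_model; reproduces the same permutation draws as the fast path.
naive_permutation_test <- function(Y, cov, n_perm, seed,
                                   variant = "ratio_of_maxima") {
  k <- ncol(Y)
  fits <- lapply(seq_len(k), function(c) fit_cluster_model(Y[, c], cov))
  sse_null <- vapply(fits, `[[`, numeric(1), "sse_null")
  sse_alt <- vapply(fits, `[[`, numeric(1), "sse_alt")
  t_obs <- perm_statistic(sse_null, sse_alt, variant)
  cov_p <- cov
  t_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      cov_p$vest <- cov$vest[sample.int(nrow(cov))]
      f <- lapply(seq_len(k), function(c) fit_cluster_model(Y[, c], cov_p))
      perm_statistic(vapply(f, `[[`, numeric(1), "sse_null"),
                     vapply(f, `[[`, numeric(1), "sse_alt"), variant)
    }, numeric(1))
  })
  list(t_observed = t_obs, t_null = t_null,
       p_perm = (1 + sum(t_null >= t_obs)) / (n_perm + 1))
}
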