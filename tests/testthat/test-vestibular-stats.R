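test_that("covariate preparation applies the best-ear, bilateral-absent, and VOR rules", {
  raw <- raw_cov_table(8)
  raw$cvemp_left <- c(1.0, 2.0, 0.4, 1.1, 0.9, 0.5, 1.8, 0.7)
  raw$cvemp_right <- c(1.5, 1.2, 0.6, 0.2, 1.4, 0.8, 0.3, 0.9)
  raw$cvemp_present_left <- c(1, 1, 0, 1, 0, 0, 1, 1)
  raw$cvemp_present_right <- c(1, 0, 0, 1, 1, 0, 1, 1)

  cont <- suppressMessages(prepare_covariates(raw, "cvemp", "continuous",
                                              standardize = FALSE))
  # both present -> max; single present -> that ear; bilaterally absent -> dropped
  expect_equal(cont$vest[1], 1.5)
  expect_equal(cont$vest[2], 2.0)   # right absent: left ear used
  expect_equal(cont$vest[cont$subject_id == "S005"], 1.4)
  expect_false(any(cont$subject_id %in% c("S003", "S006")))
  expect_equal(attr(cont, "n_dropped"), 2L)

  cat <- prepare_covariates(raw, "cvemp", "categorical")
  expect_equal(cat$vest, c(1, 1, 0, 1, 1, 0, 1, 1))

  # VOR: mean of eyes; impaired strictly below 0.8
  raw$vor_gain_left_eye <- c(0.9, 0.7, 0.79, 0.85, 1.0, 0.6, 0.8, 0.8)
  raw$vor_gain_right_eye <- c(0.7, 0.9, 0.79, 0.75, 1.1, 0.6, 0.8, 0.8)
  vor <- prepare_covariates(raw, "vor", "continuous", standardize = FALSE)
  expect_equal(vor$vest[1], 0.8)
  vcat <- prepare_covariates(raw, "vor", "categorical")
  expect_equal(vcat$vest, c(0, 0, 1, 0, 0, 1, 0, 0))  # 0.8 is unimpaired

  std <- prepare_covariates(raw, "vor", "continuous", standardize = TRUE)
  expect_equal(sd(std$vest), 1, tolerance = 1e-12)
  expect_equal(attr(std, "vest_sd"), sd(vor$vest), tolerance = 1e-12)

  raw$cvemp_present_left <- 0; raw$cvemp_present_right <- 0
  expect_error(prepare_covariates(raw, "cvemp", "continuous"), "no subject")
})

test_that("noise-free responses are interpolated exactly by the alternate model", {
  cov <- data.frame(subject_id = sprintf("S%02d", 1:8),
                    vest = c(0, 1, 2, 3, 0, 1, 2, 3),
                    icv = rep(c(1, -1), 4),           # orthogonal dummy
                    age = rep(c(1, -1, -1, 1), 2),    # orthogonal dummy
                    sex = c(0, 0, 0, 0, 1, 1, 1, 1))
  class(cov) <- c("covariate_table", "data.frame")
  y <- 2 * cov$vest + 1
  fit <- fit_cluster_model(y, cov)
  expect_equal(fit$c_v, 2, tolerance = 1e-9)
  expect_equal(fit$c_0, 1, tolerance = 1e-9)
  expect_equal(fit$c_i, 0, tolerance = 1e-9)
  expect_equal(fit$c_a, 0, tolerance = 1e-9)
  expect_lt(fit$sse_alt, 1e-18)
})

test_that("least-squares fits agree with the pseudo-inverse oracle on 50 random designs", {
  withr::with_seed(101, {
    for (r in 1:50) {
      cov <- data.frame(subject_id = sprintf("S%02d", 1:10),
                        vest = rnorm(10), icv = rnorm(10, 1200, 100),
                        age = rnorm(10, 75, 8), sex = rbinom(10, 1, 0.5))
      if (length(unique(cov$sex)) == 1L) cov$sex[1] <- 1 - cov$sex[1]
      class(cov) <- c("covariate_table", "data.frame")
      y <- rnorm(10)
      fit <- fit_cluster_model(y, cov)
      XA <- cbind(cov$vest, 1, cov$icv, cov$age, cov$sex)
      X0 <- XA[, -1]
      oa <- ols_oracle(XA, y); o0 <- ols_oracle(X0, y)
      expect_equal(fit$c_v, oa$coef[1], tolerance = 1e-8)
      expect_equal(c(fit$c_0, fit$c_i, fit$c_a, fit$c_s), oa$coef[2:5],
                   tolerance = 1e-8)
      expect_equal(fit$sse_alt, oa$sse, tolerance = 1e-8)
      expect_equal(fit$sse_null, o0$sse, tolerance = 1e-8)
      expect_lte(fit$sse_alt, fit$sse_null + 1e-12)
    }
  })
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  cov <- data.frame(subject_id = sprintf("S%02d", 1:8),
                    vest = c(0, 0, 0, 0, 1, 1, 1, 1),
                    icv = rnorm(8, 1200, 50), age = rnorm(8, 75, 5),
                    sex = c(0, 0, 0, 0, 1, 1, 1, 1))  # vest duplicates sex
  class(cov) <- c("covariate_table", "data.frame")
  expect_error(fit_cluster_model(rnorm(8), cov), "rank-deficient")
  expect_error(fit_cluster_model(rnorm(4), cov[1:4, ]), ">= 6 subjects")
})

test_that("the max-SSE-ratio statistic matches its definition and stays >= 1 on nested fits", {
  expect_equal(perm_statistic(c(4, 9, 1), c(2, 3, 1)), 3.0)
  expect_equal(perm_statistic(c(4, 9, 1), c(4, 9, 1)), 1.0)
  expect_equal(perm_statistic(c(4, 9, 1), c(2, 3, 1), "max_of_ratios"), 3.0)
  expect_equal(perm_statistic(c(8, 2), c(2, 2), "max_of_ratios"), 4.0)
  expect_error(perm_statistic(c(1, 2), c(1, 0)), "non-positive")
  expect_error(perm_statistic(c(1, 2), c(1)), "equal-length")

  withr::with_seed(21, {
    for (r in 1:20) {
      cov <- data.frame(subject_id = 1:12, vest = rnorm(12),
                        icv = rnorm(12), age = rnorm(12),
                        sex = rbinom(12, 1, 0.5))
      class(cov) <- c("covariate_table", "data.frame")
      Y <- matrix(rnorm(36), 12, 3)
      fits <- apply(Y, 2, fit_cluster_model, cov = cov)
      t <- perm_statistic(vapply(fits, `[[`, numeric(1), "sse_null"),
                          vapply(fits, `[[`, numeric(1), "sse_alt"))
      expect_gte(t, 1)
    }
  })
})

test_that("the fast permutation path reproduces naive whole-model refits exactly", {
  withr::with_seed(77, {
    cov <- data.frame(subject_id = sprintf("S%02d", 1:20), vest = rnorm(20),
                      icv = rnorm(20, 1200, 100), age = rnorm(20, 75, 8),
                      sex = rbinom(20, 1, 0.4))
    class(cov) <- c("covariate_table", "data.frame")
    Y <- matrix(rnorm(80), 20, 4)
  })
  fast <- permutation_test(Y, cov, n_perm = 99, seed = 13)
  naive <- naive_permutation_test(Y, cov, n_perm = 99, seed = 13)
  expect_equal(fast$t_observed, naive$t_observed, tolerance = 1e-10)
  expect_equal(fast$t_null, naive$t_null, tolerance = 1e-10)
  expect_equal(fast$p_perm, naive$p_perm)
})

test_that("permutation p-values are deterministic and invariant to rescaling and cluster relabeling", {
  withr::with_seed(31, {
    cov <- data.frame(subject_id = sprintf("S%02d", 1:25), vest = rnorm(25),
                      icv = rnorm(25, 1200, 100), age = rnorm(25, 75, 8),
                      sex = rbinom(25, 1, 0.4))
    class(cov) <- c("covariate_table", "data.frame")
    Y <- matrix(rnorm(100), 25, 4)
  })
  p1 <- permutation_test(Y, cov, n_perm = 199, seed = 4)
  p2 <- permutation_test(Y, cov, n_perm = 199, seed = 4)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_identical(p1$t_null, p2$t_null)

  # common positive rescaling of all descriptor values
  p3 <- permutation_test(Y * 3.7, cov, n_perm = 199, seed = 4)
  expect_equal(p3$p_perm, p1$p_perm)
  expect_equal(p3$t_observed, p1$t_observed, tolerance = 1e-10)

  # relabeling clusters (permuting columns)
  p4 <- permutation_test(Y[, c(3, 1, 4, 2)], cov, n_perm = 199, seed = 4)
  expect_equal(p4$p_perm, p1$p_perm)

  expect_error(permutation_test(Y, cov, n_perm = 50, seed = 1), "n_perm")
})

test_that("percent change converts log-scale coefficients to percentages", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(1.1)), 10, tolerance = 1e-12)
  expect_equal(percent_change(-0.084), -8.0569, tolerance = 1e-4)
})

test_that("report assembly flags non-significant analyses and joins multi-cluster results", {
  expect_equal(nrow(build_report(list())), 0L)
  expect_equal(ncol(build_report(list())), 15L)

  fake <- function(p, sig_cl, cvs) {
    fits <- lapply(seq_along(cvs), function(i) list(cluster_id = i - 1L, c_v = cvs[i]))
    ov <- lapply(seq_along(cvs) - 1L, function(c) {
      data.frame(parcel_id = 4L, name = "ERC-Pr", group = "ERC",
                 fraction = 1, reported = TRUE)
    })
    names(ov) <- as.character(seq_along(cvs) - 1L)
    list(side = "left", variable = "vor", form = "categorical",
         descriptor = "log_surf", n = 90L, k = length(cvs),
         fits = fits, overlap = ov, significant_clusters = sig_cl,
         permutation = list(p_perm = p, n_perm = 999L, seed = 1L,
                            variant = "ratio_of_maxima"))
  }
  rep1 <- build_report(list(a = fake(0.2, integer(0), c(0.1, 0.2))))
  expect_false(rep1$significant)
  expect_equal(rep1$coef, "")

  rep2 <- build_report(list(a = fake(0.01, c(0L, 1L), c(0.25, -0.03))))
  expect_true(rep2$significant)
  expect_equal(rep2$coef, "0.25, -0.03")
  expect_match(rep2$regions, "ERC-Pr; ERC-Pr")
})
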