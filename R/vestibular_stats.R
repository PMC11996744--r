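# Covariate preparation and cluster-wise inference.
#
# For each super-vertex (cluster) c the nested linear models are
#   H0:  jac = c_i ICV + c_a Age + c_s Sex + c_0
#   HA:  jac = c_V Vest + c_i ICV + c_a Age + c_s Sex + c_0
# estimated by ordinary least squares, with jac a log-Jacobian super-vertex
# value.  Family-wise inference across the k clusters uses a permutation
# test on the statistic T = max_c SSE0_c / max_c SSEA_c (ratio of maximum
# squared errors under the null and alternate models); the vestibular
# covariate is permuted across subjects with nuisance covariates fixed.

#' Prepare a modeling covariate table from raw vestibular measures
#'
#' Implements the covariate rules used throughout: for cVEMP and oVEMP the
#' continuous measure is the higher amplitude from either ear with a present
#' response, and the categorical measure codes bilaterally absent (0) versus
#' any present response (1); for VOR the continuous measure is the average
#' gain of the two eyes and the categorical measure codes impaired
#' (mean gain strictly `< 0.8`, coded 1) versus unimpaired (0).  Subjects
#' missing the modeled variable (e.g. bilaterally absent responses under a
#' continuous VEMP form) are dropped with a message.  Continuous variables
#' are standardized to unit SD by default so coefficients read as change per
#' 1 SD increase.
#'
#' @param raw data.frame with columns `subject_id`, `cvemp_left`,
#'   `cvemp_right`, `cvemp_present_left`, `cvemp_present_right`,
#'   `ovemp_left`, `ovemp_right`, `ovemp_present_left`,
#'   `ovemp_present_right`, `vor_gain_left_eye`, `vor_gain_right_eye`,
#'   `age_years`, `sex_female` (1 female / 0 male), `icv`.
#' @param variable one of `"cvemp"`, `"ovemp"`, `"vor"`.
#' @param form `"continuous"` or `"categorical"`.
#' @param standardize scale the continuous vestibular variable to unit SD
#'   (per-1-SD reporting); ignored for categorical forms.
#' @param impaired_threshold VOR gain threshold for the impaired category
#'   (strict inequality; default 0.8).
#' @return data.frame of class `covariate_table` with columns `subject_id`,
#'   `vest`, `icv`, `age`, `sex`, plus attributes `variable`, `form`,
#'   `n_dropped`, and `vest_sd` (the SD divided out, or `NA`).
#' @export
prepare_covariates <- function(raw, variable = c("cvemp", "ovemp", "vor"),
                               form = c("continuous", "categorical"),
                               standardize = TRUE, impaired_threshold = 0.8) {
  variable <- match.arg(variable)
  form <- match.arg(form)
  need <- c("subject_id", "age_years", "sex_female", "icv")
  if (any(!need %in% names(raw))) {
    stopf("prepare_covariates: missing column(s) %s",
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  if (variable %in% c("cvemp", "ovemp")) {
    amp <- cbind(raw[[paste0(variable, "_left")]], raw[[paste0(variable, "_right")]])
    pres <- cbind(raw[[paste0(variable, "_present_left")]] > 0,
                  raw[[paste0(variable, "_present_right")]] > 0)
    any_present <- pres[, 1L] | pres[, 2L]
    if (form == "categorical") {
      vest <- as.numeric(any_present)  # 0 iff bilaterally absent
    } else {
      best <- ifelse(pres[, 1L] & pres[, 2L], pmax(amp[, 1L], amp[, 2L]),
                     ifelse(pres[, 1L], amp[, 1L],
                            ifelse(pres[, 2L], amp[, 2L], NA_real_)))
      vest <- best
    }
  } else {
    gain <- (raw$vor_gain_left_eye + raw$vor_gain_right_eye) / 2
    vest <- if (form == "categorical") as.numeric(gain < impaired_threshold) else gain
  }
  keep <- !is.na(vest) & !is.na(raw$age_years) & !is.na(raw$icv) & !is.na(raw$sex_female)
  n_dropped <- sum(!keep)
  if (all(!keep)) stopf("prepare_covariates: no subject has the '%s' variable measured", variable)
  if (n_dropped > 0) {
    message(sprintf("prepare_covariates: dropped %d subject(s) missing %s (%s)",
                    n_dropped, variable, form))
  }
  vest <- vest[keep]
  vest_sd <- NA_real_
  if (form == "continuous" && standardize) {
    vest_sd <- stats::sd(vest)
    if (!is.finite(vest_sd) || vest_sd == 0) stopf("prepare_covariates: vestibular variable has zero variance")
    vest <- vest / vest_sd
  }
  sex <- as.numeric(raw$sex_female[keep])
  if (any(!sex %in% c(0, 1))) stopf("prepare_covariates: sex_female must be coded 0/1")
  out <- data.frame(subject_id = raw$subject_id[keep], vest = vest,
                    icv = raw$icv[keep], age = raw$age_years[keep], sex = sex)
  if (any(out$icv <= 0)) stopf("prepare_covariates: non-positive ICV")
  if (any(out$age <= 0)) stopf("prepare_covariates: non-positive age")
  class(out) <- c("covariate_table", "data.frame")
  attr(out, "variable") <- variable
  attr(out, "form") <- form
  attr(out, "n_dropped") <- n_dropped
  attr(out, "vest_sd") <- vest_sd
  out
}

# Null-model design matrix (intercept + nuisance covariates).
null_design <- function(cov) {
  cbind("(Intercept)" = 1, icv = cov$icv, age = cov$age, sex = cov$sex)
}

#' Fit the nested cluster models by least squares
#'
#' Ordinary least squares for the null model (ICV, age, sex, intercept) and
#' the alternate model (the vestibular variable plus the same nuisances).
#' Returns both coefficient sets and residual sums of squares; by nesting,
#' `sse_alt <= sse_null` always.
#'
#' @param y numeric response vector, one super-vertex column.
#' @param cov a `covariate_table` aligned with `y`.
#' @param cluster_id optional id recorded on the result.
#' @return object of class `cluster_model`: list with `cluster_id`,
#'   coefficients `c_v`, `c_i`, `c_a`, `c_s`, `c_0`, `sse_null`, `sse_alt`,
#'   and `n`.
#' @export
fit_cluster_model <- function(y, cov, cluster_id = NA_integer_) {
  n <- length(y)
  if (n != nrow(cov)) stopf("fit_cluster_model: %d responses for %d subjects", n, nrow(cov))
  if (n < 6L) stopf("fit_cluster_model: need >= 6 subjects, got %d", n)
  X0 <- null_design(cov)
  XA <- cbind(vest = cov$vest, X0)
  qa <- qr(XA)
  if (qa$rank < ncol(XA)) {
    piv <- qa$pivot[seq_len(qa$rank)]
    stopf("fit_cluster_model: rank-deficient design; aliased column(s): %s",
          paste(setdiff(colnames(XA), colnames(XA)[piv]), collapse = ", "))
  }
  f0 <- stats::lm.fit(X0, y)
  fa <- stats::lm.fit(XA, y)
  ca <- fa$coefficients
  structure(list(cluster_id = cluster_id,
                 c_v = unname(ca["vest"]), c_i = unname(ca["icv"]),
                 c_a = unname(ca["age"]), c_s = unname(ca["sex"]),
                 c_0 = unname(ca["(Intercept)"]),
                 sse_null = sum(f0$residuals^2),
                 sse_alt = sum(fa$residuals^2),
                 n = n),
            class = "cluster_model")
}

#' Max-SSE-ratio permutation statistic
#'
#' The default `"ratio_of_maxima"` reading is
#' `T = max(sse_null) / max(sse_alt)` over clusters; the alternative
#' `"max_of_ratios"` reading, `T = max(sse_null / sse_alt)`, is kept behind
#' this switch for sensitivity analysis.  For nested least-squares fits
#' `T >= 1` under either reading.
#'
#' @param sse_null,sse_alt positive numeric vectors of per-cluster residual
#'   sums of squares under the null and alternate models.
#' @param variant `"ratio_of_maxima"` (default) or `"max_of_ratios"`.
#' @return scalar test statistic.
#' @export
perm_statistic <- function(sse_null, sse_alt,
                           variant = c("ratio_of_maxima", "max_of_ratios")) {
  variant <- match.arg(variant)
  if (length(sse_null) != length(sse_alt) || length(sse_null) < 1L) {
    stopf("perm_statistic: need equal-length non-empty SSE vectors")
  }
  if (any(sse_alt <= 0)) stopf("perm_statistic: degenerate fit, non-positive alternate SSE")
  if (any(sse_null <= 0)) stopf("perm_statistic: degenerate fit, non-positive null SSE")
  switch(variant,
         ratio_of_maxima = max(sse_null) / max(sse_alt),
         max_of_ratios = max(sse_null / sse_alt))
}

# Orthonormal basis of the null design's column space, for fast repeated
# residualization during permutation.
null_projector <- function(cov) {
  qr.Q(qr(null_design(cov)))
}

resid_on_null <- function(M, Q0) M - Q0 %*% crossprod(Q0, M)

#' Permutation test with family-wise error control
#'
#' Computes the observed statistic from the unpermuted data, then for each of
#' `n_perm` replicates permutes the vestibular column across subjects
#' (nuisance covariates and responses fixed), refits all k cluster models,
#' and recomputes the statistic.  The p-value uses the add-one convention
#' `p = (1 + #\{T_perm >= T_obs\}) / (n_perm + 1)`, which recovers "the
#' fraction of replicates greater than the observed statistic" as
#' `n_perm` grows and can never be exactly zero; ties count against
#' rejection (">=", the conservative choice).
#'
#' Internally the replicate refits use the exact algebraic shortcut for
#' adding one regressor to a fixed null model (residualize the permuted
#' vestibular column against the null design, then subtract the squared
#' scaled covariance from the null SSE), which is identical to refitting the
#' alternate model by least squares but avoids `n_perm * k` full
#' decompositions.
#'
#' @param sv a `supervertex_matrix` (or plain subjects x k matrix).
#' @param cov a `covariate_table` row-aligned with `sv`.
#' @param n_perm number of permutation replicates (>= 99).
#' @param seed integer seed; the replicate permutations are drawn under it.
#' @param variant statistic variant, see [perm_statistic()].
#' @param scheme `"label"` permutes the raw vestibular column (default);
#'   `"freedman_lane"` permutes null-model residuals of the vestibular
#'   column instead (equivalent here because the statistic only involves
#'   vest through its null residual, but kept explicit as an opt-in).
#' @return object of class `permutation_result`: list with `t_observed`,
#'   `t_null` (length `n_perm`), `p_perm`, `n_perm`, `seed`, `variant`,
#'   `sse_null`, `sse_alt` (observed per-cluster values), and `fits`
#'   (per-cluster `cluster_model` objects).
#' @export
permutation_test <- function(sv, cov, n_perm = 999L, seed = 1L,
                             variant = c("ratio_of_maxima", "max_of_ratios"),
                             scheme = c("label", "freedman_lane")) {
  variant <- match.arg(variant)
  scheme <- match.arg(scheme)
  Y <- if (inherits(sv, "supervertex_matrix")) sv$values else as.matrix(sv)
  if (!is_count(n_perm) || n_perm < 99L) stopf("permutation_test: n_perm must be >= 99")
  n <- nrow(Y); k <- ncol(Y)
  if (n != nrow(cov)) stopf("permutation_test: %d subjects in sv, %d in covariates", n, nrow(cov))

  fits <- lapply(seq_len(k), function(c) fit_cluster_model(Y[, c], cov, cluster_id = c - 1L))
  sse_null <- vapply(fits, `[[`, numeric(1), "sse_null")
  sse_alt <- vapply(fits, `[[`, numeric(1), "sse_alt")
  t_obs <- perm_statistic(sse_null, sse_alt, variant)

  Q0 <- null_projector(cov)
  RY <- resid_on_null(Y, Q0)            # null residuals of responses (n x k)
  v_base <- if (scheme == "freedman_lane") {
    as.numeric(resid_on_null(matrix(cov$vest, ncol = 1L), Q0))
  } else cov$vest
  t_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      vp <- v_base[sample.int(n)]
      rv <- as.numeric(resid_on_null(matrix(vp, ncol = 1L), Q0))
      den <- sum(rv^2)
      if (den <= 0) return(1)          # permuted vest aliased with nuisances
      gain <- as.numeric(crossprod(rv, RY))^2 / den
      perm_statistic(sse_null, pmax(sse_null - gain, .Machine$double.eps), variant)
    }, numeric(1))
  })
  p <- (1 + sum(t_null >= t_obs)) / (n_perm + 1)
  structure(list(t_observed = t_obs, t_null = t_null, p_perm = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 variant = variant, scheme = scheme,
                 sse_null = sse_null, sse_alt = sse_alt, fits = fits),
            class = "permutation_result")
}

#' Percent change implied by a log-Jacobian coefficient
#'
#' For an outcome on the natural-log scale, a coefficient `c_v` corresponds
#' to a multiplicative change `exp(c_v)`, i.e. `100 * (exp(c_v) - 1)`
#' percent.  The raw coefficient should always be reported alongside.
#'
#' @param c_v numeric coefficient(s) on a log-Jacobian outcome.
#' @return percentage change(s).
#' @examples
#' percent_change(log(1.1))  # 10
#' @export
percent_change <- function(c_v) 100 * (exp(c_v) - 1)

#' Assemble report rows from completed analyses
#'
#' One row per analysis (side x variable x form x descriptor).  Clusters
#' significant at `alpha` are listed with comma-joined coefficients, percent
#' changes, and their dominant parcellation regions; analyses with no
#' significant cluster are retained with `significant = FALSE`.
#'
#' @param analyses list of analysis results as returned by [run_analysis()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns `side`, `variable`, `form`, `descriptor`,
#'   `significant`, `clusters`, `coef`, `pct_change`, `regions`, `p_perm`,
#'   `n`, `n_perm`, `k`, `statistic`, `seed`.
#' @export
build_report <- function(analyses, alpha = 0.05) {
  if (length(analyses) == 0L) {
    return(data.frame(side = character(), variable = character(),
                      form = character(), descriptor = character(),
                      significant = logical(), clusters = character(),
                      coef = character(), pct_change = character(),
                      regions = character(), p_perm = numeric(),
                      n = integer(), n_perm = integer(), k = integer(),
                      statistic = character(), seed = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(analyses, function(a) {
    pr <- a$permutation
    sig <- pr$p_perm <= alpha
    sig_cl <- if (sig) a$significant_clusters else integer(0)
    fmt_join <- function(x) paste(sprintf("%.4g", x), collapse = ", ")
    coefs <- vapply(sig_cl, function(c) a$fits[[c + 1L]]$c_v, numeric(1))
    regions <- vapply(sig_cl, function(c) {
      ov <- a$overlap[[as.character(c)]]
      paste(ov$name[ov$reported], collapse = "+")
    }, character(1))
    data.frame(side = a$side, variable = a$variable, form = a$form,
               descriptor = a$descriptor, significant = sig,
               clusters = paste(sig_cl, collapse = ", "),
               coef = fmt_join(coefs),
               pct_change = fmt_join(percent_change(coefs)),
               regions = paste(regions, collapse = "; "),
               p_perm = pr$p_perm, n = a$n, n_perm = pr$n_perm,
               k = a$k, statistic = pr$variant, seed = pr$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
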