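# Per-vertex deformation descriptors for a corresponded template/target pair.
#
# Three scalars summarise how a smooth orientation-preserving map deforms the
# surface near a vertex:
#   * surface Jacobian  -- ratio of attached-face (one-ring) area after vs
#     before the map: expansion/contraction tangent to the surface;
#   * Jacobian determinant -- volume-change factor of the ambient 3D map;
#   * normal Jacobian   -- determinant / surface Jacobian: stretch of an
#     infinitesimal line normal to the surface.
# The surface and normal log-Jacobians are the quantities entering the
# statistical models; a positive log value denotes expansion.

#' Evaluable deformation field
#'
#' Wraps a map of 3D space as an evaluable function, optionally with its
#' analytic spatial gradient.  `fun` takes an `n x 3` matrix of points and
#' returns the mapped `n x 3` matrix; `grad`, if given, returns a
#' `3 x 3 x n` array of Jacobian matrices (d output_i / d input_j).
#'
#' @param fun function mapping an `n x 3` point matrix to an `n x 3` matrix.
#' @param grad optional function returning a `3 x 3 x n` gradient array.
#' @param det optional function returning the analytic per-point determinant
#'   directly (a vectorised shortcut over `grad`).
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(fun, grad = NULL, det = NULL) {
  stopifnot(is.function(fun), is.null(grad) || is.function(grad),
            is.null(det) || is.function(det))
  structure(list(fun = fun, grad = grad, det = det),
            class = "deformation_field")
}

#' Surface Jacobian from corresponded vertex positions
#'
#' Per-vertex ratio of one-ring areas, deformed over template:
#' `one_ring_areas(deformed) / one_ring_areas(template)`.  Strictly positive
#' for any non-degenerate deformed configuration.
#'
#' @param template a `triangle_mesh`.
#' @param deformed_vertices `n x 3` matrix of deformed positions, one row per
#'   template vertex.
#' @return numeric vector of per-vertex surface Jacobians (dimensionless).
#' @export
surface_jacobian <- function(template, deformed_vertices) {
  deformed_vertices <- as.matrix(deformed_vertices)
  if (nrow(deformed_vertices) != nrow(template$vertices)) {
    stopf("surface_jacobian: %d deformed vertices for a %d-vertex template",
          nrow(deformed_vertices), nrow(template$vertices))
  }
  a_def <- triangle_areas(template, deformed_vertices)
  bad <- which(a_def <= 0 | !is.finite(a_def))
  if (length(bad)) {
    stopf("surface_jacobian: degenerate deformed face %d (zero area)", bad[1L])
  }
  acc <- numeric(nrow(template$vertices))
  f <- template$faces
  for (j in 1:3) {
    s <- rowsum(a_def, group = f[, j])
    idx <- as.integer(rownames(s))
    acc[idx] <- acc[idx] + s[, 1L]
  }
  acc / one_ring_areas(template)
}

#' Jacobian determinant of a deformation field at sample points
#'
#' Uses the field's analytic determinant or gradient when available;
#' otherwise a second-order central finite difference with step `step` along
#' each axis.  The numeric path remains available for cross-checking via
#' `use_analytic = FALSE`.
#'
#' @param field a `deformation_field`.
#' @param points `n x 3` matrix of evaluation points.
#' @param step finite-difference step in mm; default `1e-3` times the
#'   bounding-box diagonal of `points`.
#' @param use_analytic use the analytic gradient if the field carries one.
#' @return numeric vector of per-point determinants.
#' @export
det_jacobian <- function(field, points, step = NULL, use_analytic = TRUE) {
  stopifnot(inherits(field, "deformation_field"))
  points <- as.matrix(points)
  n <- nrow(points)
  if (use_analytic && !is.null(field$det)) return(field$det(points))
  if (use_analytic && !is.null(field$grad)) {
    G <- field$grad(points)
    return(vapply(seq_len(n), function(i) det(G[, , i]), numeric(1)))
  }
  if (is.null(step)) {
    bbox <- apply(points, 2L, range)
    step <- 1e-3 * sqrt(sum((bbox[2L, ] - bbox[1L, ])^2))
    if (step == 0) step <- 1e-3
  }
  if (step <= 0) stopf("det_jacobian: step must be > 0")
  cols <- vector("list", 3L)
  for (ax in 1:3) {
    hp <- points; hp[, ax] <- hp[, ax] + step
    hm <- points; hm[, ax] <- hm[, ax] - step
    fp <- field$fun(hp); fm <- field$fun(hm)
    if (anyNA(fp) || anyNA(fm)) {
      stopf("det_jacobian: field not evaluable near point %d",
            which(rowSums(is.na(fp) | is.na(fm)) > 0)[1L])
    }
    cols[[ax]] <- (fp - fm) / (2 * step)
  }
  # det of [dF/dx | dF/dy | dF/dz] per point, expanded explicitly.
  a <- cols[[1L]]; b <- cols[[2L]]; c3 <- cols[[3L]]
  a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
    b[, 1L] * (a[, 2L] * c3[, 3L] - a[, 3L] * c3[, 2L]) +
    c3[, 1L] * (a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L])
}

#' Normal Jacobian
#'
#' Element-wise ratio of the Jacobian determinant to the surface Jacobian:
#' the stretch factor normal to the surface.
#'
#' @param det numeric vector of per-vertex Jacobian determinants.
#' @param surf numeric vector of per-vertex surface Jacobians (must be > 0).
#' @return numeric vector `det / surf`.
#' @export
normal_jacobian <- function(det, surf) {
  if (length(det) != length(surf)) stopf("normal_jacobian: length mismatch")
  if (any(surf <= 0 | !is.finite(surf))) {
    stopf("normal_jacobian: non-positive surface Jacobian at vertex %d",
          which(surf <= 0 | !is.finite(surf))[1L])
  }
  det / surf
}

#' Assemble per-vertex Jacobian descriptor fields
#'
#' Computes the surface Jacobian from the corresponded pair and the
#' determinant either from a `deformation_field` (synthetic/analytic path) or
#' from per-vertex values supplied directly (the real-data path, where the
#' registration pipeline reports a determinant per vertex).  The normal
#' Jacobian is their ratio, so `normal * surf == det` holds exactly by
#' construction.
#'
#' @param template a `triangle_mesh`.
#' @param deformed_vertices `n x 3` deformed vertex positions.
#' @param field optional `deformation_field` used to obtain determinants.
#' @param det optional numeric vector of per-vertex determinants (used when
#'   no field is available).
#' @param step finite-difference step forwarded to [det_jacobian()].
#' @return object of class `jacobian_fields` with elements `surf`, `det`,
#'   `normal`, `log_surf`, `log_normal`, and `boundary` (logical flag of
#'   boundary vertices on open patches, to be excluded from statistics).
#' @export
jacobian_fields <- function(template, deformed_vertices, field = NULL,
                            det = NULL, step = NULL) {
  surf <- surface_jacobian(template, deformed_vertices)
  if (is.null(det)) {
    if (is.null(field)) stopf("jacobian_fields: supply either `field` or per-vertex `det`")
    det <- det_jacobian(field, template$vertices, step = step)
  }
  if (length(det) != length(surf)) stopf("jacobian_fields: `det` length mismatch")
  normal <- normal_jacobian(det, surf)
  det <- normal * surf  # re-derive so normal * surf == det holds bitwise
  jf <- structure(list(surf = surf, det = det, normal = normal,
                       log_surf = NULL, log_normal = NULL,
                       boundary = boundary_vertices(template)),
                  class = "jacobian_fields")
  log_fields(jf)
}

#' Populate the log-descriptor fields
#'
#' Natural logarithms of the (positive) surface and normal Jacobians.  A
#' positive `log_surf` denotes tangent expansion, negative contraction; same
#' sign convention for `log_normal` in the normal direction.
#'
#' @param jac a `jacobian_fields` object.
#' @return `jac` with `log_surf` and `log_normal` filled in.
#' @export
log_fields <- function(jac) {
  stopifnot(inherits(jac, "jacobian_fields"))
  if (any(jac$surf <= 0)) stopf("log_fields: non-positive surface Jacobian")
  if (any(jac$normal <= 0)) stopf("log_fields: non-positive normal Jacobian")
  jac$log_surf <- log(jac$surf)
  jac$log_normal <- log(jac$normal)
  jac
}

#' Write per-vertex descriptors for one subject as CSV
#'
#' Columns: `subject_id, vertex_id, surf_jac, det_jac, normal_jac, log_surf,
#' log_normal` with 0-based `vertex_id`, matching the on-disk mesh indexing.
#'
#' @param jac a `jacobian_fields` object.
#' @param subject_id subject identifier.
#' @param path output CSV path (appends when the file exists headerlessly if
#'   `append = TRUE`).
#' @param append logical.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(jac, subject_id, path, append = FALSE) {
  df <- data.frame(subject_id = subject_id,
                   vertex_id = seq_along(jac$surf) - 1L,
                   surf_jac = jac$surf, det_jac = jac$det,
                   normal_jac = jac$normal,
                   log_surf = jac$log_surf, log_normal = jac$log_normal)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}
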