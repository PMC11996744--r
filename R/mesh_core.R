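#' Construct a triangle mesh
#'
#' A `triangle_mesh` stores an oriented triangulated 2-manifold: an `n x 3`
#' matrix of vertex coordinates (millimetres) and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangular face.  An optional integer
#' vector of per-vertex parcel labels may be attached.  On construction the
#' mesh is validated against the structural invariants required downstream:
#' in-range face indices, no degenerate faces, no isolated vertices,
#' consistent orientation, and strictly positive triangle areas.
#'
#' @param vertices numeric matrix (`n x 3`) of vertex coordinates in mm.
#' @param faces integer matrix (`m x 3`) of 1-based vertex indices.
#' @param labels optional integer vector of length `n` with parcel ids.
#' @param validate logical; run [validate_mesh()] (default `TRUE`).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and (optionally) `labels`.
#' @examples
#' m <- tetrahedron_mesh()
#' nrow(m$vertices)  # 4
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stopf("`vertices` must have 3 columns, got %d", ncol(vertices))
  if (ncol(faces) != 3L) stopf("`faces` must have 3 columns, got %d", ncol(faces))
  mesh <- structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
  if (!is.null(labels)) {
    if (length(labels) != nrow(vertices)) {
      stopf("`labels` must have one entry per vertex (%d), got %d",
            nrow(vertices), length(labels))
    }
    mesh$labels <- as.integer(labels)
  }
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$labels)) sprintf(", %d parcel labels", length(unique(x$labels))) else ""))
  invisible(x)
}

#' Validate triangle-mesh invariants
#'
#' Checks that every face index refers to an existing vertex, that no face
#' repeats a vertex, that every vertex belongs to at least one face, that the
#' orientation is consistent (each interior edge traversed in opposite
#' directions by its two incident faces, no edge shared by more than two
#' faces), and that all triangle areas are strictly positive.  Fails with an
#' error naming the violated check.
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh`, invisibly.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (n < 3L || nrow(f) < 1L) stopf("mesh validation failed [size]: need >= 3 vertices and >= 1 face")
  if (anyNA(v) || any(!is.finite(v))) stopf("mesh validation failed [coordinates]: non-finite vertex coordinate")
  if (anyNA(f)) stopf("mesh validation failed [face-index]: NA face index")
  if (any(f < 1L) || any(f > n)) {
    bad <- which(rowSums(f < 1L | f > n) > 0L)[1L]
    stopf("mesh validation failed [face-index]: face %d refers to a vertex outside 1..%d", bad, n)
  }
  deg <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  if (any(deg)) stopf("mesh validation failed [degenerate-face]: face %d repeats a vertex", which(deg)[1L])
  used <- tabulate(f, nbins = n)
  if (any(used == 0L)) stopf("mesh validation failed [isolated-vertex]: vertex %d belongs to no face", which(used == 0L)[1L])
  # Orientation: collect directed half-edges; a directed edge may appear at
  # most once, and each undirected edge at most twice (opposite directions).
  he_from <- c(f[, 1L], f[, 2L], f[, 3L])
  he_to <- c(f[, 2L], f[, 3L], f[, 1L])
  dir_key <- (he_from - 1) * n + he_to
  if (anyDuplicated(dir_key)) {
    stopf("mesh validation failed [orientation]: a directed edge appears twice (inconsistent winding)")
  }
  und_key <- pmin(he_from, he_to) * (n + 1) + pmax(he_from, he_to)
  cnt <- table(und_key)
  if (any(cnt > 2L)) stopf("mesh validation failed [manifold]: an edge is shared by more than two faces")
  a <- triangle_areas(mesh)
  if (any(a <= 0 | !is.finite(a))) {
    stopf("mesh validation failed [area]: face %d has non-positive area", which(a <= 0 | !is.finite(a))[1L])
  }
  invisible(mesh)
}

# Per-face triangle areas (mm^2), vectorised cross product.
triangle_areas <- function(mesh, vertices = mesh$vertices) {
  f <- mesh$faces
  p1 <- vertices[f[, 1L], , drop = FALSE]
  e1 <- vertices[f[, 2L], , drop = FALSE] - p1
  e2 <- vertices[f[, 3L], , drop = FALSE] - p1
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' One-ring vertex areas
#'
#' For each vertex, the sum of the full areas of all faces incident to it
#' (the "attached-face" area).  Summed over all vertices this triple-counts
#' each face, so `sum(one_ring_areas(m)) == 3 * sum(triangle areas)`.  The
#' full-incident-area convention is used consistently for both the template
#' and the deformed surface, so the convention cancels in the surface
#' Jacobian ratio.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertices optional replacement coordinates (same topology), e.g. a
#'   deformed configuration of the same mesh.
#' @return numeric vector of per-vertex areas in mm^2, strictly positive.
#' @export
one_ring_areas <- function(mesh, vertices = mesh$vertices) {
  a <- triangle_areas(mesh, vertices)
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  for (j in 1:3) {
    acc <- rowsum(a, group = f[, j])
    idx <- as.integer(rownames(acc))
    out[idx] <- out[idx] + acc[, 1L]
  }
  out
}

# Unique undirected edges of a mesh as a 2-column matrix (i < j).
mesh_edge_list <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Vertices on the boundary of an open mesh
#'
#' A boundary vertex is an endpoint of an edge incident to exactly one face.
#' Closed surfaces have none.  Boundary vertices are flagged so statistics on
#' open patches can exclude them.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical vector, one entry per vertex.
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) * (n + 1) + pmax(e[, 1L], e[, 2L])
  once <- names(which(table(key) == 1L))
  out <- logical(n)
  if (length(once)) {
    k <- as.numeric(once)
    out[c(k %/% (n + 1), k %% (n + 1))] <- TRUE
  }
  out
}

#' Rigid (Kabsch) alignment of paired point sets
#'
#' Finds the rotation and translation minimising the sum of squared
#' distances between paired points, with reflections excluded (the recovered
#' rotation always has determinant +1).  Scaling is deliberately not
#' estimated: overall size is handled statistically via the intracranial
#' volume covariate, not geometrically.
#'
#' @param moving numeric matrix (`n x 3`) of points to move.
#' @param fixed numeric matrix of target points, paired row-by-row with
#'   `moving` (after applying `correspondence`).
#' @param correspondence optional integer vector: `fixed[correspondence[i], ]`
#'   is the partner of `moving[i, ]`.  Defaults to identity pairing.
#' @return list with `aligned` (transformed `moving`), `rotation` (3 x 3,
#'   det +1), `translation` (length 3), and `rmsd` after alignment.
#' @examples
#' m <- tetrahedron_mesh()
#' th <- pi / 6
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' moved <- m$vertices %*% t(R) + rep(c(1, 2, 3), each = 4)
#' rigid_align(moved, m$vertices)$rmsd  # ~1e-16
#' @export
rigid_align <- function(moving, fixed, correspondence = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!is.null(correspondence)) fixed <- fixed[correspondence, , drop = FALSE]
  if (nrow(moving) == 0L || nrow(fixed) == 0L) stopf("rigid_align: empty point set")
  if (nrow(moving) != nrow(fixed)) stopf("rigid_align: point sets differ in size under the pairing")
  if (nrow(moving) < 3L) stopf("rigid_align: degenerate geometry, need >= 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2L, cm); B <- sweep(fixed, 2L, cf)
  # Collinearity check: rank of the centred moving cloud.
  if (qr(A)$rank < 2L) stopf("rigid_align: degenerate geometry, points are collinear")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cf - R %*% cm)
  aligned <- moving %*% t(R) + rep(t_vec, each = nrow(moving))
  list(aligned = aligned,
       rotation = R,
       translation = t_vec,
       rmsd = sqrt(mean(rowSums((aligned - fixed)^2))))
}

#' Corresponded mesh cohort
#'
#' Bundles a template mesh with per-subject vertex positions that all share
#' the template topology (same vertex count and faces), the substrate for
#' vertex-wise shape descriptors.
#'
#' @param template a `triangle_mesh`.
#' @param subject_vertices named list of `n x 3` matrices, one per subject.
#' @return object of class `corresponded_cohort`.
#' @export
corresponded_cohort <- function(template, subject_vertices) {
  if (length(subject_vertices) == 0L) stopf("corresponded_cohort: empty cohort")
  n <- nrow(template$vertices)
  for (i in seq_along(subject_vertices)) {
    sv <- as.matrix(subject_vertices[[i]])
    if (nrow(sv) != n || ncol(sv) != 3L) {
      stopf("corresponded_cohort: subject %d has %d x %d vertices, template has %d x 3",
            i, nrow(sv), ncol(sv), n)
    }
    subject_vertices[[i]] <- sv
  }
  if (is.null(names(subject_vertices))) {
    names(subject_vertices) <- sprintf("S%03d", seq_along(subject_vertices))
  }
  structure(list(template = template, subject_vertices = subject_vertices),
            class = "corresponded_cohort")
}

#' Mean-shape template from a corresponded cohort
#'
#' Rigidly aligns every subject to the first cohort member (one pass, no
#' iterative re-referencing) and averages vertex positions; the faces are
#' copied from the shared topology.  Set `align = FALSE` if the cohort is
#' already rigidly aligned.
#'
#' @param cohort a `corresponded_cohort`.
#' @param align logical; rigidly align to the first subject first.
#' @return a `triangle_mesh` whose vertices are the per-vertex means.
#' @export
mean_shape <- function(cohort, align = TRUE) {
  svs <- cohort$subject_vertices
  if (length(svs) == 0L) stopf("mean_shape: empty cohort")
  ref <- svs[[1L]]
  acc <- matrix(0, nrow(ref), 3L)
  for (sv in svs) {
    if (align) sv <- rigid_align(sv, ref)$aligned
    acc <- acc + sv
  }
  triangle_mesh(acc / length(svs), cohort$template$faces,
                labels = cohort$template$labels)
}

#' Regular tetrahedron fixture
#'
#' Unit-edge regular tetrahedron with outward-consistent orientation; handy
#' for analytic-area tests (every one-ring area is `3 * sqrt(3) / 4`).
#'
#' @return a `triangle_mesh` with 4 vertices and 4 faces.
#' @export
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  f <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L), c(2L, 3L, 4L))
  triangle_mesh(v, f)
}
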