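# Spectral super-vertex reduction.  Template vertices are partitioned into k
# clusters using only the surface geometry (a Gaussian kernel on mesh-edge
# lengths), and per-vertex descriptor matrices are reduced to one value per
# cluster -- the cluster maximum -- yielding k "super-vertices" and thus k
# statistical models instead of one per vertex.

#' Geometry-only affinity graph of a template mesh
#'
#' Vertices are graph nodes; edges are the mesh edges, weighted by
#' `exp(-d^2 / sigma^2)` where `d` is the Euclidean edge length and `sigma`
#' the median edge length (scale-adaptive, so uniformly refined meshes of any
#' size get comparable weights).
#'
#' @param template a `triangle_mesh`.
#' @return object of class `mesh_graph` with elements `n`, `edges` (2-col
#'   matrix, i < j), `weights`, `sigma`, and `n_components`.
#' @export
mesh_affinity <- function(template) {
  e <- mesh_edge_list(template)
  d <- sqrt(rowSums((template$vertices[e[, 1L], , drop = FALSE] -
                     template$vertices[e[, 2L], , drop = FALSE])^2))
  sigma <- stats::median(d)
  w <- exp(-(d / sigma)^2)
  g <- structure(list(n = nrow(template$vertices), edges = e, weights = w,
                      sigma = sigma),
                 class = "mesh_graph")
  g$n_components <- n_components(g)
  g
}

#' Build a `mesh_graph` from an explicit edge list
#'
#' Mainly for tests and non-mesh graphs (e.g. path graphs).
#'
#' @param n number of vertices.
#' @param edges 2-column matrix of vertex index pairs (1-based).
#' @param weights positive edge weights (default all 1).
#' @return a `mesh_graph`.
#' @export
vertex_graph <- function(n, edges, weights = rep(1, nrow(edges))) {
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (any(weights <= 0)) stopf("vertex_graph: weights must be positive")
  g <- structure(list(n = n, edges = edges, weights = as.numeric(weights),
                      sigma = NA_real_),
                 class = "mesh_graph")
  g$n_components <- n_components(g)
  g
}

# Connected components via min-label propagation to a fixpoint.
n_components <- function(graph) {
  comp <- seq_len(graph$n)
  if (nrow(graph$edges) == 0L) return(graph$n)
  ends <- c(graph$edges[, 1L], graph$edges[, 2L])
  repeat {
    m <- pmin(comp[graph$edges[, 1L]], comp[graph$edges[, 2L]])
    agg <- tapply(c(m, m), ends, min)
    idx <- as.integer(names(agg))
    comp_new <- comp
    comp_new[idx] <- pmin(comp_new[idx], as.integer(agg))
    if (identical(comp_new, comp)) break
    comp <- comp_new
  }
  length(unique(comp))
}

# Dense symmetric normalized Laplacian L = I - D^{-1/2} W D^{-1/2}.
normalized_laplacian <- function(graph) {
  n <- graph$n
  W <- matrix(0, n, n)
  W[graph$edges] <- graph$weights
  W[graph$edges[, c(2L, 1L), drop = FALSE]] <- graph$weights
  dg <- rowSums(W)
  dg[dg == 0] <- 1  # isolated vertices cannot occur on valid meshes
  dm <- 1 / sqrt(dg)
  L <- -W * tcrossprod(dm)
  diag(L) <- 1
  L
}

#' Spectral partition of a vertex graph
#'
#' Normalized-Laplacian embedding (the k eigenvectors of the symmetric
#' normalized Laplacian with smallest eigenvalues, rows normalized to unit
#' length) followed by seeded k-means with 50 restarts.  Deterministic for a
#' fixed seed; if k-means ever yields an empty cluster the seed is bumped by
#' one and the clustering re-run, up to 10 attempts.
#'
#' @param graph a `mesh_graph`.
#' @param k number of clusters (2 <= k <= number of vertices).
#' @param seed integer RNG seed for the k-means restarts.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (per-vertex ids in 0..k-1), `k`, and `seed`.
#' @export
spectral_partition <- function(graph, k, seed = 1L) {
  if (!is_count(k) || k < 2L || k > graph$n) {
    stopf("spectral_partition: k must be an integer in 2..%d, got %s", graph$n, format(k))
  }
  if (!is.null(graph$n_components) && graph$n_components > k) {
    warning(sprintf("graph has %d connected components but k = %d; clusters will merge components",
                    graph$n_components, k), call. = FALSE)
  }
  L <- normalized_laplacian(graph)
  eig <- eigen(L, symmetric = TRUE)
  emb <- eig$vectors[, rev(seq(ncol(L) - k + 1L, ncol(L))), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  for (attempt in 0:9) {
    km <- try(with_seed(seed + attempt,
                        stats::kmeans(emb, centers = k, nstart = 50L, iter.max = 100L)),
              silent = TRUE)
    if (!inherits(km, "try-error") && all(tabulate(km$cluster, k) > 0L)) {
      # Relabel clusters deterministically by their first member vertex so
      # the labeling does not depend on k-means' internal ordering.
      first <- vapply(seq_len(k), function(c) which(km$cluster == c)[1L], integer(1))
      remap <- integer(k)
      remap[order(first)] <- seq_len(k)
      return(structure(list(labels = remap[km$cluster] - 1L, k = k,
                            seed = seed + attempt),
                       class = "cluster_assignment"))
    }
  }
  stopf("spectral_partition: persistent empty cluster after 10 seeded attempts")
}

#' Reduce a descriptor matrix to super-vertex maxima
#'
#' Entry `(i, c)` of the result is the maximum of descriptor values of
#' subject `i` over the vertices assigned to cluster `c`.  The reduction is
#' applied to log-Jacobians; because the log is monotone, max-then-log and
#' log-then-max agree, so the order is immaterial.
#'
#' @param descriptor numeric matrix, subjects x vertices.
#' @param assignment a `cluster_assignment` whose vertex count matches
#'   `ncol(descriptor)`.
#' @param descriptor_name optional name recorded on the result.
#' @return object of class `supervertex_matrix`: list with `values`
#'   (subjects x k matrix, columns named `cluster_0` ...) and
#'   `descriptor_name`.
#' @export
supervertex_reduce <- function(descriptor, assignment, descriptor_name = NULL) {
  descriptor <- as.matrix(descriptor)
  if (ncol(descriptor) != length(assignment$labels)) {
    stopf("supervertex_reduce: descriptor has %d vertices, assignment %d",
          ncol(descriptor), length(assignment$labels))
  }
  k <- assignment$k
  vals <- matrix(NA_real_, nrow(descriptor), k)
  for (c in seq_len(k)) {
    sel <- assignment$labels == c - 1L
    vals[, c] <- apply(descriptor[, sel, drop = FALSE], 1L, max)
  }
  colnames(vals) <- sprintf("cluster_%d", seq_len(k) - 1L)
  rownames(vals) <- rownames(descriptor)
  structure(list(values = vals, descriptor_name = descriptor_name),
            class = "supervertex_matrix")
}

#' Write a cluster assignment as CSV (`vertex_id`, `cluster_id`, 0-based)
#'
#' @param assignment a `cluster_assignment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  df <- data.frame(vertex_id = seq_along(assignment$labels) - 1L,
                   cluster_id = assignment$labels)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
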