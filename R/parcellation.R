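# Krimer-style parcellation of the entorhinal region: nine subregions, of
# which seven are grouped as the entorhinal cortex proper (ERC) and two --
# the sulcal and trans-entorhinal subregions -- as the trans-entorhinal
# cortex (TEC).

#' The nine Krimer subregions and their ERC/TEC grouping
#'
#' @return data.frame with columns `id` (1..9), `name` (ERC-Is, ERC-Ir,
#'   ERC-Ic, ERC-Pr, ERC-Mr, ERC-Mc, ERC-L, ERC-S, TE) and `group`
#'   (`"ERC"` for the first seven, `"TEC"` for ERC-S and TE).
#' @export
krimer_regions <- function() {
  data.frame(
    id = 1:9,
    name = c("ERC-Is", "ERC-Ir", "ERC-Ic", "ERC-Pr", "ERC-Mr", "ERC-Mc",
             "ERC-L", "ERC-S", "TE"),
    group = c(rep("ERC", 7L), "TEC", "TEC"),
    stringsAsFactors = FALSE)
}

#' Construct a parcellation of a template mesh
#'
#' Per-vertex integer parcel ids drawn from the nine Krimer subregions.
#' Validates that exactly the nine ids are defined, that seven map to group
#' ERC and two to TEC, and that every vertex carries exactly one id.
#'
#' @param labels integer vector of per-vertex parcel ids in 1..9.
#' @param require_all logical; demand that all nine parcels be non-empty
#'   (default `TRUE`, the invariant for full templates).
#' @return object of class `parcellation` with elements `labels` and
#'   `regions` (the [krimer_regions()] table).
#' @export
parcellation <- function(labels, require_all = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stopf("parcellation: vertex %d is unlabeled", which(is.na(labels))[1L])
  reg <- krimer_regions()
  if (any(!labels %in% reg$id)) {
    stopf("parcellation: vertex %d carries unknown parcel id %d",
          which(!labels %in% reg$id)[1L], labels[!labels %in% reg$id][1L])
  }
  if (require_all && length(unique(labels)) != 9L) {
    stopf("parcellation: expected all 9 parcels non-empty, found %d",
          length(unique(labels)))
  }
  structure(list(labels = labels, regions = reg), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$regions$id))
  cat("parcellation:", length(x$labels), "vertices\n")
  print(stats::setNames(as.integer(tab), x$regions$name))
  invisible(x)
}

#' Transfer atlas labels to a template by rigid alignment + nearest neighbour
#'
#' Aligns the template to the labeled atlas with an ICP-style loop (closest-
#' point pairing, Kabsch solve, at most `max_iter` iterations), then assigns
#' each template vertex the parcel label of its nearest atlas vertex.  Exact
#' distance ties are broken toward the lowest parcel id.
#'
#' @param atlas a `triangle_mesh` with `labels` on every vertex.
#' @param template a `triangle_mesh` to be labeled.
#' @param max_iter maximum ICP iterations (default 20).
#' @param tol convergence tolerance on the RMSD change (default 1e-10).
#' @return a `parcellation` on the template (non-empty-parcel check relaxed,
#'   since a template may legitimately not touch all atlas parcels).
#' @export
transfer_labels <- function(atlas, template, max_iter = 20L, tol = 1e-10) {
  if (is.null(atlas$labels)) stopf("transfer_labels: atlas vertex 1 is unlabeled (no labels present)")
  if (anyNA(atlas$labels)) {
    stopf("transfer_labels: atlas vertex %d is unlabeled", which(is.na(atlas$labels))[1L])
  }
  av <- atlas$vertices
  tv <- template$vertices
  # initialize by matching centroids so closest-point pairing starts sane
  tv <- sweep(tv, 2L, colMeans(av) - colMeans(tv), "+")
  rmsd_prev <- Inf
  for (it in seq_len(max_iter)) {
    nn <- nearest_vertex(tv, av)
    fit <- rigid_align(tv, av[nn$index, , drop = FALSE])
    tv <- fit$aligned
    if (abs(rmsd_prev - fit$rmsd) < tol) break
    rmsd_prev <- fit$rmsd
  }
  nn <- nearest_vertex(tv, av, labels = atlas$labels)
  parcellation(nn$label, require_all = FALSE)
}

# For each query point, index of the nearest reference point (Euclidean).
# With `labels`, ties at the minimal distance (relative tolerance 1e-9) are
# broken toward the lowest label, then the lowest index.
nearest_vertex <- function(query, ref, labels = NULL) {
  nq <- nrow(query)
  ref2 <- rowSums(ref^2)
  idx <- integer(nq)
  lab <- if (!is.null(labels)) integer(nq) else NULL
  for (i in seq_len(nq)) {
    d2 <- ref2 - 2 * as.numeric(ref %*% query[i, ]) + sum(query[i, ]^2)
    dmin <- min(d2)
    ties <- which(d2 <= dmin + 1e-9 * max(dmin, 1e-12))
    if (!is.null(labels)) {
      ties <- ties[order(labels[ties], ties)]
      lab[i] <- labels[ties[1L]]
    }
    idx[i] <- ties[1L]
  }
  list(index = idx, label = lab)
}

#' Overlap of clusters with parcellation regions
#'
#' For each cluster, the fraction of its vertices lying in each parcel,
#' sorted in descending order.  Fractions always sum to one per cluster; in
#' the rendered report, regions below `floor` are suppressed, but the full
#' breakdown is retained in the returned object.
#'
#' @param cluster_labels integer vector of per-vertex cluster ids.
#' @param parc a `parcellation` on the same vertex set.
#' @param floor reporting floor on the fraction (default 0.10).
#' @return named list (one element per cluster id) of data.frames with
#'   columns `parcel_id`, `name`, `group`, `fraction`, `reported`.
#' @export
region_overlap <- function(cluster_labels, parc, floor = 0.10) {
  if (length(cluster_labels) != length(parc$labels)) {
    stopf("region_overlap: cluster labels cover %d vertices, parcellation %d",
          length(cluster_labels), length(parc$labels))
  }
  reg <- parc$regions
  out <- lapply(sort(unique(cluster_labels)), function(cl) {
    sel <- parc$labels[cluster_labels == cl]
    tab <- table(factor(sel, levels = reg$id))
    frac <- as.numeric(tab) / length(sel)
    df <- data.frame(parcel_id = reg$id, name = reg$name, group = reg$group,
                     fraction = frac, stringsAsFactors = FALSE)
    df <- df[df$fraction > 0, , drop = FALSE]
    df <- df[order(-df$fraction, df$parcel_id), , drop = FALSE]
    df$reported <- df$fraction >= floor
    rownames(df) <- NULL
    df
  })
  names(out) <- as.character(sort(unique(cluster_labels)))
  out
}

#' Write a parcellation as CSV
#'
#' Columns `vertex_id` (0-based), `parcel_id`, `parcel_name`, `group`.
#'
#' @param parc a `parcellation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  reg <- parc$regions
  df <- data.frame(vertex_id = seq_along(parc$labels) - 1L,
                   parcel_id = parc$labels,
                   parcel_name = reg$name[match(parc$labels, reg$id)],
                   group = reg$group[match(parc$labels, reg$id)])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
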