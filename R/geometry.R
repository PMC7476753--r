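#' Mesh edge graph with Euclidean edge weights
#'
#' Builds the undirected graph whose nodes are mesh vertices and whose edges
#' are triangle edges, weighted by Euclidean length in mm. Geodesic distance
#' in this package is shortest-path distance on this graph (the usual
#' parcel-scale approximation, not an exact polyhedral geodesic).
#'
#' @param mesh a [cortical_mesh()].
#' @return An `igraph` graph with edge attribute `weight` (mm).
#' @export
mesh_edge_graph <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) -
                                        igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances from a source vertex
#'
#' Shortest-path distances (mm) on the mesh edge graph from one source
#' vertex to every vertex. Vertices in the other hemisphere (or any
#' disconnected component) get `Inf`, not an error.
#'
#' @param mesh a [cortical_mesh()].
#' @param source_vertex 1-based vertex index.
#' @param graph optional precomputed [mesh_edge_graph()] (saves rebuilding
#'   when querying many sources).
#' @return Numeric vector of length `n_vertices`; `Inf` where unreachable.
#' @export
geodesic_distances <- function(mesh, source_vertex, graph = NULL) {
  n <- nrow(mesh$vertices)
  if (!is.numeric(source_vertex) || length(source_vertex) != 1 ||
      source_vertex < 1 || source_vertex > n) {
    stop("source_vertex must be a single index in 1..", n, call. = FALSE)
  }
  if (is.null(graph)) graph <- mesh_edge_graph(mesh)
  d <- igraph::distances(graph, v = source_vertex, algorithm = "dijkstra")
  as.numeric(d[1, ])
}

#' ROI centroid vertex
#'
#' The parcel vertex minimizing the sum of within-parcel geodesic distances
#' to all other parcel vertices (distances computed on the full mesh graph).
#' Ties are broken by lowest vertex index.
#'
#' @param mesh a [cortical_mesh()].
#' @param parc a [parcellation()].
#' @param roi ROI id.
#' @param graph optional precomputed edge graph.
#' @return The 1-based centroid vertex index.
#' @export
roi_centroid <- function(mesh, parc, roi, graph = NULL) {
  v <- roi_vertices(parc, roi)
  if (length(v) == 1) return(v)
  if (is.null(graph)) graph <- mesh_edge_graph(mesh)
  d <- igraph::distances(graph, v = v, to = v, algorithm = "dijkstra")
  tot <- rowSums(d)
  v[which.min(tot)]  # which.min takes the first, i.e. lowest index (v sorted)
}

#' ROI geometry table: centroids, coordinates, distance axis
#'
#' Computes the centroid vertex and coordinates of every ROI and, when a
#' reference ROI is given, the geodesic distance from each ROI centroid to
#' the reference centroid of the same hemisphere. Cross-hemisphere distances
#' are undefined and reported as `Inf`; supply `reference_roi` as a named
#' vector `c(L = ..., R = ...)` to get a per-hemisphere axis.
#'
#' @param mesh a [cortical_mesh()].
#' @param parc a [parcellation()].
#' @param reference_roi `NULL`, a single ROI id, or a named `c(L=, R=)` pair.
#' @return A tibble (`roi_id`, `hemisphere`, `centroid_vertex`, `x`, `y`,
#'   `z`, `dist_to_reference`).
#' @export
roi_geometry <- function(mesh, parc, reference_roi = NULL) {
  graph <- mesh_edge_graph(mesh)
  ids <- roi_ids(parc)
  cen <- vapply(ids, function(r) roi_centroid(mesh, parc, r, graph = graph),
                integer(1))
  hemi <- vapply(ids, function(r) parc$hemisphere[parc$roi_id == r][1],
                 character(1))
  geom <- tibble::tibble(
    roi_id = ids,
    hemisphere = hemi,
    centroid_vertex = cen,
    x = mesh$vertices[cen, 1],
    y = mesh$vertices[cen, 2],
    z = mesh$vertices[cen, 3],
    dist_to_reference = NA_real_
  )
  if (!is.null(reference_roi)) {
    geom$dist_to_reference <- distance_axis(mesh, parc, geom, reference_roi,
                                            graph = graph)
  }
  geom
}

#' Geodesic distance axis relative to a reference ROI
#'
#' Per-ROI geodesic distance (mm) between each ROI centroid and the centroid
#' of a reference ROI (e.g. a V1-like posterior parcel), the axis used as a
#' leakage-robust stand-in for the posterior-anterior coordinate. Computed
#' per hemisphere: pass a named `c(L=, R=)` reference pair; with a single
#' reference, other-hemisphere ROIs get `Inf`.
#'
#' @inheritParams roi_geometry
#' @param geom a [roi_geometry()] table (centroids already computed).
#' @param graph optional precomputed edge graph.
#' @return Numeric vector aligned with `geom$roi_id`.
#' @export
distance_axis <- function(mesh, parc, geom, reference_roi, graph = NULL) {
  if (is.null(graph)) graph <- mesh_edge_graph(mesh)
  refs <- reference_roi
  if (is.null(names(refs))) {
    if (length(refs) != 1) {
      stop("multiple reference ROIs must be named by hemisphere (L, R)",
           call. = FALSE)
    }
    names(refs) <- geom$hemisphere[match(refs, geom$roi_id)]
  }
  if (any(!refs %in% geom$roi_id)) {
    stop("reference ROI not in parcellation: ",
         paste(setdiff(refs, geom$roi_id), collapse = ", "), call. = FALSE)
  }
  out <- rep(Inf, nrow(geom))
  for (h in names(refs)) {
    ref_vertex <- geom$centroid_vertex[geom$roi_id == refs[[h]]]
    d <- geodesic_distances(mesh, ref_vertex, graph = graph)
    idx <- geom$hemisphere == h
    out[idx] <- d[geom$centroid_vertex[idx]]
  }
  out
}

#' Select ROIs in a distance annulus
#'
#' ROIs whose distance-axis value lies in the closed interval
#' `[rmin, rmax]` — e.g. 20-30 mm from the reference parcel, the control
#' band used to rule out leakage from the reference region itself.
#'
#' @param geom a [roi_geometry()] table with `dist_to_reference` filled in.
#' @param rmin,rmax annulus radii in mm, `rmin < rmax`.
#' @return Character vector of ROI ids (possibly empty).
#' @export
select_annulus <- function(geom, rmin, rmax) {
  stopifnot(rmin < rmax)
  d <- geom$dist_to_reference
  if (all(is.na(d))) stop("distance axis not computed", call. = FALSE)
  geom$roi_id[!is.na(d) & is.finite(d) & d >= rmin & d <= rmax]
}

#' Split ROIs into consecutive windows along the Y axis
#'
#' Divides the centroid-Y range into `n_windows` equal-width consecutive
#' intervals (half-open `[a, b)`, the last closed) and labels each ROI with
#' its window, `"w1"` (most posterior) to `"w<n>"` (most anterior).
#'
#' @param geom a [roi_geometry()] table.
#' @param n_windows number of windows (>= 1).
#' @return `geom` with an added `window` column.
#' @export
split_y_windows <- function(geom, n_windows) {
  stopifnot(n_windows >= 1)
  y <- geom$y
  lo <- min(y); hi <- max(y)
  if (n_windows > 1 && hi - lo <= 0) {
    stop("all ROI centroids share one Y value; windows would be zero-width",
         call. = FALSE)
  }
  if (n_windows == 1) {
    idx <- rep(1L, length(y))
  } else {
    width <- (hi - lo) / n_windows
    idx <- pmin(floor((y - lo) / width) + 1L, n_windows)  # hi lands in last
  }
  dplyr::mutate(geom, window = paste0("w", idx))
}
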