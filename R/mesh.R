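#' Cortical surface mesh
#'
#' A triangulated cortical surface: vertex coordinates in mm (X left-right,
#' Y posterior-anterior, Z inferior-superior), triangle vertex indices
#' (1-based), and a hemisphere label per vertex. The two hemispheres are
#' expected to be disconnected components of the edge graph, so geodesic
#' distances across hemispheres are infinite.
#'
#' @param vertices numeric matrix `[n_vertices x 3]` of coordinates in mm.
#' @param triangles integer matrix `[n_triangles x 3]` of 1-based vertex
#'   indices.
#' @param hemisphere character vector of `"L"`/`"R"` labels, one per vertex.
#' @return An object of class `cortical_mesh`.
#' @export
cortical_mesh <- function(vertices, triangles, hemisphere) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  n <- nrow(vertices)
  if (length(hemisphere) != n) {
    stop("hemisphere must have one label per vertex", call. = FALSE)
  }
  if (!all(hemisphere %in% c("L", "R"))) {
    stop("hemisphere labels must be 'L' or 'R'", call. = FALSE)
  }
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  # degenerate (repeated-vertex) triangles carry no edges and break area
  # assumptions downstream
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3])) {
    stop("mesh contains degenerate triangles", call. = FALSE)
  }
  structure(
    list(vertices = vertices, triangles = triangles,
         hemisphere = as.character(hemisphere)),
    class = "cortical_mesh"
  )
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("<cortical_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles (",
      sum(x$hemisphere == "L"), " L / ", sum(x$hemisphere == "R"), " R)\n",
      sep = "")
  invisible(x)
}

#' Read a triangulated surface from an ASCII OFF or PLY file
#'
#' Supports plain ASCII OFF and ASCII PLY 1.0 with triangular faces only.
#' Hemisphere labels are assigned by the sign of the X coordinate
#' (X < 0 is left) unless supplied explicitly.
#'
#' @param path file path; format is detected from the header.
#' @param hemisphere optional explicit per-vertex labels.
#' @return A [cortical_mesh()].
#' @export
read_surface_mesh <- function(path, hemisphere = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty mesh file: ", path, call. = FALSE)
  if (identical(toupper(lines[[1]]), "OFF")) {
    out <- parse_off(lines[-1])
  } else if (identical(tolower(lines[[1]]), "ply")) {
    out <- parse_ply(lines[-1])
  } else {
    stop("unrecognised mesh format (expected OFF or ascii PLY): ", path,
         call. = FALSE)
  }
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(out$vertices[, 1] < 0, "L", "R")
  }
  cortical_mesh(out$vertices, out$triangles, hemisphere)
}

num_fields <- function(line) as.numeric(strsplit(line, "[[:space:]]+")[[1]])

parse_off <- function(lines) {
  counts <- num_fields(lines[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- t(vapply(lines[1 + seq_len(nv)],
                    function(l) num_fields(l)[1:3], numeric(3)))
  faces <- t(vapply(lines[1 + nv + seq_len(nf)],
                    function(l) num_fields(l), numeric(4)))
  if (any(faces[, 1] != 3)) {
    stop("only triangular faces are supported", call. = FALSE)
  }
  list(vertices = unname(verts), triangles = unname(faces[, 2:4] + 1L))
}

parse_ply <- function(lines) {
  header_end <- match("end_header", lines)
  if (is.na(header_end)) stop("PLY header not terminated", call. = FALSE)
  header <- lines[seq_len(header_end - 1)]
  if (!any(grepl("^format[[:space:]]+ascii", header))) {
    stop("only ascii PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub(".*[[:space:]]", "", grep("^element vertex", header,
                                                 value = TRUE)))
  nf <- as.integer(sub(".*[[:space:]]", "", grep("^element face", header,
                                                 value = TRUE)))
  body <- lines[-seq_len(header_end)]
  verts <- t(vapply(body[seq_len(nv)],
                    function(l) num_fields(l)[1:3], numeric(3)))
  faces <- t(vapply(body[nv + seq_len(nf)],
                    function(l) num_fields(l), numeric(4)))
  if (any(faces[, 1] != 3)) {
    stop("only triangular faces are supported", call. = FALSE)
  }
  list(vertices = unname(verts), triangles = unname(faces[, 2:4] + 1L))
}

#' Write a mesh as ASCII OFF
#'
#' @param mesh a [cortical_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  writeLines(apply(mesh$vertices, 1,
                   function(v) paste(format(v, trim = TRUE), collapse = " ")),
             con)
  writeLines(apply(mesh$triangles - 1L, 1,
                   function(f) paste(c(3L, f), collapse = " ")), con)
  invisible(path)
}

#' Vertex-to-ROI parcellation
#'
#' Maps each mesh vertex to an ROI identifier or to `"excluded"` (e.g. the
#' medial wall). Every non-excluded ROI must be non-empty and lie in a single
#' hemisphere.
#'
#' @param roi_of_vertex character vector, one ROI id (or `"excluded"`) per
#'   vertex.
#' @param mesh the [cortical_mesh()] the parcellation refers to.
#' @return A tibble of class `parcellation` with columns `vertex_id`
#'   (1-based), `roi_id`, `hemisphere`.
#' @export
parcellation <- function(roi_of_vertex, mesh) {
  n <- nrow(mesh$vertices)
  if (length(roi_of_vertex) != n) {
    stop("roi_of_vertex must have one entry per mesh vertex", call. = FALSE)
  }
  tbl <- tibble::tibble(
    vertex_id = seq_len(n),
    roi_id = as.character(roi_of_vertex),
    hemisphere = mesh$hemisphere
  )
  rois <- dplyr::filter(tbl, .data$roi_id != "excluded")
  hemi_per_roi <- tapply(rois$hemisphere, rois$roi_id,
                         function(h) length(unique(h)))
  if (any(hemi_per_roi > 1)) {
    stop("ROIs spanning both hemispheres: ",
         paste(names(hemi_per_roi)[hemi_per_roi > 1], collapse = ", "),
         call. = FALSE)
  }
  class(tbl) <- c("parcellation", class(tbl))
  tbl
}

#' Read a parcellation TSV (columns vertex_id 0-based, roi_id, hemisphere)
#'
#' @param path TSV path.
#' @param mesh the mesh it annotates.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, mesh) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("vertex_id", "roi_id") %in% names(tbl)))
  roi <- rep("excluded", nrow(mesh$vertices))
  roi[tbl$vertex_id + 1L] <- as.character(tbl$roi_id)
  parcellation(roi, mesh)
}

roi_ids <- function(parc) {
  sort(unique(parc$roi_id[parc$roi_id != "excluded"]))
}

roi_vertices <- function(parc, roi) {
  v <- parc$vertex_id[parc$roi_id == roi]
  if (length(v) == 0) stop("empty or unknown ROI: ", roi, call. = FALSE)
  v
}
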