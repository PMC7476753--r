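test_that("geodesic distances follow the edge graph: path, identity, Inf", {
  mesh <- make_path_mesh()
  d <- geodesic_distances(mesh, 1)
  expect_equal(d, c(0, 1, 2))
  expect_identical(geodesic_distances(mesh, 2)[2], 0)
  expect_error(geodesic_distances(mesh, 9), "source_vertex")

  # other hemisphere unreachable -> Inf, not an error
  two <- make_synthetic_mesh(tiny_cohort_config())
  d2 <- geodesic_distances(two$mesh, 1)
  other <- two$mesh$hemisphere != two$mesh$hemisphere[1]
  expect_true(all(is.infinite(d2[other])))
  expect_true(all(is.finite(d2[!other])))
})

test_that("geodesic distances match a dense Floyd-Warshall oracle", {
  for (seed in 1:3) {
    mesh <- make_patch_mesh(7, 7, jitter = 0.5, seed = seed)
    oracle <- floyd_warshall_distances(mesh)
    graph <- mesh_edge_graph(mesh)
    for (src in c(1, 17, 49)) {
      expect_equal(geodesic_distances(mesh, src, graph = graph),
                   oracle[src, ], tolerance = 1e-12)
    }
  }
})

test_that("ROI centroid minimizes summed within-parcel distance", {
  mesh <- make_path_mesh()
  parc <- parcellation(c("A", "A", "A"), mesh)
  expect_identical(roi_centroid(mesh, parc, "A"), 2L)

  parc1 <- parcellation(c("A", "B", "B"), mesh)
  expect_identical(roi_centroid(mesh, parc1, "A"), 1L)
  expect_error(roi_centroid(mesh, parc1, "Z"), "empty or unknown")

  # brute-force oracle on a 30-vertex patch ROI
  mesh2 <- make_patch_mesh(5, 6, jitter = 0.4, seed = 11)
  parc2 <- parcellation(rep("R1", 30), mesh2)
  oracle_d <- floyd_warshall_distances(mesh2)
  sums <- rowSums(oracle_d)
  expect_identical(roi_centroid(mesh2, parc2, "R1"),
                   which(sums == min(sums))[1])
})

test_that("centroid choice is stable under vertex relabeling", {
  mesh <- make_patch_mesh(5, 5, jitter = 0.6, seed = 21)
  n <- nrow(mesh$vertices)
  parc <- parcellation(rep("A", n), mesh)
  cen <- roi_centroid(mesh, parc, "A")
  set.seed(1)
  perm <- sample(n)                         # perm[old] = new index
  inv <- order(perm)
  mesh2 <- cortical_mesh(mesh$vertices[inv, ],
                         matrix(perm[mesh$triangles], ncol = 3),
                         mesh$hemisphere[inv])
  parc2 <- parcellation(rep("A", n), mesh2)
  expect_identical(roi_centroid(mesh2, parc2, "A"), perm[cen])
})

test_that("distance axis equals pairwise centroid geodesics", {
  mp <- make_synthetic_mesh(tiny_cohort_config())
  geom <- roi_geometry(mp$mesh, mp$parcellation)
  refs <- c(L = geom$roi_id[geom$hemisphere == "L"][1],
            R = geom$roi_id[geom$hemisphere == "R"][1])
  d <- distance_axis(mp$mesh, mp$parcellation, geom, refs)
  oracle <- floyd_warshall_distances(mp$mesh)
  for (i in seq_len(nrow(geom))) {
    ref_v <- geom$centroid_vertex[geom$roi_id == refs[[geom$hemisphere[i]]]]
    expect_equal(d[i], oracle[ref_v, geom$centroid_vertex[i]],
                 tolerance = 1e-12)
  }
  expect_equal(d[geom$roi_id == refs[["L"]]], 0)
  expect_error(distance_axis(mp$mesh, mp$parcellation, geom,
                             c(L = "nope")), "reference ROI")
})

test_that("annulus selection is a closed-interval filter", {
  geom <- tibble::tibble(roi_id = c("A", "B", "C"),
                         dist_to_reference = c(0, 25, 40))
  expect_identical(select_annulus(geom, 20, 30), "B")
  expect_setequal(select_annulus(geom, 0, Inf), c("A", "B", "C"))
  expect_identical(select_annulus(geom, 25, 25.5), "B")  # closed lower edge
  expect_length(select_annulus(geom, 41, 50), 0)
  expect_error(select_annulus(geom, 30, 20))

  set.seed(5)
  geom2 <- tibble::tibble(roi_id = as.character(1:100),
                          dist_to_reference = runif(100, 0, 60))
  expect_setequal(
    select_annulus(geom2, 20, 30),
    geom2$roi_id[geom2$dist_to_reference >= 20 &
                   geom2$dist_to_reference <= 30])
})

test_that("Y windows are equal-width, exhaustive and disjoint", {
  geom <- tibble::tibble(roi_id = c("a", "b", "c"), y = c(0, 5, 11),
                         x = 0, z = 0)
  w <- split_y_windows(geom, 3)
  expect_identical(w$window, c("w1", "w2", "w3"))
  expect_identical(split_y_windows(geom, 1)$window, rep("w1", 3))
  expect_error(split_y_windows(dplyr::mutate(geom, y = 2), 3),
               "zero-width")

  set.seed(7)
  geom2 <- tibble::tibble(roi_id = as.character(1:100),
                          y = runif(100, -70, 70))
  w2 <- split_y_windows(geom2, 3)
  # histogram oracle with identical edges
  lo <- min(geom2$y); hi <- max(geom2$y); width <- (hi - lo) / 3
  oracle <- pmin(floor((geom2$y - lo) / width) + 1, 3)
  expect_identical(w2$window, paste0("w", oracle))
  expect_identical(sort(unique(w2$window)), c("w1", "w2", "w3"))
  expect_identical(sum(table(w2$window)), 100L)
})

test_that("mesh files round-trip through OFF and parcellation TSV", {
  mesh <- make_patch_mesh(4, 4, jitter = 0.3, seed = 3)
  off <- withr::local_tempfile(fileext = ".off")
  write_surface_mesh(mesh, off)
  back <- read_surface_mesh(off, hemisphere = mesh$hemisphere)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(back$triangles, mesh$triangles)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(vertex_id = 0:15,
                                  roi_id = rep(c("A", "B"), each = 8),
                                  hemisphere = "L"), tsv)
  parc <- read_parcellation(tsv, mesh)
  expect_identical(roi_ids_for_test(parc), c("A", "B"))
  expect_length(parc$vertex_id[parc$roi_id == "A"], 8)
})

test_that("parcellation rejects ROIs spanning hemispheres", {
  mp <- make_synthetic_mesh(tiny_cohort_config())
  bad <- rep("X", nrow(mp$mesh$vertices))
  expect_error(parcellation(bad, mp$mesh), "hemispheres")
})

test_that("ascii PLY meshes are readable", {
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "3 0 1 2", "3 0 2 3"), ply)
  mesh <- read_surface_mesh(ply, hemisphere = rep("R", 4))
  expect_equal(nrow(mesh$vertices), 4)
  expect_identical(mesh$triangles,
                   matrix(c(1L, 1L, 2L, 3L, 3L, 4L), ncol = 3))
})
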