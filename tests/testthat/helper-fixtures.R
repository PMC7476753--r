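# Fixture builders and independent oracles shared across tests.

# dense all-pairs shortest-path oracle (Floyd-Warshall) on the triangle
# edge graph with Euclidean weights -- independent of igraph
floyd_warshall_distances <- function(mesh) {
  n <- nrow(mesh$vertices)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  tr <- mesh$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    w <- sqrt(sum((mesh$vertices[i, ] - mesh$vertices[j, ])^2))
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- d[i, j]
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    d <- pmin(d, outer(dk, d[k, ], "+"))
  }
  d
}

# small triangulated grid patch (one hemisphere), optionally jittered
make_patch_mesh <- function(n_row, n_col, jitter = 0, seed = NULL,
                            hemisphere = "L") {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(i = seq_len(n_row), j = seq_len(n_col))
  verts <- cbind(grid$i * 2, grid$j * 2,
                 if (jitter > 0) rnorm(nrow(grid), 0, jitter) else 0)
  idx <- matrix(seq_len(n_row * n_col), nrow = n_row)
  tris <- list()
  for (i in seq_len(n_row - 1)) {
    for (j in seq_len(n_col - 1)) {
      a <- idx[i, j]; b <- idx[i + 1, j]
      c2 <- idx[i, j + 1]; d <- idx[i + 1, j + 1]
      tris[[length(tris) + 1]] <- c(a, b, d)
      tris[[length(tris) + 1]] <- c(a, d, c2)
    }
  }
  cortical_mesh(verts, do.call(rbind, tris),
                rep(hemisphere, nrow(verts)))
}

# collinear 3-vertex "path" mesh: edge graph is v1 - v2 - v3 with unit
# edges plus the direct v1 - v3 edge of length 2
make_path_mesh <- function() {
  cortical_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                rbind(c(1, 2, 3)), rep("L", 3))
}

# analytic spectrum on a 0.5 Hz grid: power law plus optional Gaussian
# bumps in log10 power, plus optional log-normal noise
make_synthetic_spectrum <- function(offset, slope, peaks = NULL,
                                    noise_sd = 0, freq = seq(1, 50, 0.5)) {
  logp <- offset + slope * log10(freq)
  if (!is.null(peaks)) {
    for (p in peaks) {
      logp <- logp + p$height * exp(-(freq - p$f0)^2 / (2 * p$sd^2))
    }
  }
  if (noise_sd > 0) logp <- logp + rnorm(length(freq), 0, noise_sd)
  tibble::tibble(frequency = freq, power = 10^logp)
}

lmem_term_est <- function(fit, term) {
  tt <- generics::tidy(fit)
  unname(tt$estimate[tt$term == term])
}

roi_ids_for_test <- function(parc) {
  sort(unique(parc$roi_id[parc$roi_id != "excluded"]))
}

tiny_cohort_config <- function(...) {
  cohort_config(n_participants = 2, n_rois_per_hemisphere = 4,
                n_vertices_per_hemisphere = 60, duration = 12, ...)
}
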