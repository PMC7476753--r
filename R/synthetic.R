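#' Synthetic cohort configuration
#'
#' Parameters of the synthetic resting-state cohort generator. The generator
#' emulates the statistical structure the gradient analysis assumes: per-ROI
#' component time series carrying a narrowband oscillation whose centre
#' frequency decreases linearly along the posterior-anterior (Y) axis with
#' per-participant random intercepts and slopes, superimposed on 1/f-shaped
#' background noise whose log-log slope and offset themselves vary along Y;
#' several correlated "vertex" channels per ROI; optional geodesic leakage
#' mixing; and a cortical-thickness field increasing along Y, anticorrelated
#' with peak frequency.
#'
#' Spatial fields are parameterized at the posterior reference
#' `y_ref = -75 mm` (so `pf_intercept` is the population peak frequency at
#' the posterior pole) and evolve linearly per mm toward anterior.
#'
#' @param n_participants cohort size.
#' @param n_rois_per_hemisphere parcels per hemisphere.
#' @param n_vertices_per_hemisphere mesh vertices per hemisphere.
#' @param sampling_rate Hz.
#' @param duration seconds of resting-state signal per participant.
#' @param pf_intercept population peak frequency (Hz) at `y_ref`.
#' @param pf_slope_y fixed-effect PF gradient along Y (Hz/mm, negative =
#'   decreasing toward anterior).
#' @param pf_slope_z fixed-effect PF gradient along Z (Hz/mm).
#' @param random_intercept_sd SD of per-participant PF intercepts (Hz).
#' @param random_slope_sd SD of per-participant Y-slope deviations (Hz/mm).
#' @param aperiodic_offset_field `c(intercept, slope_y)`: log10-power offset
#'   of the 1/f background at `y_ref` and its change per mm along Y.
#' @param aperiodic_slope_field `c(intercept, slope_y)`: signed log-log slope
#'   of the 1/f background at `y_ref` and its change per mm along Y.
#' @param osc_amplitude_field `c(intercept, slope_y)`: RMS amplitude of the
#'   dominant oscillation at `y_ref` and change per mm (alpha dominant
#'   posteriorly).
#' @param band_components extra narrowband components, each
#'   `list(label, amp = c(intercept, slope_y), freq = c(intercept, slope_y),
#'   halfwidth)`; defaults add a theta and a beta component whose centre
#'   frequencies increase toward anterior.
#' @param aperiodic_noise_sd SD of per-(participant, ROI) jitter added to
#'   both aperiodic fields (regional variability beyond the Y trend).
#' @param pf_slope_coupling Hz of PF shift per unit of aperiodic-slope
#'   jitter: couples PF to the 1/f slope beyond their shared spatial trend
#'   (0 = uncoupled; used to probe residualization).
#' @param ct_intercept,ct_slope_y,ct_noise_sd cortical thickness field (mm):
#'   value at `y_ref`, change per mm along Y, and vertex noise SD.
#' @param vertex_noise_sd SD of per-channel sensor noise.
#' @param n_vertices_per_roi_signal channels simulated per ROI.
#' @param leakage_fwhm `NULL` for no leakage, else FWHM (mm) of Gaussian
#'   mixing of ROI components over geodesic centroid distance.
#' @param oscillation_halfwidth half-width (Hz) of the dominant narrowband
#'   component.
#' @param pf_limits admissible PF range (Hz); sampled fields are clipped
#'   here and clipping is reported.
#' @param y_ref,z_ref field reference coordinates (mm).
#' @param seed integer master seed; all stages derive child seeds from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          n_rois_per_hemisphere = 48,
                          n_vertices_per_hemisphere = 1000,
                          sampling_rate = 300,
                          duration = 300,
                          pf_intercept = 11,
                          pf_slope_y = -0.02,
                          pf_slope_z = 0,
                          random_intercept_sd = 0.5,
                          random_slope_sd = 0.004,
                          aperiodic_offset_field = c(-1.0, 0.002),
                          aperiodic_slope_field = c(-1.2, 0.001),
                          osc_amplitude_field = c(1.0, 0),
                          band_components = list(
                            list(label = "theta", amp = c(0.35, 0),
                                 freq = c(4.5, 0.005), halfwidth = 0.75),
                            list(label = "beta", amp = c(0.35, 0),
                                 freq = c(18, 0.04), halfwidth = 1.5)
                          ),
                          aperiodic_noise_sd = 0.03,
                          pf_slope_coupling = 0,
                          ct_intercept = 2.0,
                          ct_slope_y = 0.004,
                          ct_noise_sd = 0.08,
                          vertex_noise_sd = 0.3,
                          n_vertices_per_roi_signal = 3,
                          leakage_fwhm = NULL,
                          oscillation_halfwidth = 3,
                          pf_limits = c(3, 35),
                          y_ref = -75,
                          z_ref = 0,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 1, n_rois_per_hemisphere >= 1,
            n_vertices_per_hemisphere >= n_rois_per_hemisphere,
            sampling_rate > 0, duration >= 2)
  max_f <- max(pf_limits[2],
               vapply(band_components,
                      function(b) b$freq[1] + abs(b$freq[2]) * 150 +
                        b$halfwidth, numeric(1)))
  if (sampling_rate <= 2 * max_f) {
    stop("sampling_rate must exceed twice the highest simulated frequency",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Documented counter scheme: child seed for stage k of master seed s is
# (s mod 1000003) * 2049 + k, which stays below 2^31 - 1 for k < 2049.
# Stages: 2 = field sampling, 1000 + j = recording of participant j.
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003) * 2049 + stage)
}

#' Build the synthetic two-hemisphere cortical mesh and parcellation
#'
#' Each hemisphere is a deformed ellipsoid sheet built on a regular
#' parameter grid spanning Y in about \[-75, 75\] mm and Z in about
#' \[0, 80\] mm, mirrored in X for the two hemispheres and triangulated
#' from the grid quads. The parcellation tiles the parameter grid into
#' `n_rois_per_hemisphere` rectangles, so every ROI is edge-connected and
#' single-hemisphere by construction. Deterministic given the config.
#'
#' @param config a [cohort_config()].
#' @return `list(mesh, parcellation)`.
#' @export
make_synthetic_mesh <- function(config) {
  nv <- config$n_vertices_per_hemisphere
  nr <- config$n_rois_per_hemisphere
  if (nr > nv) stop("more ROIs than vertices per hemisphere", call. = FALSE)
  # near-square grid, rows along Y (longer axis)
  n_col <- max(2L, floor(sqrt(nv / 2.5)))
  n_row <- max(2L, ceiling(nv / n_col))
  u <- seq(0, 1, length.out = n_row)   # posterior -> anterior
  v <- seq(0, 1, length.out = n_col)   # inferior -> superior arc
  grid <- expand.grid(iv = seq_len(n_col), iu = seq_len(n_row))
  uu <- u[grid$iu]; vv <- v[grid$iv]
  y <- -75 + 150 * uu
  # lateral extent tapers toward the occipital and frontal poles
  # (ellipsoid-like), so the most posterior parcel behaves like a pole and
  # geodesic distance from it tracks the posterior-anterior axis in every
  # direction, as it does from V1 on a real hemisphere
  taper <- 0.1 + 0.9 * pmax(0, 1 - ((uu - 0.5) / 0.5)^2)^1.2
  z <- 40 + 38 * (vv - 0.5) * 2 * taper
  bulge <- 8 + 35 * sin(pi * vv) * taper
  one_hemi <- function(sgn) cbind(sgn * bulge, y, z)
  verts <- rbind(one_hemi(-1), one_hemi(1))
  tri_grid <- function(offset) {
    idx <- matrix(seq_len(n_row * n_col), nrow = n_col)  # [iv, iu]
    tris <- vector("list", (n_row - 1) * (n_col - 1) * 2)
    k <- 1
    for (i in seq_len(n_col - 1)) {
      for (j in seq_len(n_row - 1)) {
        a <- idx[i, j]; b <- idx[i + 1, j]
        c2 <- idx[i, j + 1]; d <- idx[i + 1, j + 1]
        tris[[k]] <- c(a, b, d) + offset; k <- k + 1
        tris[[k]] <- c(a, d, c2) + offset; k <- k + 1
      }
    }
    do.call(rbind, tris)
  }
  n_hemi <- n_row * n_col
  triangles <- rbind(tri_grid(0L), tri_grid(n_hemi))
  hemi <- rep(c("L", "R"), each = n_hemi)
  mesh <- cortical_mesh(verts, triangles, hemi)
  # tile the grid into near-square ROI rectangles: pick the divisor pair
  # (tiles_u x tiles_v = nr) closest to the grid aspect with every tile
  # holding at least one grid line in each direction
  divisors <- which(nr %% seq_len(nr) == 0)
  ok <- divisors <= n_row & (nr %/% divisors) <= n_col
  if (!any(ok)) {
    stop("cannot tile ", nr, " ROIs onto a ", n_row, "x", n_col,
         " vertex grid", call. = FALSE)
  }
  target <- sqrt(nr * n_row / n_col)
  tiles_u <- divisors[ok][which.min(abs(divisors[ok] - target))]
  tiles_v <- nr %/% tiles_u
  bin_u <- pmin(ceiling(grid$iu / n_row * tiles_u), tiles_u)
  bin_u[bin_u < 1] <- 1L
  bin_v <- pmin(ceiling(grid$iv / n_col * tiles_v), tiles_v)
  bin_v[bin_v < 1] <- 1L
  tile <- (bin_u - 1L) * tiles_v + bin_v
  roi <- c(sprintf("L%03d", tile), sprintf("R%03d", tile))
  list(mesh = mesh, parcellation = parcellation(roi, mesh))
}

field_at <- function(field, dy) field[1] + field[2] * dy

#' Sample ground-truth spatial fields for a cohort
#'
#' Draws the per-participant, per-ROI ground truth of the generative model:
#' `true_pf[i,j] = pf_intercept + u0_j + (pf_slope_y + uY_j) * (y_i - y_ref)
#' + pf_slope_z * (z_i - z_ref)`, with participant random intercepts `u0_j`
#' and Y-slope deviations `uY_j` drawn from centred normals; a
#' cortical-thickness field linear in Y plus noise; and aperiodic offset and
#' slope fields linear in Y. PF values are clipped to `config$pf_limits`
#' (clip count reported via attribute `n_clipped`).
#'
#' @param mesh,parc from [make_synthetic_mesh()].
#' @param config a [cohort_config()].
#' @param geom optional precomputed [roi_geometry()] (saves recomputation).
#' @return A list of class `cohort_truth`: `fields` (tibble with one row per
#'   participant x ROI), `fixed`, `random` (per-participant effects),
#'   `geom`, `config`.
#' @export
sample_fields <- function(mesh, parc, config, geom = NULL) {
  if (is.null(geom)) geom <- roi_geometry(mesh, parc)
  set.seed(child_seed(config$seed, 2L))
  np <- config$n_participants
  u0 <- rnorm(np, 0, config$random_intercept_sd)
  uY <- rnorm(np, 0, config$random_slope_sd)
  rand <- tibble::tibble(participant = sprintf("sub%03d", seq_len(np)),
                         u0 = u0, uY = uY)
  dy <- geom$y - config$y_ref
  dz <- geom$z - config$z_ref
  fields <- tidyr::crossing(participant = rand$participant,
                            roi_id = geom$roi_id) |>
    dplyr::left_join(rand, by = "participant") |>
    dplyr::left_join(
      tibble::tibble(roi_id = geom$roi_id, hemisphere = geom$hemisphere,
                     dy = dy, dz = dz, y = geom$y, z = geom$z),
      by = "roi_id"
    ) |>
    dplyr::mutate(
      true_ct = config$ct_intercept + config$ct_slope_y * .data$dy +
        rnorm(dplyr::n(), 0, config$ct_noise_sd),
      offset_jitter = rnorm(dplyr::n(), 0, config$aperiodic_noise_sd),
      slope_jitter = rnorm(dplyr::n(), 0, config$aperiodic_noise_sd),
      true_aperiodic_offset = field_at(config$aperiodic_offset_field,
                                       .data$dy) + .data$offset_jitter,
      true_aperiodic_slope = field_at(config$aperiodic_slope_field,
                                      .data$dy) + .data$slope_jitter,
      true_pf = config$pf_intercept + .data$u0 +
        (config$pf_slope_y + .data$uY) * .data$dy +
        config$pf_slope_z * .data$dz +
        config$pf_slope_coupling * .data$slope_jitter,
      osc_amplitude = pmax(field_at(config$osc_amplitude_field, .data$dy),
                           0.05)
    )
  nyq <- config$sampling_rate / 2
  if (any(fields$true_pf <= 0 | fields$true_pf >= nyq)) {
    stop("configured PF fields produce frequencies outside (0, Nyquist)",
         call. = FALSE)
  }
  clipped <- fields$true_pf < config$pf_limits[1] |
    fields$true_pf > config$pf_limits[2]
  if (any(clipped)) {
    message("sample_fields: clipping ", sum(clipped),
            " PF values to [", config$pf_limits[1], ", ",
            config$pf_limits[2], "] Hz")
  }
  fields$true_pf <- pmin(pmax(fields$true_pf, config$pf_limits[1]),
                         config$pf_limits[2])
  out <- structure(
    list(fields = dplyr::select(fields, -"u0", -"uY", -"offset_jitter",
                                -"slope_jitter"),
         fixed = list(gamma0 = config$pf_intercept,
                      gammaY = config$pf_slope_y,
                      gammaZ = config$pf_slope_z),
         random = rand, geom = geom, config = config),
    class = "cohort_truth"
  )
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Gaussian noise with a power-law (1/f-shaped) spectrum
#'
#' Frequency-domain amplitude shaping of white Gaussian noise so the
#' one-sided power spectral density follows `10^offset * f^slope` (power
#' units^2/Hz, `f` in Hz). The DC bin is zeroed.
#'
#' @param n samples.
#' @param sampling_rate Hz.
#' @param offset log10 PSD at 1 Hz.
#' @param slope signed log-log slope (negative for 1/f decay).
#' @return Numeric vector of length `n`.
#' @export
colored_noise <- function(n, sampling_rate, offset, slope) {
  x <- rnorm(n)
  f <- freq_grid_full(n, sampling_rate)
  h <- numeric(n)
  nz <- f != 0
  h[nz] <- sqrt(10^offset * abs(f[nz])^slope * sampling_rate / 2)
  Re(fft(fft(x) * h, inverse = TRUE)) / n
}

#' Band-limited oscillation (filtered white noise)
#'
#' White Gaussian noise narrow-band filtered around `f_center` and
#' standardized to unit variance: a narrowband oscillation with realistic
#' finite spectral width rather than a pure tone. The default `"gaussian"`
#' profile shapes the amplitude spectrum as
#' `exp(-(f - f_center)^2 / (2 sigma^2))` with `sigma = halfwidth / 2`
#' (about 95% of the power within `f_center +/- halfwidth`), giving the
#' rounded spectral peak seen in real recordings; a peaked profile also
#' keeps bin-resolution peak extraction unbiased when the oscillation sits
#' on a sloped 1/f background, which a flat-top (brick-wall) band does not.
#' `profile = "flat"` gives the ideal band-pass `f_center +/- halfwidth`.
#'
#' @param n samples.
#' @param sampling_rate Hz.
#' @param f_center centre frequency, Hz.
#' @param halfwidth nominal half-bandwidth, Hz.
#' @param profile `"gaussian"` (default) or `"flat"`.
#' @return Numeric vector of length `n`, unit variance.
#' @export
bandlimited_oscillation <- function(n, sampling_rate, f_center,
                                    halfwidth = 1,
                                    profile = c("gaussian", "flat")) {
  profile <- match.arg(profile)
  lo <- f_center - halfwidth
  hi <- f_center + halfwidth
  if (hi >= sampling_rate / 2 ||
      (profile == "flat" && lo <= 0) ||
      (profile == "gaussian" && f_center <= halfwidth / 2)) {
    stop("oscillation band [", lo, ", ", hi, "] Hz outside (0, Nyquist)",
         call. = FALSE)
  }
  x <- rnorm(n)
  f <- freq_grid_full(n, sampling_rate)
  if (profile == "flat") {
    mask <- as.numeric(abs(f) >= lo & abs(f) <= hi)
  } else {
    sigma <- halfwidth / 2
    mask <- exp(-(abs(f) - f_center)^2 / (2 * sigma^2))
    mask[f == 0] <- 0
  }
  y <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  y / sd(y)
}

# two-sided frequency grid matching R's fft bin order
freq_grid_full <- function(n, sampling_rate) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * sampling_rate / n
}

#' Simulate per-ROI multichannel recordings
#'
#' For each requested participant, every ROI gets a component signal: a
#' dominant narrowband oscillation at the participant/ROI ground-truth PF
#' (amplitude from the oscillation amplitude field), optional extra band
#' components (theta/beta by default), and 1/f-shaped background noise at
#' the ROI's ground-truth (offset, slope). The component is observed on
#' `n_vertices_per_roi_signal` channels with loadings `Uniform(0.5, 1.5)`
#' plus white vertex noise. With `leakage_fwhm` set, ROI components are
#' mixed within hemisphere with Gaussian weights in geodesic centroid
#' distance before channels are formed. Deterministic per participant given
#' the master seed (participant `j` uses child seed `1000 + j`), so
#' participants can be simulated independently or streamed.
#'
#' @param truth a [sample_fields()] result.
#' @param config the [cohort_config()] used for `truth`.
#' @param participants integer indices of participants to simulate
#'   (default: all).
#' @param mesh the source mesh; only needed for leakage mixing when `truth`
#'   does not already carry the edge graph.
#' @return A list of `participant_recording` objects: each has `participant`,
#'   `sampling_rate`, `hemisphere_of_roi`, and `rois`, a named list of
#'   `[n_channels x n_samples]` matrices.
#' @export
simulate_roi_timeseries <- function(truth, config = truth$config,
                                    participants = NULL, mesh = NULL) {
  geom <- truth$geom
  np <- config$n_participants
  if (is.null(participants)) participants <- seq_len(np)
  n <- round(config$duration * config$sampling_rate)
  fs <- config$sampling_rate
  leak_w <- NULL
  if (!is.null(config$leakage_fwhm)) {
    graph <- truth$mesh_graph
    if (is.null(graph)) {
      if (is.null(mesh)) {
        stop("leakage mixing needs the mesh (or truth$mesh_graph)",
             call. = FALSE)
      }
      graph <- mesh_edge_graph(mesh)
    }
    leak_w <- leakage_weights(geom, config$leakage_fwhm, graph)
  }
  dy <- geom$y - config$y_ref
  lapply(participants, function(j) {
    pid <- truth$random$participant[j]
    set.seed(child_seed(config$seed, 1000L + j))
    frows <- truth$fields[truth$fields$participant == pid, ]
    frows <- frows[match(geom$roi_id, frows$roi_id), ]
    comp <- matrix(0, n, nrow(geom))
    for (i in seq_len(nrow(geom))) {
      sig <- frows$osc_amplitude[i] *
        bandlimited_oscillation(n, fs, frows$true_pf[i],
                                config$oscillation_halfwidth)
      for (b in config$band_components) {
        fb <- field_at(b$freq, dy[i])
        sig <- sig + field_at(b$amp, dy[i]) *
          bandlimited_oscillation(n, fs, fb, b$halfwidth)
      }
      comp[, i] <- sig + colored_noise(n, fs, frows$true_aperiodic_offset[i],
                                       frows$true_aperiodic_slope[i])
    }
    if (!is.null(leak_w)) comp <- comp %*% leak_w
    nch <- config$n_vertices_per_roi_signal
    rois <- lapply(seq_len(nrow(geom)), function(i) {
      loadings <- runif(nch, 0.5, 1.5)
      tcrossprod(loadings, comp[, i]) +
        matrix(rnorm(nch * n, 0, config$vertex_noise_sd), nch, n)
    })
    names(rois) <- geom$roi_id
    structure(list(participant = pid, sampling_rate = fs,
                   hemisphere_of_roi = setNames(geom$hemisphere,
                                                geom$roi_id),
                   rois = rois),
              class = "participant_recording")
  })
}

# column-stochastic Gaussian-in-geodesic-distance mixing weights between ROI
# components within hemisphere
leakage_weights <- function(geom, fwhm, graph) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- igraph::distances(graph, v = geom$centroid_vertex,
                         to = geom$centroid_vertex, algorithm = "dijkstra")
  w <- exp(-d^2 / (2 * sigma^2))
  w[!is.finite(d)] <- 0
  sweep(w, 2, colSums(w), "/")
}

#' Generate a full synthetic cohort
#'
#' Composes [make_synthetic_mesh()], [sample_fields()] and
#' [simulate_roi_timeseries()]; optionally writes the mesh (OFF), the
#' parcellation, the ROI geometry and the ground-truth table as plain-text
#' files. At the default scale the recordings are large; set
#' `keep_recordings = FALSE` and simulate participants one at a time via
#' [simulate_roi_timeseries()] when streaming (what [run_pipeline()] does).
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory for ground-truth TSVs.
#' @param keep_recordings simulate and return all recordings now?
#' @return `list(mesh, parcellation, geom, truth, recordings)`.
#' @export
generate_cohort <- function(config, out_dir = NULL, keep_recordings = TRUE) {
  mp <- make_synthetic_mesh(config)
  geom <- roi_geometry(mp$mesh, mp$parcellation)
  truth <- sample_fields(mp$mesh, mp$parcellation, config, geom = geom)
  truth$mesh_graph <- mesh_edge_graph(mp$mesh)
  recordings <- NULL
  if (keep_recordings) {
    recordings <- simulate_roi_timeseries(truth, config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_surface_mesh(mp$mesh, file.path(out_dir, "mesh.off"))
    readr::write_tsv(
      tibble::tibble(vertex_id = mp$parcellation$vertex_id - 1L,
                     roi_id = mp$parcellation$roi_id,
                     hemisphere = mp$parcellation$hemisphere),
      file.path(out_dir, "parcellation.tsv"))
    readr::write_tsv(geom, file.path(out_dir, "roi_geometry.tsv"))
    readr::write_tsv(truth$fields, file.path(out_dir, "ground_truth.tsv"))
  }
  list(mesh = mp$mesh, parcellation = mp$parcellation, geom = geom,
       truth = truth, recordings = recordings)
}

#' Feature-level cohort table straight from ground truth
#'
#' Produces the long cohort table the gradient models consume without
#' running the signal chain: observed PF is the ground-truth PF plus
#' peak-extraction measurement noise (`pf_noise_sd`, emulating
#' bin-resolution reporting and detection jitter), and the aperiodic
#' parameters get small estimation noise. Used for statistical calibration
#' experiments (type-I error, estimator consistency) where the spectral
#' stage is deliberately out of the loop. Draws from the current RNG state;
#' seed before calling.
#'
#' @param truth a [sample_fields()] result.
#' @param pf_noise_sd SD (Hz) of PF measurement noise.
#' @param param_noise_sd SD of aperiodic-parameter estimation noise.
#' @return A cohort tibble (`participant`, `hemisphere`, `roi_id`, `x`,
#'   `y`, `z`, `pf`, `ct`, `aperiodic_offset`, `aperiodic_slope`).
#' @export
cohort_table_from_truth <- function(truth, pf_noise_sd = 0.35,
                                    param_noise_sd = 0.02) {
  f <- truth$fields
  geom <- truth$geom
  n <- nrow(f)
  tibble::tibble(
    participant = f$participant, hemisphere = f$hemisphere,
    roi_id = f$roi_id,
    x = geom$x[match(f$roi_id, geom$roi_id)],
    y = f$y, z = f$z,
    pf = f$true_pf + rnorm(n, 0, pf_noise_sd),
    ct = f$true_ct,
    aperiodic_offset = f$true_aperiodic_offset +
      rnorm(n, 0, param_noise_sd),
    aperiodic_slope = f$true_aperiodic_slope + rnorm(n, 0, param_noise_sd)
  )
}

#' Assign resting-state-network labels along the Y axis
#'
#' Orders ROIs by centroid Y within hemisphere and splits them into eight
#' equal groups labelled, posterior to anterior, VIS, AUD, SOM (sensory)
#' then DAN, VAN, CON, FPN, DMN (association) — the synthetic counterpart of
#' an anterior-association network layout.
#'
#' @param geom a [roi_geometry()] table.
#' @return `geom` with an added `network` column.
#' @export
assign_networks <- function(geom) {
  labels <- c("VIS", "AUD", "SOM", "DAN", "VAN", "CON", "FPN", "DMN")
  geom |>
    dplyr::group_by(.data$hemisphere) |>
    dplyr::mutate(network = labels[pmin(
      floor((rank(.data$y, ties.method = "first") - 1) /
              dplyr::n() * 8) + 1, 8)]) |>
    dplyr::ungroup()
}

#' Assign a seven-level visual-like hierarchy along the Y axis
#'
#' Picks, per hemisphere, the seven ROIs whose centroids are nearest to
#' seven equally spaced Y positions and labels them with hierarchy levels
#' 1 (most posterior, V1-like) through 7.
#'
#' @param geom a [roi_geometry()] table.
#' @param n_levels number of hierarchy levels.
#' @return `geom` with an added `hierarchy_level` column (NA off-hierarchy).
#' @export
assign_hierarchy <- function(geom, n_levels = 7) {
  geom$hierarchy_level <- NA_integer_
  for (h in unique(geom$hemisphere)) {
    idx <- which(geom$hemisphere == h)
    ys <- geom$y[idx]
    targets <- seq(min(ys), max(ys), length.out = n_levels)
    used <- integer(0)
    for (lvl in seq_len(n_levels)) {
      cand <- idx[order(abs(ys - targets[lvl]))]
      cand <- setdiff(cand, used)[1]
      if (is.na(cand)) break               # fewer parcels than levels
      geom$hierarchy_level[cand] <- lvl
      used <- c(used, cand)
    }
  }
  geom
}
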