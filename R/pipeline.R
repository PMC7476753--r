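#' Pipeline configuration
#'
#' Bundles the cohort generator settings with every analysis parameter of
#' the spectra -> peaks -> gradients chain. All thresholds live here; the
#' analysis functions read them from the config, never hard-code them.
#'
#' @param cohort a [cohort_config()].
#' @param epoch_length epoch length, s.
#' @param smoothing multitaper half-bandwidth, Hz.
#' @param variance_fraction SVD variance retention.
#' @param trim_proportion trimmed-mean proportion per tail.
#' @param fit_range aperiodic fit range, Hz.
#' @param min_prominence,min_height peak thresholds, log10-power.
#' @param bands band definition tibble used for band-specific peaks.
#' @param annulus `c(rmin, rmax)` mm for the reference-distance annulus
#'   control.
#' @param n_windows number of consecutive Y windows.
#' @param alpha significance level used in reports and surface predictions.
#' @param df_method `"residual"` or `"satterthwaite"` for LMEM p values.
#' @param write_spectra write the (large) long spectra table?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            epoch_length = 2,
                            smoothing = 2,
                            variance_fraction = 0.95,
                            trim_proportion = 0.1,
                            fit_range = c(3, 45),
                            min_prominence = 0.05,
                            min_height = 0.05,
                            bands = default_bands(),
                            annulus = c(20, 30),
                            n_windows = 3,
                            alpha = 0.05,
                            df_method = "residual",
                            write_spectra = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `cohort` mapping
#' holds [cohort_config()] arguments; `bands` may be a list of
#' `{label, f_low, f_high}` records.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort
  raw$cohort <- NULL
  if (!is.null(raw$bands)) {
    raw$bands <- dplyr::bind_rows(raw$bands)
  }
  args <- raw
  args$cohort <- do.call(cohort_config,
                         if (is.null(cohort_args)) list() else cohort_args)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  }))
}

write_output_tsv <- function(df, path, hash, units) {
  con <- file(path, "w")
  writeLines(sprintf("# cortexgrad config=%s units=%s", hash, units), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Read a pipeline output table (skipping header comments)
#'
#' @param path TSV written by [run_pipeline()].
#' @return A tibble.
#' @export
read_output_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Assemble the long cohort table
#'
#' Joins per-(participant, ROI) spectral features with ROI geometry
#' (coordinates, distance axis, window, network and hierarchy annotations)
#' and the cortical-thickness observations.
#'
#' @param features tibble from [parameterize_spectra()].
#' @param geom annotated [roi_geometry()] table.
#' @param ct tibble (`participant`, `roi_id`, `ct`) or `NULL`.
#' @return The cohort tibble, one row per (participant, ROI).
#' @export
build_cohort_table <- function(features, geom, ct = NULL) {
  out <- dplyr::left_join(
    features,
    dplyr::select(geom, -dplyr::any_of("centroid_vertex")),
    by = c("roi_id", "hemisphere")
  )
  if (!is.null(ct)) {
    out <- dplyr::left_join(out, ct, by = c("participant", "roi_id"))
  }
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> spectra -> peaks -> gradients -> report, streaming one
#' participant at a time so the raw recordings never need to be held in
#' memory together. Writes all numeric tables (TSV with a config-hash
#' header comment), a JSON summary, a run manifest, and a markdown report
#' into `out_dir`. Re-running with the same config and seed reproduces
#' every numeric table byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param report also render the markdown report (and figures)?
#' @return Invisibly, a list with the cohort table, fitted models and
#'   summary statistics.
#' @export
run_pipeline <- function(config, out_dir, report = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  ccfg <- config$cohort

  mp <- make_synthetic_mesh(ccfg)
  geom <- roi_geometry(mp$mesh, mp$parcellation)
  refs <- vapply(split(seq_len(nrow(geom)), geom$hemisphere), function(idx) {
    idx <- idx[order(geom$y[idx], geom$roi_id[idx])]
    geom$roi_id[idx[1]]
  }, character(1))
  geom$dist_to_reference <- distance_axis(mp$mesh, mp$parcellation, geom,
                                          refs)
  geom <- split_y_windows(geom, config$n_windows)
  geom <- assign_networks(geom)
  geom <- assign_hierarchy(geom)
  truth <- sample_fields(mp$mesh, mp$parcellation, ccfg, geom = geom)
  truth$mesh_graph <- mesh_edge_graph(mp$mesh)

  features <- vector("list", ccfg$n_participants)
  peaks <- vector("list", ccfg$n_participants)
  spectra_rows <- vector("list", ccfg$n_participants)
  for (j in seq_len(ccfg$n_participants)) {
    rec <- simulate_roi_timeseries(truth, ccfg, participants = j)[[1]]
    sp <- roi_spectra(rec, config$variance_fraction, config$epoch_length,
                      config$smoothing, config$trim_proportion)
    feat <- parameterize_spectra(sp, config$fit_range,
                                 config$min_prominence, config$min_height,
                                 bands = config$bands)
    features[[j]] <- feat
    peaks[[j]] <- attr(feat, "peaks")
    if (config$write_spectra) spectra_rows[[j]] <- sp
  }
  features <- dplyr::bind_rows(features)
  peaks <- dplyr::bind_rows(peaks)

  ct <- dplyr::select(truth$fields, "participant", "roi_id",
                      ct = "true_ct")
  cohort <- build_cohort_table(features, geom, ct)

  models <- list()
  add_model <- function(name, response, fit) {
    models[[length(models) + 1]] <<- dplyr::mutate(
      tidy(fit), model = name, response = response,
      converged = fit$converged, singular = fit$singular,
      reduced = fit$reduced, n_obs = fit$n_obs, .before = 1)
  }

  coord_pf <- fit_coordinate_gradient(cohort, "pf",
                                      df_method = config$df_method)
  add_model("coordinate", "pf", coord_pf)
  coord_ct <- fit_coordinate_gradient(cohort, "ct",
                                      df_method = config$df_method)
  add_model("coordinate", "ct", coord_ct)
  for (resp in c("aperiodic_offset", "aperiodic_slope")) {
    add_model("coordinate", resp,
              fit_coordinate_gradient(cohort, resp,
                                      df_method = config$df_method))
  }

  # 1/f-residualized PF: standardized 1/f covariates, PF kept in Hz
  cohort_std <- standardize_within_participant(
    cohort, c("aperiodic_offset", "aperiodic_slope"))
  cohort_res <- residualize(cohort_std, "pf",
                            c("aperiodic_slope", "aperiodic_offset"),
                            df_method = config$df_method)
  cohort$pf_res <- cohort_res$pf_res
  coord_res <- fit_coordinate_gradient(cohort, "pf_res",
                                       df_method = config$df_method)
  add_model("coordinate", "pf_res", coord_res)

  # subset models can be infeasible on very small cohorts (an empty
  # annulus, a window with < 3 parcels); they are skipped with a message
  try_model <- function(name, response, expr) {
    fit <- tryCatch(expr, error = function(e) {
      message("skipping ", name, " (", response, "): ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) add_model(name, response, fit)
    fit
  }
  axis_all <- try_model("axis_all", "pf",
                        fit_axis_gradient(cohort, "pf",
                                          df_method = config$df_method))
  window_fits <- list()
  for (w in sort(unique(geom$window))) {
    window_fits[[w]] <- try_model(
      paste0("axis_", w), "pf",
      fit_axis_gradient(cohort, "pf", window = w,
                        df_method = config$df_method))
  }
  annulus_rois <- select_annulus(geom, config$annulus[1], config$annulus[2])
  annulus_fit <- try_model(
    "axis_annulus", "pf",
    fit_axis_gradient(cohort, "pf", rois = annulus_rois,
                      df_method = config$df_method))

  hier_pf <- try_model("hierarchy", "pf",
                       fit_hierarchy_model(cohort, "pf",
                                           df_method = config$df_method))
  hier_ct <- try_model("hierarchy", "ct",
                       fit_hierarchy_model(cohort, "ct",
                                           df_method = config$df_method))
  try_network <- function(response) {
    tryCatch(fit_network_model(cohort, response,
                               df_method = config$df_method),
             error = function(e) {
               message("skipping network model (", response, "): ",
                       conditionMessage(e))
               NULL
             })
  }
  net_pf <- try_network("pf")
  net_ct <- try_network("ct")

  roi_mean <- cohort |>
    dplyr::group_by(.data$roi_id, .data$y, .data$z) |>
    dplyr::summarise(pf_tm = trimmed_mean(.data$pf,
                                          config$trim_proportion),
                     ct_tm = trimmed_mean(.data$ct,
                                          config$trim_proportion),
                     .groups = "drop")
  try_stat <- function(label, expr, fallback) {
    tryCatch(expr, error = function(e) {
      message("skipping ", label, ": ", conditionMessage(e))
      fallback
    })
  }
  na_cor <- list(r = NA_real_, p = NA_real_, n_used = NA, n_skipped = NA)
  sk_pf_y <- try_stat("skipped correlation (pf, y)",
                      skipped_pearson(roi_mean$pf_tm, roi_mean$y), na_cor)
  sk_pf_ct <- try_stat("skipped correlation (pf, ct)",
                       skipped_pearson(roi_mean$pf_tm, roi_mean$ct_tm),
                       na_cor)
  consistency <- try_stat(
    "individual correlation consistency",
    individual_correlation_consistency(cohort, "pf", "y",
                                       alpha = config$alpha),
    list(per_participant = tibble::tibble(participant = character(),
                                          n = integer(), r = numeric(),
                                          p = numeric()),
         fraction_significant = NA_real_, modal_sign = NA,
         t = NA_real_, p = NA_real_, n_participants = 0L))

  data_bands <- tryCatch(
    peak_histogram_bands(peaks$frequency, fit_range = config$fit_range),
    error = function(e) NULL)

  surface <- predict_fixed_surface(coord_pf, geom, alpha = config$alpha)

  units <- "mm,Hz,log10-power"
  write_output_tsv(geom, file.path(out_dir, "roi_geometry.tsv"), hash,
                   units)
  write_output_tsv(truth$fields, file.path(out_dir, "ground_truth.tsv"),
                   hash, units)
  if (config$write_spectra) {
    write_output_tsv(dplyr::bind_rows(spectra_rows),
                     file.path(out_dir, "spectra.tsv"), hash,
                     "Hz,power-au2-per-Hz")
  }
  write_output_tsv(features, file.path(out_dir, "features.tsv"), hash,
                   units)
  write_output_tsv(cohort, file.path(out_dir, "cohort.tsv"), hash, units)
  write_output_tsv(peaks, file.path(out_dir, "peaks.tsv"), hash, units)
  write_output_tsv(dplyr::bind_rows(models),
                   file.path(out_dir, "models.tsv"), hash, units)
  net_rows <- dplyr::bind_rows(
    if (!is.null(net_pf)) dplyr::mutate(net_pf$per_network,
                                        response = "pf"),
    if (!is.null(net_ct)) dplyr::mutate(net_ct$per_network,
                                        response = "ct"))
  if (nrow(net_rows) == 0) {
    net_rows <- tibble::tibble(network = character(), estimate = numeric(),
                               std_error = numeric(),
                               response = character())
  }
  write_output_tsv(net_rows, file.path(out_dir, "networks.tsv"), hash,
                   units)
  write_output_tsv(consistency$per_participant,
                   file.path(out_dir, "correlations.tsv"), hash, "r,p")
  if (!is.null(data_bands)) {
    write_output_tsv(data_bands, file.path(out_dir, "bands.tsv"), hash,
                     "Hz")
    write_output_tsv(attr(data_bands, "histogram"),
                     file.path(out_dir, "peak_histogram.tsv"), hash, "Hz")
  }
  write_output_tsv(surface, file.path(out_dir, "predicted_surface.tsv"),
                   hash, "Hz")

  summary_stats <- list(
    config_hash = hash,
    seed = ccfg$seed,
    skipped_r_pf_y = sk_pf_y$r, skipped_p_pf_y = sk_pf_y$p,
    skipped_r_pf_ct = sk_pf_ct$r, skipped_p_pf_ct = sk_pf_ct$p,
    fraction_individually_significant = consistency$fraction_significant,
    consistency_t = consistency$t, consistency_p = consistency$p,
    network_f_pf = if (is.null(net_pf)) NA else net_pf$f_statistic,
    network_f_p_pf = if (is.null(net_pf)) NA else net_pf$f_p_value,
    network_f_ct = if (is.null(net_ct)) NA else net_ct$f_statistic,
    network_f_p_ct = if (is.null(net_ct)) NA else net_ct$f_p_value,
    sensory_vs_association_t_pf =
      if (is.null(net_pf)) NA else unname(net_pf$contrast$statistic),
    sensory_vs_association_t_ct =
      if (is.null(net_ct)) NA else unname(net_ct$contrast$statistic),
    n_missing_pf = sum(is.na(cohort$pf)),
    annulus_n_rois = length(annulus_rois)
  )
  jsonlite::write_json(summary_stats, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "cortexgrad",
    version = as.character(utils::packageVersion("cortexgrad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = hash,
    seed = ccfg$seed,
    n_participants = ccfg$n_participants,
    n_rois = nrow(geom),
    stages = c("simulate", "spectra", "peaks", "gradients", "report")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  result <- list(cohort = cohort, geom = geom, truth = truth,
                 models = dplyr::bind_rows(models),
                 fits = list(coordinate_pf = coord_pf,
                             coordinate_ct = coord_ct,
                             coordinate_pf_res = coord_res,
                             axis_all = axis_all, windows = window_fits,
                             annulus = annulus_fit,
                             hierarchy_pf = hier_pf, hierarchy_ct = hier_ct,
                             network_pf = net_pf, network_ct = net_ct),
                 correlations = list(pf_y = sk_pf_y, pf_ct = sk_pf_ct,
                                     consistency = consistency),
                 bands = data_bands, surface = surface,
                 summary = summary_stats, out_dir = out_dir)
  if (report) make_report(out_dir)
  invisible(result)
}

#' Render the markdown run report
#'
#' Summarizes a finished pipeline run: trimmed-mean PF against the
#' posterior-anterior axis, per-participant correlation consistency, the
#' mixed-model t table, the predicted fixed-effect surface and the
#' data-driven band histogram. Figures are written as PNG when a graphics
#' device is available; the numeric content stands alone in the markdown.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return Path of the written `report.md`, invisibly.
#' @export
make_report <- function(out_dir) {
  required <- c("cohort.tsv", "models.tsv", "correlations.tsv",
                "predicted_surface.tsv", "peaks.tsv")
  missing_f <- required[!file.exists(file.path(out_dir, required))]
  if (length(missing_f)) {
    stop("missing pipeline outputs: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  cohort <- read_output_tsv(file.path(out_dir, "cohort.tsv"))
  models <- read_output_tsv(file.path(out_dir, "models.tsv"))
  cors <- read_output_tsv(file.path(out_dir, "correlations.tsv"))
  surface <- read_output_tsv(file.path(out_dir, "predicted_surface.tsv"))
  peaks <- read_output_tsv(file.path(out_dir, "peaks.tsv"))
  summary_stats <- jsonlite::read_json(file.path(out_dir, "summary.json"))

  roi_mean <- cohort |>
    dplyr::group_by(.data$roi_id, .data$y, .data$z) |>
    dplyr::summarise(pf_tm = trimmed_mean(.data$pf), .groups = "drop")

  fig <- function(plot, name) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      ggplot2::ggsave(path, plot, width = 5, height = 4, dpi = 120)
      TRUE
    }, error = function(e) FALSE)
    if (ok) sprintf("![](%s)", name) else "(figure device unavailable)"
  }

  md_table <- function(df, digits = 4) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, digits)))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
    paste(c(header, sep, rows), collapse = "\n")
  }

  tvals <- models |>
    dplyr::filter(.data$model == "coordinate") |>
    dplyr::select("response", "term", "estimate", "statistic", "p_value")

  lines <- c(
    "# cortexgrad run report", "",
    sprintf("Config hash `%s`, seed %s, %d participants, %d ROIs.",
            summary_stats$config_hash, summary_stats$seed,
            dplyr::n_distinct(cohort$participant),
            dplyr::n_distinct(cohort$roi_id)), "",
    "## Peak frequency along the posterior-anterior axis", "",
    sprintf(paste0("Skipped Pearson correlation between trimmed-mean PF ",
                   "and Y: r = %.3f (p = %.3g)."),
            summary_stats$skipped_r_pf_y, summary_stats$skipped_p_pf_y), "",
    fig(plot_pf_gradient(cohort), "fig_pf_gradient.png"), "",
    "## Individual-level consistency", "",
    sprintf(paste0("%.0f%% of participants individually significant ",
                   "(modal sign); group t = %.2f (p = %.3g)."),
            100 * summary_stats$fraction_individually_significant,
            summary_stats$consistency_t, summary_stats$consistency_p), "",
    fig(ggplot2::ggplot(cors, ggplot2::aes(x = .data$r)) +
          ggplot2::geom_histogram(bins = 15, fill = "grey40") +
          ggplot2::labs(x = "per-participant r(PF, Y)", y = "count") +
          ggplot2::theme_minimal(), "fig_consistency.png"), "",
    "## Mixed-effect coordinate models", "",
    md_table(tvals), "",
    "## Predicted fixed-effect surface", "",
    sprintf("Predicted PF range across ROIs: %.2f to %.2f Hz.",
            min(surface$predicted), max(surface$predicted)), "",
    "## Peak histogram and data-driven bands", "",
    if (file.exists(file.path(out_dir, "bands.tsv"))) {
      md_table(read_output_tsv(file.path(out_dir, "bands.tsv")))
    } else "(too few peaks for data-driven bands)", "",
    fig(plot_peak_histogram(peaks$frequency), "fig_peak_histogram.png"), ""
  )
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
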