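#' Coordinate gradient model
#'
#' The central spatial model: response (e.g. peak frequency) as a linear
#' function of ROI centroid coordinates X, Y, Z plus their two-way
#' interactions XY, XZ, YZ (fixed effects), with random intercept and
#' X, Y, Z slopes by participant and a random intercept for hemisphere
#' nested in participant. No random effects for the interactions.
#' Coordinates are centred at their ROI-wise means before forming
#' interactions (reduces collinearity; switch off with `center = FALSE`).
#'
#' @param table cohort tibble with columns `participant`, `hemisphere`,
#'   `roi_id`, `x`, `y`, `z` and the response.
#' @param response response column (default `"pf"`).
#' @param center centre coordinates at ROI-wise means?
#' @param df_method passed to [fit_lmem()].
#' @return An `lmem_fit` with terms `x`, `y`, `z`, `x:y`, `x:z`, `y:z`
#'   (estimates per mm); the coordinate centring is stored in `$centers`.
#' @export
fit_coordinate_gradient <- function(table, response = "pf", center = TRUE,
                                    df_method = "residual") {
  rois <- dplyr::distinct(table, .data$roi_id, .data$x, .data$y, .data$z)
  centers <- if (center) {
    c(x = mean(rois$x), y = mean(rois$y), z = mean(rois$z))
  } else {
    c(x = 0, y = 0, z = 0)
  }
  # coordinates fitted in units of `coord_scale` mm so the optimizer sees
  # comparably scaled predictors; estimates rescaled to per-mm afterwards
  s <- coord_scale
  tab <- dplyr::mutate(table,
                       x_c = (.data$x - centers[["x"]]) / s,
                       y_c = (.data$y - centers[["y"]]) / s,
                       z_c = (.data$z - centers[["z"]]) / s,
                       xy = .data$x_c * .data$y_c,
                       xz = .data$x_c * .data$z_c,
                       yz = .data$y_c * .data$z_c)
  fit <- fit_lmem(tab, response,
                  fixed_terms = c("x_c", "y_c", "z_c", "xy", "xz", "yz"),
                  random_terms = c("(1 + x_c + y_c + z_c | participant)",
                                   "(1 | participant:hemisphere)"),
                  df_method = df_method)
  relabel <- c(x_c = "x", y_c = "y", z_c = "z",
               xy = "x:y", xz = "x:z", yz = "y:z")
  fit$terms$term <- ifelse(fit$terms$term %in% names(relabel),
                           relabel[fit$terms$term], fit$terms$term)
  divisors <- c(x = s, y = s, z = s,
                `x:y` = s^2, `x:z` = s^2, `y:z` = s^2)
  fit <- rescale_terms(fit, divisors)
  fit$centers <- centers
  fit$response <- response
  fit
}

coord_scale <- 50  # mm per fitted coordinate unit

# convert estimates fitted on scaled predictors back to natural units:
# dividing a predictor by s multiplies its coefficient by s, so divide back
rescale_terms <- function(fit, divisors) {
  idx <- match(fit$terms$term, names(divisors))
  d <- ifelse(is.na(idx), 1, divisors[idx])
  for (col in c("estimate", "std_error", "ci_low", "ci_high")) {
    fit$terms[[col]] <- fit$terms[[col]] / d
  }
  fit
}

#' Fixed-effect surface prediction
#'
#' Evaluates the fixed part of a coordinate gradient fit at every ROI
#' centroid: `b0 + b1 x + b2 y + b3 z + b4 xy + b5 xz + b6 yz` (on the
#' centred coordinates the model was fitted with). With
#' `significant_only` (the default) only terms with `p < alpha` enter the
#' prediction (the intercept always does).
#'
#' @param fit a [fit_coordinate_gradient()] result.
#' @param geom a [roi_geometry()] table.
#' @param significant_only zero out non-significant terms?
#' @param alpha significance level.
#' @return Tibble (`roi_id`, `predicted`).
#' @export
predict_fixed_surface <- function(fit, geom, significant_only = TRUE,
                                  alpha = 0.05) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  beta <- setNames(fit$terms$estimate, fit$terms$term)
  pvals <- setNames(fit$terms$p_value, fit$terms$term)
  if (significant_only) {
    drop <- names(beta) != "(Intercept)" &
      (is.na(pvals) | pvals >= alpha)
    beta[drop] <- 0
  }
  xc <- geom$x - fit$centers[["x"]]
  yc <- geom$y - fit$centers[["y"]]
  zc <- geom$z - fit$centers[["z"]]
  g <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  pred <- g("(Intercept)") + g("x") * xc + g("y") * yc + g("z") * zc +
    g("x:y") * xc * yc + g("x:z") * xc * zc + g("y:z") * yc * zc
  tibble::tibble(roi_id = geom$roi_id, predicted = pred)
}

#' Residualize a response on nuisance covariates
#'
#' Fits the response on the covariates (fixed effects, with random
#' intercepts by participant and hemisphere-within-participant), subtracts
#' the fixed-effect prediction, and centres the result — the residual
#' scores (e.g. PFres after removing the 1/f offset and slope, or
#' coordinate-residualized PF/CT). The new column is named
#' `<response>_res`.
#'
#' @param table cohort tibble.
#' @param response response column.
#' @param covariates covariate columns (standardize them first when
#'   comparability of coefficients matters; see
#'   [standardize_within_participant()]).
#' @param df_method passed to [fit_lmem()].
#' @return The table with an added residual column; the underlying
#'   `lmem_fit` is attached as attribute `fit`.
#' @export
residualize <- function(table, response, covariates,
                        df_method = "residual") {
  fit <- fit_lmem(table, response, fixed_terms = covariates,
                  random_terms = c("(1 | participant)",
                                   "(1 | participant:hemisphere)"),
                  df_method = df_method)
  beta <- setNames(fit$terms$estimate, fit$terms$term)
  pred <- rep(beta[["(Intercept)"]], nrow(table))
  for (cv in covariates) pred <- pred + beta[[cv]] * table[[cv]]
  res <- table[[response]] - pred
  res <- res - mean(res, na.rm = TRUE)
  out <- table
  out[[paste0(response, "_res")]] <- res
  attr(out, "fit") <- fit
  out
}

#' Gradient along a one-dimensional spatial axis
#'
#' Models the response as a linear function of a single axis (typically the
#' geodesic distance to a posterior reference parcel), with random
#' intercept and axis slope by participant. Optionally restricted to a
#' subset of ROIs: an annulus, or one of the consecutive Y windows.
#'
#' @param table cohort tibble.
#' @param response response column.
#' @param axis_column axis column (default `"dist_to_reference"`).
#' @param rois optional ROI id subset (e.g. from [select_annulus()]).
#' @param window optional window label; requires a `window` column (see
#'   [split_y_windows()]).
#' @param df_method passed to [fit_lmem()].
#' @return An `lmem_fit`; the axis term keeps the column name.
#' @export
fit_axis_gradient <- function(table, response,
                              axis_column = "dist_to_reference",
                              rois = NULL, window = NULL,
                              df_method = "residual") {
  tab <- table
  if (!is.null(rois)) tab <- dplyr::filter(tab, .data$roi_id %in% rois)
  if (!is.null(window)) {
    if (!"window" %in% names(tab)) {
      stop("no window column; run split_y_windows() first", call. = FALSE)
    }
    tab <- dplyr::filter(tab, .data$window == !!window)
  }
  tab <- tab[is.finite(tab[[axis_column]]), ]
  if (dplyr::n_distinct(tab$roi_id) < 3) {
    stop("fewer than 3 ROIs in subset", call. = FALSE)
  }
  tab[[axis_column]] <- tab[[axis_column]] / coord_scale
  fit <- fit_lmem(tab, response, fixed_terms = axis_column,
                  random_terms = sprintf("(1 + %s | participant)",
                                         axis_column),
                  df_method = df_method)
  rescale_terms(fit, setNames(coord_scale, axis_column))
}

#' Hierarchy-vector model
#'
#' Tests for a monotone change of the (standardized) response along an
#' ordinal hierarchy of parcels (levels 1..k, e.g. a seven-level visual
#' hierarchy V1...7A), with random intercept and level slope by participant
#' plus a hemisphere-within-participant intercept.
#'
#' @param table cohort tibble with a hierarchy-level column (NA for
#'   off-hierarchy ROIs; see [assign_hierarchy()]).
#' @param response response column.
#' @param level_column hierarchy level column.
#' @param standardize z-score the response within participant across the
#'   hierarchy parcels first (the convention for comparing responses on
#'   different scales)?
#' @param df_method passed to [fit_lmem()].
#' @return An `lmem_fit`; the level effect carries the level column name.
#' @export
fit_hierarchy_model <- function(table, response,
                                level_column = "hierarchy_level",
                                standardize = TRUE,
                                df_method = "residual") {
  tab <- table[!is.na(table[[level_column]]), ]
  levels_present <- sort(unique(tab[[level_column]]))
  expected <- seq_len(max(levels_present))
  missing_lv <- setdiff(expected, levels_present)
  if (length(missing_lv)) {
    stop("missing hierarchy levels: ", paste(missing_lv, collapse = ", "),
         call. = FALSE)
  }
  if (standardize) {
    tab <- standardize_within_participant(tab, response)
  }
  tab[[level_column]] <- as.numeric(tab[[level_column]])
  fit_lmem(tab, response, fixed_terms = level_column,
           random_terms = c(sprintf("(1 + %s | participant)", level_column),
                            "(1 | participant:hemisphere)"),
           df_method = df_method)
}

#' Resting-state-network model
#'
#' Categorical model of the response over resting-state networks: a Wald F
#' for the network factor, per-network fixed-effect estimates (cell means),
#' and a sensory-versus-association contrast (sensory = VIS, AUD, SOM by
#' default; association = the rest), all with random intercepts by
#' participant and hemisphere-within-participant.
#'
#' @param table cohort tibble with a network label column.
#' @param response response column.
#' @param network_column label column (default `"network"`).
#' @param sensory labels forming the sensory group.
#' @param df_method passed to [fit_lmem()].
#' @return A list of class `network_fit`: `per_network` (tibble `network`,
#'   `estimate`, `std_error`), `f_statistic`, `f_df`, `f_p_value`,
#'   `contrast` (one-row tibble for the association-vs-sensory term),
#'   `fit` and `contrast_fit` (`lmem_fit` objects).
#' @export
fit_network_model <- function(table, response, network_column = "network",
                              sensory = c("VIS", "AUD", "SOM"),
                              df_method = "residual") {
  tab <- table[!is.na(table[[network_column]]), ]
  tab[[network_column]] <- factor(tab[[network_column]])
  nets <- levels(tab[[network_column]])
  rois_per_net <- vapply(split(tab$roi_id, tab[[network_column]]),
                         dplyr::n_distinct, integer(1))
  if (length(nets) < 2 || sum(rois_per_net >= 2) < 2) {
    stop("need >= 2 networks with >= 2 ROIs each", call. = FALSE)
  }
  fit <- fit_lmem(tab, response, fixed_terms = network_column,
                  random_terms = c("(1 | participant)",
                                   "(1 | participant:hemisphere)"),
                  df_method = df_method)
  # Wald F for the factor: joint test of the q dummy coefficients
  beta_all <- lme4::fixef(fit$model)
  vc <- as.matrix(stats::vcov(fit$model))
  dummy_idx <- grep(paste0("^", network_column), names(beta_all))
  q <- length(dummy_idx)
  b <- beta_all[dummy_idx]
  f_stat <- as.numeric(t(b) %*% solve(vc[dummy_idx, dummy_idx]) %*% b) / q
  df2 <- fit$n_obs - length(beta_all)
  f_p <- stats::pf(f_stat, q, df2, lower.tail = FALSE)
  # cell means from the treatment-coded fit
  lmat <- cbind(1, rbind(0, diag(q)))
  means <- as.numeric(lmat %*% beta_all[c(1, dummy_idx)])
  ses <- sqrt(diag(lmat %*% vc[c(1, dummy_idx), c(1, dummy_idx)] %*%
                     t(lmat)))
  per_network <- tibble::tibble(network = nets, estimate = means,
                                std_error = ses)
  tab$is_association <- as.integer(!(as.character(tab[[network_column]])
                                     %in% sensory))
  cfit <- fit_lmem(tab, response, fixed_terms = "is_association",
                   random_terms = c("(1 | participant)",
                                    "(1 | participant:hemisphere)"),
                   df_method = df_method)
  structure(list(per_network = per_network, f_statistic = f_stat,
                 f_df = c(q, df2), f_p_value = f_p,
                 contrast = lmem_term(cfit, "is_association"),
                 fit = fit, contrast_fit = cfit),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("<network_fit> F(%d, %d) = %.2f, p = %.3g\n",
              x$f_df[1], x$f_df[2], x$f_statistic, x$f_p_value))
  print(as.data.frame(x$per_network), digits = 4)
  cat(sprintf("association vs sensory: t = %.2f, p = %.3g\n",
              x$contrast$statistic, x$contrast$p_value))
  invisible(x)
}
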