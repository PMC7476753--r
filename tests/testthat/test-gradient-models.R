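# small field-level cohorts for model tests
make_model_cohort <- function(n_part = 8, n_roi = 48, slope_y = -0.02,
                              slope_z = 0, ri_sd = 0.3, rs_sd = 0,
                              noise = 0.3, seed = 1) {
  set.seed(seed)
  y <- seq(-70, 70, length.out = n_roi)
  x <- rep(c(-30, 30), length.out = n_roi)
  z <- 40 + 25 * sin(seq(0, 3 * pi, length.out = n_roi))
  u0 <- rnorm(n_part, 0, ri_sd)
  uy <- rnorm(n_part, 0, rs_sd)
  tidyr::crossing(participant = sprintf("p%02d", seq_len(n_part)),
                  roi = seq_len(n_roi)) |>
    dplyr::mutate(
      roi_id = sprintf("r%03d", roi),
      hemisphere = ifelse(x[roi] < 0, "L", "R"),
      x = x[roi], y = y[roi], z = z[roi],
      pf = 10 + u0[as.integer(factor(participant))] +
        (slope_y + uy[as.integer(factor(participant))]) * y +
        slope_z * z + rnorm(dplyr::n(), 0, noise)) |>
    dplyr::select(-"roi")
}

test_that("within-participant standardization is exact and idempotent", {
  tab <- tibble::tibble(participant = rep(c("a", "b"), each = 3),
                        v = c(8, 10, 12, 1, 2, 3))
  st <- standardize_within_participant(tab, "v")
  expect_equal(st$v[1:3], c(-1, 0, 1))
  st2 <- standardize_within_participant(st, "v")
  expect_equal(st2$v, st$v, tolerance = 1e-12)

  set.seed(6)
  big <- tibble::tibble(participant = rep(letters[1:5], each = 30),
                        v = rnorm(150, 5, 3))
  stb <- standardize_within_participant(big, "v")
  per <- dplyr::summarise(dplyr::group_by(stb, participant),
                          m = mean(v), s = sd(v))
  expect_true(all(abs(per$m) < 1e-12))
  expect_equal(per$s, rep(1, 5), tolerance = 1e-12)

  bad <- tibble::tibble(participant = "a", v = c(2, 2, 2))
  expect_error(standardize_within_participant(bad, "v"), "zero")
})

test_that("fit_lmem matches OLS in the zero-variance limit", {
  set.seed(7)
  tab <- make_model_cohort(n_part = 10, n_roi = 50, slope_y = 2,
                           ri_sd = 0, rs_sd = 0, noise = 0.1, seed = 7)
  fit <- fit_lmem(tab, "pf", "y", "(1 | participant)")
  ols <- stats::lm(pf ~ y, data = tab)
  expect_equal(lmem_term_est(fit, "y"), unname(coef(ols)[2]),
               tolerance = 0.01)
  expect_true(lmem_term_est(fit, "y") > 1.9 &&
                lmem_term_est(fit, "y") < 2.1)
})

test_that("fit_lmem flags degenerate and collinear inputs", {
  tab <- make_model_cohort(seed = 8)
  tab$pf <- 7
  fit <- fit_lmem(tab, "pf", "y", "(1 | participant)")
  expect_true(fit$degenerate)
  expect_equal(tidy(fit)$estimate[2], 0)

  tab2 <- make_model_cohort(seed = 9)
  tab2$y2 <- 2 * tab2$y
  expect_error(fit_lmem(tab2, "pf", c("y", "y2"), "(1 | participant)"),
               "collinear.*y2")
})

test_that("missing rows are dropped and counted exactly", {
  tab <- make_model_cohort(seed = 10)
  fit0 <- fit_lmem(tab, "pf", "y", "(1 | participant)")
  tab$pf[c(3, 50, 77)] <- NA
  fit1 <- fit_lmem(tab, "pf", "y", "(1 | participant)")
  expect_identical(fit0$n_obs - fit1$n_obs, 3L)
  expect_identical(fit1$n_dropped, 3L)
})

test_that("mixed-model estimates are calibrated over replicates", {
  ests <- vapply(1:40, function(r) {
    tab <- make_model_cohort(n_part = 6, n_roi = 24, slope_y = -0.02,
                             ri_sd = 0.4, rs_sd = 0.004, noise = 0.35,
                             seed = 100 + r)
    fit <- fit_coordinate_gradient(tab, "pf")
    lmem_term_est(fit, "y")
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-0.02)), 2 * mc_se + 1e-4)
})

test_that("coordinate model recovers a noiseless linear field exactly", {
  tab <- make_model_cohort(n_part = 4, n_roi = 30, slope_y = -0.02,
                           ri_sd = 0, rs_sd = 0, noise = 0, seed = 11)
  # noiseless fit is perfectly collinear for lmer; tiny jitter on the
  # response keeps the solver honest without moving the estimate
  fit <- fit_coordinate_gradient(
    dplyr::mutate(tab, pf = pf + rep(c(1e-9, -1e-9),
                                     length.out = dplyr::n())), "pf")
  expect_equal(lmem_term_est(fit, "y"), -0.02, tolerance = 1e-6)
})

test_that("coordinate model separates true and null axes", {
  tab <- make_model_cohort(n_part = 10, n_roi = 48, slope_y = -0.02,
                           slope_z = 0, ri_sd = 0.4, rs_sd = 0.003,
                           noise = 0.35, seed = 12)
  fit <- fit_coordinate_gradient(tab, "pf")
  yt <- dplyr::filter(tidy(fit), term == "y")
  zt <- dplyr::filter(tidy(fit), term == "z")
  expect_lt(yt$estimate, 0)
  expect_lt(abs(yt$estimate - (-0.02)) / 0.02, 0.15)
  expect_lt(yt$p_value, 0.001)
  expect_gt(zt$p_value, 0.001)
})

test_that("shuffled responses do not produce spurious axis gradients", {
  pvals <- vapply(1:20, function(r) {
    tab <- make_model_cohort(n_part = 6, n_roi = 24, slope_y = -0.02,
                             ri_sd = 0.3, rs_sd = 0, noise = 0.3,
                             seed = 300 + r)
    tab <- tab |>
      dplyr::group_by(participant) |>
      dplyr::mutate(pf = sample(pf)) |>
      dplyr::ungroup() |>
      dplyr::mutate(dist_to_reference = y + 70)
    fit <- fit_axis_gradient(tab, "pf")
    dplyr::filter(tidy(fit), term == "dist_to_reference")$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.2)
})

test_that("residualization preserves orthogonal structure", {
  set.seed(13)
  tab <- make_model_cohort(n_part = 8, n_roi = 60, slope_y = 0,
                           ri_sd = 0, rs_sd = 0, noise = 1, seed = 13)
  tab$cov <- rnorm(nrow(tab))            # uncorrelated covariate
  res <- residualize(tab, "pf", "cov")
  centred <- tab$pf - mean(tab$pf)
  expect_gt(cor(res$pf_res, centred), 0.99)
  expect_lt(abs(mean(res$pf_res)), 1e-6)

  tab2 <- tab
  tab2$pf <- 3 * tab2$cov + 5
  res2 <- residualize(tab2, "pf", "cov")
  expect_lt(sd(res2$pf_res), 1e-6)
})

test_that("gradients survive residualizing out a coupled covariate", {
  set.seed(14)
  tab <- make_model_cohort(n_part = 10, n_roi = 48, slope_y = -0.02,
                           ri_sd = 0.3, rs_sd = 0, noise = 0.2, seed = 14)
  slope_jit <- rnorm(nrow(tab), 0, 0.05)
  tab$aperiodic_slope <- -1.2 + slope_jit
  tab$pf <- tab$pf + 4 * slope_jit
  tab <- standardize_within_participant(tab, "aperiodic_slope")
  res <- residualize(tab, "pf", "aperiodic_slope")
  fit <- fit_coordinate_gradient(res, "pf_res")
  yt <- dplyr::filter(tidy(fit), term == "y")
  expect_lt(abs(yt$estimate - (-0.02)) / 0.02, 0.15)
  expect_lt(yt$p_value, 0.001)
})

test_that("fixed-effect surface prediction is plain polynomial evaluation", {
  mk_fit <- function(beta, p = rep(0, 7)) {
    structure(list(
      terms = tibble::tibble(
        term = c("(Intercept)", "x", "y", "z", "x:y", "x:z", "y:z"),
        estimate = beta, std_error = 1, df = 10, statistic = beta,
        p_value = p, ci_low = beta, ci_high = beta),
      centers = c(x = 0, y = 0, z = 0), converged = TRUE),
      class = "lmem_fit")
  }
  geom <- tibble::tibble(roi_id = "A", x = 0, y = 50, z = 0)
  pred <- predict_fixed_surface(mk_fit(c(0, 0, -0.02, 0, 0, 0, 0)), geom)
  expect_equal(pred$predicted, -1.0)
  expect_equal(
    predict_fixed_surface(mk_fit(rep(0, 7)), geom)$predicted, 0)

  set.seed(15)
  beta <- rnorm(7)
  geom2 <- tibble::tibble(roi_id = sprintf("r%02d", 1:20),
                          x = rnorm(20, 0, 30), y = rnorm(20, 0, 40),
                          z = rnorm(20, 40, 15))
  pred2 <- predict_fixed_surface(mk_fit(beta), geom2,
                                 significant_only = FALSE)
  oracle <- beta[1] + beta[2] * geom2$x + beta[3] * geom2$y +
    beta[4] * geom2$z + beta[5] * geom2$x * geom2$y +
    beta[6] * geom2$x * geom2$z + beta[7] * geom2$y * geom2$z
  expect_equal(pred2$predicted, oracle, tolerance = 1e-12)
  # non-significant terms are zeroed when requested
  pred3 <- predict_fixed_surface(mk_fit(beta, p = rep(1, 7)), geom2)
  expect_equal(pred3$predicted, rep(beta[1], 20), tolerance = 1e-12)
})

test_that("axis gradients work on subsets and demand enough ROIs", {
  tab <- make_model_cohort(n_part = 8, n_roi = 48, slope_y = -0.02,
                           ri_sd = 0.3, rs_sd = 0, noise = 0.3, seed = 16)
  tab$dist_to_reference <- tab$y + 70
  fit <- fit_axis_gradient(tab, "pf")
  dt <- dplyr::filter(tidy(fit), term == "dist_to_reference")
  expect_lt(dt$estimate, 0)
  expect_lt(dt$p_value, 0.001)
  sub <- unique(tab$roi_id)[1:2]
  expect_error(fit_axis_gradient(tab, "pf", rois = sub), "3 ROIs")
  expect_error(fit_axis_gradient(tab, "pf", window = "w1"), "window")
})

test_that("hierarchy model recovers per-level steps and their sign", {
  set.seed(17)
  base <- tidyr::crossing(participant = sprintf("p%02d", 1:10),
                          hemisphere = c("L", "R"),
                          hierarchy_level = 1:7)
  tab <- dplyr::mutate(base,
                       roi_id = paste0("h", hierarchy_level, hemisphere),
                       pf = 11 - 0.5 * hierarchy_level +
                         rnorm(dplyr::n(), 0, 0.05))
  fit <- fit_hierarchy_model(tab, "pf", standardize = FALSE)
  est <- lmem_term_est(fit, "hierarchy_level")
  expect_lt(abs(est - (-0.5)) / 0.5, 0.1)

  tab$ct <- 2 + 0.1 * tab$hierarchy_level + rnorm(nrow(tab), 0, 0.02)
  fit_ct <- fit_hierarchy_model(tab, "ct", standardize = FALSE)
  expect_gt(lmem_term_est(fit_ct, "hierarchy_level"), 0)

  tab$flat <- rnorm(nrow(tab), 5, 0.3)
  fit_flat <- fit_hierarchy_model(tab, "flat", standardize = FALSE)
  expect_gt(dplyr::filter(tidy(fit_flat),
                          term == "hierarchy_level")$p_value, 0.05)

  expect_error(
    fit_hierarchy_model(dplyr::filter(tab, hierarchy_level != 3), "pf"),
    "missing hierarchy levels: 3")
})

test_that("network model detects shifted networks and codes the contrast", {
  set.seed(18)
  nets <- c("VIS", "AUD", "SOM", "DAN", "VAN", "CON", "FPN", "DMN")
  base <- tidyr::crossing(participant = sprintf("p%02d", 1:10),
                          hemisphere = c("L", "R"),
                          roi = 1:40) |>
    dplyr::mutate(roi_id = paste0("r", roi, hemisphere),
                  network = nets[(roi - 1) %% 8 + 1])
  null_tab <- dplyr::mutate(base, pf = rnorm(dplyr::n(), 10, 0.5))
  fm0 <- fit_network_model(null_tab, "pf")
  expect_gt(fm0$f_p_value, 0.05)

  shift <- dplyr::mutate(base,
                         pf = rnorm(dplyr::n(), 10, 0.5) +
                           ifelse(network == "DMN", 1, 0))
  fm1 <- fit_network_model(shift, "pf")
  expect_lt(fm1$f_p_value, 0.001)
  best <- fm1$per_network$network[which.max(fm1$per_network$estimate)]
  expect_identical(best, "DMN")
  # DMN is an association network, so its excess raises the contrast
  expect_gt(fm1$contrast$statistic, 2)

  solo <- dplyr::mutate(base, network = "VIS",
                        pf = rnorm(dplyr::n(), 10, 0.5))
  expect_error(fit_network_model(solo, "pf"), "2 networks")
})
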