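#' Trimmed mean
#'
#' Mean after discarding `floor(trim * n)` smallest and largest values
#' (missing values are removed first). The 10% default discards 10% from
#' each tail, the robust pooling rule used for spectra and for
#' across-participant ROI summaries.
#'
#' @param values numeric vector.
#' @param trim_proportion proportion per tail, in \[0, 0.5).
#' @return Scalar; `NA` when all values are missing.
#' @export
trimmed_mean <- function(values, trim_proportion = 0.1) {
  stopifnot(trim_proportion >= 0, trim_proportion < 0.5)
  x <- values[!is.na(values)]
  if (length(x) == 0) return(NA_real_)
  mean(x, trim = trim_proportion)
}

#' Spatial (geometric) median of bivariate points
#'
#' Weiszfeld iteration for the point minimizing the sum of Euclidean
#' distances; the robust centre used by the skipped-correlation outlier
#' rule.
#'
#' @param xy two-column matrix.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return Length-2 numeric vector.
#' @export
spatial_median <- function(xy, tol = 1e-8, max_iter = 200) {
  m <- c(median(xy[, 1]), median(xy[, 2]))
  for (it in seq_len(max_iter)) {
    d <- sqrt((xy[, 1] - m[1])^2 + (xy[, 2] - m[2])^2)
    if (any(d < 1e-12)) d[d < 1e-12] <- 1e-12
    w <- 1 / d
    m_new <- c(sum(w * xy[, 1]), sum(w * xy[, 2])) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Skipped Pearson correlation
#'
#' Pearson correlation after removing bivariate outliers by the projection
#' rule: points are centred at the spatial median; for every data point,
#' all points are projected onto the direction from the centre to that
#' point, and any point whose projected distance violates the MAD-median
#' rule (cutoff `sqrt(qchisq(cutoff_quantile, 2))` times the MAD) on any
#' projection is skipped. Significance is from the t distribution with
#' `n_used - 2` df. Mirrors the robust-correlation-toolbox family of
#' skipped estimators; the exact flagged set may differ from any one
#' implementation. The default cutoff quantile (0.999) keeps the
#' false-flag rate on clean Gaussian data near 0.1% — because flagging is
#' a union over one projection per data point, the conventional per-test
#' 0.975 quantile would flag several percent of clean points and pull the
#' estimate measurably away from Pearson; gross contamination is many MADs
#' out and is caught at either setting.
#'
#' @param x,y paired numeric vectors, `n >= 10` finite pairs.
#' @param cutoff_quantile chi-square quantile for the projection cutoff.
#' @return A list of class `skipped_cor`: `r`, `p`, `n_used`, `n_skipped`,
#'   `outlier_indices` (indices into the finite pairs, original order).
#' @export
skipped_pearson <- function(x, y, cutoff_quantile = 0.999) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 paired finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  pts <- cbind(x, y)
  center <- spatial_median(pts)
  centred <- sweep(pts, 2, center)
  cutoff <- sqrt(qchisq(cutoff_quantile, df = 2))
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dir <- centred[i, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-12) next
    proj <- as.numeric(centred %*% (dir / nrm))
    m <- median(proj)
    s <- mad(proj)
    if (s < 1e-12) next
    flagged <- flagged | (abs(proj - m) > cutoff * s)
  }
  n_used <- sum(!flagged)
  if (n_used < 4) stop("fewer than 4 points survive skipping", call. = FALSE)
  r <- cor(x[!flagged], y[!flagged])
  tstat <- r * sqrt((n_used - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n_used - 2)
  structure(list(r = r, p = p, n_used = n_used, n_skipped = sum(flagged),
                 outlier_indices = which(flagged)),
            class = "skipped_cor")
}

#' @export
print.skipped_cor <- function(x, ...) {
  cat(sprintf("<skipped_cor> r = %.3f (p = %.3g), %d used / %d skipped\n",
              x$r, x$p, x$n_used, x$n_skipped))
  invisible(x)
}

#' Per-participant correlation consistency
#'
#' Pearson correlation between two columns across each participant's ROIs,
#' the fraction of participants individually significant (p below `alpha`
#' with the modal sign), and a one-sample two-sided t test of the
#' correlation values against zero (on raw r by default; `fisher_z` tests
#' the Fisher-transformed values).
#'
#' @param table cohort tibble.
#' @param x_column,y_column column names.
#' @param alpha individual significance level.
#' @param fisher_z t test on `atanh(r)` instead of raw r?
#' @return A list: `per_participant` (tibble `participant`, `n`, `r`, `p`),
#'   `fraction_significant`, `modal_sign`, `t`, `p`, `n_participants`.
#' @export
individual_correlation_consistency <- function(table, x_column, y_column,
                                               alpha = 0.05,
                                               fisher_z = FALSE) {
  per <- table |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(function(g, key) {
      xv <- g[[x_column]]; yv <- g[[y_column]]
      ok <- is.finite(xv) & is.finite(yv)
      if (sum(ok) < 10) {
        warning("participant ", key$participant,
                " excluded: fewer than 10 complete ROI pairs",
                call. = FALSE)
        return(NULL)
      }
      if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
        warning("participant ", key$participant,
                " excluded: zero variance", call. = FALSE)
        return(NULL)
      }
      ct <- cor.test(xv[ok], yv[ok])
      tibble::tibble(participant = key$participant, n = sum(ok),
                     r = unname(ct$estimate), p = ct$p.value)
    }) |>
    dplyr::bind_rows()
  if (nrow(per) == 0) stop("no usable participants", call. = FALSE)
  modal_sign <- sign(sum(sign(per$r)))
  if (modal_sign == 0) modal_sign <- 1
  frac <- mean(per$p < alpha & sign(per$r) == modal_sign)
  vals <- if (fisher_z) atanh(pmin(pmax(per$r, -1 + 1e-12), 1 - 1e-12))
  else per$r
  if (nrow(per) >= 2 && sd(vals) > 0) {
    tt <- t.test(vals)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  } else {
    t_stat <- NA_real_
    t_p <- NA_real_
  }
  list(per_participant = per, fraction_significant = frac,
       modal_sign = modal_sign, t = t_stat, p = t_p,
       n_participants = nrow(per))
}
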