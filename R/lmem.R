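#' Z-score columns within participant
#'
#' Standardizes the named columns to mean 0, SD 1 across each participant's
#' ROIs (subtracting the participant mean and dividing by the participant
#' SD), the normalization applied before residualization and hierarchy
#' models.
#'
#' @param table a cohort tibble with a `participant` column.
#' @param columns character vector of column names.
#' @return The table with the named columns standardized.
#' @export
standardize_within_participant <- function(table, columns) {
  for (col in columns) {
    if (!col %in% names(table)) stop("no column ", col, call. = FALSE)
  }
  zscore <- function(x, pid, col) {
    ok <- !is.na(x)
    if (sum(ok) < 2) {
      stop("participant ", pid, " has < 2 non-missing values in ", col,
           call. = FALSE)
    }
    s <- sd(x[ok])
    if (s == 0) {
      stop("zero within-participant variance for participant ", pid,
           " in ", col, call. = FALSE)
    }
    (x - mean(x[ok])) / s
  }
  table |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(columns),
      ~ zscore(.x, dplyr::cur_group()$participant, dplyr::cur_column())
    )) |>
    dplyr::ungroup()
}

term_columns <- function(fixed_terms) {
  unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
}

random_group_columns <- function(random_terms) {
  groups <- sub(".*\\|", "", gsub("[()]", "", random_terms))
  unique(trimws(unlist(strsplit(groups, ":", fixed = TRUE))))
}

#' Fit a linear mixed-effect model on a cohort table
#'
#' REML fit (via lme4) with fixed terms and lme4-style random-effect terms.
#' Fixed-effect t values are `estimate / SE`; two-sided p values use
#' residual degrees of freedom (`n_obs - n_fixed`) by default, or
#' Satterthwaite approximation. Rows with missing response or predictors
#' are dropped and counted. Collinear fixed terms raise an error naming the
#' aliased terms. A fit that fails to converge is refitted with random
#' slopes removed and flagged `reduced`; if that also fails, `converged` is
#' `FALSE` and estimates are `NA` — never silent.
#'
#' @param table cohort tibble.
#' @param response response column name.
#' @param fixed_terms character vector of fixed-effect terms (columns or
#'   `"a:b"` interactions).
#' @param random_terms character vector of parenthesized lme4 random terms,
#'   e.g. `"(1 + y | participant)"`.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param alpha level for confidence bounds.
#' @return An object of class `lmem_fit`; see [tidy.lmem_fit()] and
#'   [glance.lmem_fit()].
#' @export
fit_lmem <- function(table, response, fixed_terms,
                     random_terms = "(1 | participant)",
                     df_method = c("residual", "satterthwaite"),
                     alpha = 0.05) {
  df_method <- match.arg(df_method)
  needed <- unique(c(response, term_columns(fixed_terms),
                     random_group_columns(random_terms)))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(table[, needed, drop = FALSE])
  keep <- complete.cases(data)
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  n_obs <- nrow(data)
  if (n_obs < length(fixed_terms) * 2 + 2) {
    stop("too few complete observations (", n_obs, ")", call. = FALSE)
  }
  mm <- model.matrix(stats::reformulate(fixed_terms), data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("collinear fixed terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (var(data[[response]]) == 0) {
    est <- c(data[[response]][1], rep(0, ncol(mm) - 1))
    terms_tbl <- tibble::tibble(
      term = colnames(mm), estimate = est, std_error = NA_real_,
      df = NA_real_, statistic = NA_real_, p_value = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_)
    return(structure(list(terms = terms_tbl, model = NULL, n_obs = n_obs,
                          n_dropped = n_dropped, converged = TRUE,
                          singular = TRUE, reduced = FALSE,
                          degenerate = TRUE, df_method = df_method,
                          varcor = NULL, logLik = NA_real_,
                          formula = NULL),
                     class = "lmem_fit"))
  }
  form <- stats::as.formula(paste(
    response, "~", paste(c(fixed_terms, random_terms), collapse = " + ")))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa")
  fit_once <- function(f) {
    warns <- character(0)
    fit <- withCallingHandlers(
      tryCatch(lmerTest::lmer(f, data = data, REML = TRUE, control = ctrl),
               error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    list(fit = fit, warns = warns)
  }
  res <- fit_once(form)
  failed <- inherits(res$fit, "condition") ||
    any(grepl("converge", res$warns, ignore.case = TRUE))
  reduced <- FALSE
  if (failed && any(grepl("\\+.*\\|", random_terms))) {
    reduced_terms <- unique(vapply(random_terms, function(tm) {
      sub("\\(.*\\|", "(1 |", tm)
    }, character(1)))
    form2 <- stats::as.formula(paste(
      response, "~", paste(c(fixed_terms, reduced_terms), collapse = " + ")))
    res2 <- fit_once(form2)
    if (!inherits(res2$fit, "condition") &&
        !any(grepl("converge", res2$warns, ignore.case = TRUE))) {
      warning("random slopes removed after non-convergence; ",
              "reporting the reduced model", call. = FALSE)
      res <- res2
      reduced <- TRUE
      failed <- FALSE
    }
  }
  if (inherits(res$fit, "condition")) {
    stop("mixed-model fit failed: ", conditionMessage(res$fit),
         call. = FALSE)
  }
  fit <- res$fit
  converged <- !failed
  if (df_method == "satterthwaite") {
    co <- coef(summary(fit, ddf = "Satterthwaite"))
    dfs <- co[, "df"]
    ps <- co[, "Pr(>|t|)"]
  } else {
    co <- coef(summary(fit, ddf = "lme4"))
    dfs <- rep(n_obs - nrow(co), nrow(co))
    ps <- 2 * pt(-abs(co[, "t value"]), dfs)
  }
  tcrit <- stats::qt(1 - alpha / 2, dfs)
  terms_tbl <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    df = unname(dfs),
    statistic = unname(co[, "Estimate"] / co[, "Std. Error"]),
    p_value = unname(ps),
    ci_low = unname(co[, "Estimate"] - tcrit * co[, "Std. Error"]),
    ci_high = unname(co[, "Estimate"] + tcrit * co[, "Std. Error"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(terms = terms_tbl, model = fit, n_obs = n_obs,
                 n_dropped = n_dropped, converged = converged,
                 singular = lme4::isSingular(fit), reduced = reduced,
                 degenerate = FALSE, df_method = df_method,
                 varcor = tibble::as_tibble(vc),
                 logLik = as.numeric(stats::logLik(fit)), formula = form),
            class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat("<lmem_fit> n =", x$n_obs,
      if (x$n_dropped) paste0("(", x$n_dropped, " rows dropped)"),
      if (!x$converged) "[NOT CONVERGED]",
      if (x$reduced) "[reduced: slopes dropped]",
      if (x$singular) "[singular]", "\n")
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Tidy a mixed-model fit
#'
#' @param x an `lmem_fit`.
#' @param ... unused.
#' @return Tibble (`term`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`, `ci_low`, `ci_high`).
#' @exportS3Method generics::tidy
tidy.lmem_fit <- function(x, ...) x$terms

#' One-row summary of a mixed-model fit
#'
#' @param x an `lmem_fit`.
#' @param ... unused.
#' @return One-row tibble (`n_obs`, `n_dropped`, `logLik`, `converged`,
#'   `singular`, `reduced`, `df_method`).
#' @exportS3Method generics::glance
glance.lmem_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_dropped = x$n_dropped,
                 logLik = x$logLik, converged = x$converged,
                 singular = x$singular, reduced = x$reduced,
                 df_method = x$df_method)
}

lmem_term <- function(fit, term) {
  dplyr::filter(fit$terms, .data$term == !!term)
}
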