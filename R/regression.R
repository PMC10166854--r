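#' Z-score selected columns of a cohort table
#'
#' @param table Data frame.
#' @param columns Character vector of numeric columns to transform to mean 0,
#'   SD 1 (sample SD, denominator n - 1).
#' @return The table with the named columns standardized.
#' @export
standardize <- function(table, columns) {
  stopifnot(is.data.frame(table))
  for (col in columns) {
    x <- table[[col]]
    if (is.null(x) || !is.numeric(x))
      stop(sprintf("column '%s' is missing or non-numeric", col), call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column '%s' has zero variance; cannot standardize", col),
           call. = FALSE)
    table[[col]] <- (x - mean(x)) / s
  }
  table
}

#' Ordinary least-squares fit with standardized coefficients
#'
#' Fits the response on the given predictors twice: on the raw scale and on
#' z-scored response and predictors, so that the reported coefficients are
#' standardized betas. P-values are two-sided t-tests per coefficient.
#'
#' @param table Data frame with complete rows for the named columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns (may be empty:
#'   intercept-only model).
#' @return Object of class `fitted_model`: `predictors` (in the given order),
#'   `beta_std`, `beta_raw`, `p_values`, `r_squared`, `rss` (standardized
#'   scale), `n`, `df_residual`.
#' @export
ols_fit <- function(table, response, predictors = character(0)) {
  cols <- c(response, predictors)
  if (anyNA(table[cols]))
    stop("missing values in model columns; filter rows first", call. = FALSE)
  n <- nrow(table)
  std <- standardize(table, cols)
  fml <- if (length(predictors) == 0L) {
    stats::reformulate("1", response)
  } else {
    stats::reformulate(sprintf("`%s`", predictors), response)
  }
  fit_std <- stats::lm(fml, data = std)
  fit_raw <- stats::lm(fml, data = table)
  if (fit_std$rank < length(predictors) + 1L) {
    ali <- predictors[is.na(stats::coef(fit_std)[-1])]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(ali, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit_std)
  co <- sm$coefficients
  beta_std <- if (length(predictors)) co[-1, 1] else numeric(0)
  pvals <- if (length(predictors)) co[-1, 4] else numeric(0)
  names(beta_std) <- names(pvals) <- predictors
  beta_raw <- stats::coef(fit_raw)
  rss <- sum(stats::residuals(fit_std)^2)
  structure(list(predictors = predictors,
                 beta_std = beta_std,
                 beta_raw = beta_raw,
                 p_values = pvals,
                 r_squared = if (length(predictors)) sm$r.squared else 0,
                 rss = rss,
                 n = n,
                 df_residual = fit_std$df.residual,
                 response = response),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %s ~ %s  (n=%d, R^2=%.3f)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n, x$r_squared))
  if (length(x$predictors)) {
    for (p in x$predictors)
      cat(sprintf("  %-24s beta=% .3f  p=%.4g\n", p, x$beta_std[p], x$p_values[p]))
  }
  invisible(x)
}

# one forward-selection pass: starting from `selected` (kept in the model
# whether or not significant), greedily add candidates from `pool` while the
# best candidate's coefficient p-value is below alpha. Tie rule: lowest p,
# then larger |t| (via p recomputation this is equivalent), then pool order.
forward_pass <- function(table, response, selected, pool, alpha) {
  remaining <- setdiff(pool, selected)
  repeat {
    if (length(remaining) == 0L) break
    best_p <- Inf; best_t <- -Inf; best <- NULL
    for (cand in remaining) {
      fit <- ols_fit(table, response, c(selected, cand))
      if (fit$df_residual < 1L) next
      p <- fit$p_values[[cand]]
      if (!is.finite(p)) next  # degenerate fit (e.g. zero residual already)
      tval <- abs(stats::qt(p / 2, fit$df_residual))
      if (p < best_p - 1e-12 ||
          (abs(p - best_p) <= 1e-12 && tval > best_t + 1e-12)) {
        best_p <- p; best_t <- tval; best <- cand
      }
    }
    if (!is.null(best) && best_p < alpha) {
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    } else break
  }
  selected
}

#' Forward-selection multivariate linear regression
#'
#' Iteratively adds, from the candidate pool, the predictor whose coefficient
#' t-test p-value (in the model including the already-selected predictors) is
#' lowest and below `alpha`; stops when no remaining candidate qualifies.
#' Ties in p are broken by larger |t|, then pool order. An empty selection
#' (intercept-only model) is a valid outcome.
#'
#' @param table Data frame.
#' @param response Response column.
#' @param pool Character vector of candidate predictors.
#' @param alpha Entry threshold (default 0.05).
#' @param locked Predictors kept in the model from the start (not counted
#'   against `alpha`); used by the second stage of [two_stage_select()].
#' @return A `fitted_model` of the final model; selection order is the order
#'   of `predictors`.
#' @export
forward_select <- function(table, response, pool, alpha = 0.05,
                           locked = character(0)) {
  if (length(pool) == 0L)
    stop("candidate pool is empty", call. = FALSE)
  selected <- forward_pass(table, response, locked, pool, alpha)
  ols_fit(table, response, selected)
}

#' Two-stage forward selection with nested-model comparison
#'
#' Stage 1 forward-selects over patient-specific pre-treatment variables.
#' Stage 2 keeps the stage-1 predictors locked in and forward-selects over
#' treatment-specific variables. The extended model is compared with the
#' baseline by nested ANOVA on residual sums of squares.
#'
#' @param table Data frame.
#' @param response Response column.
#' @param patient_pool,treatment_pool Disjoint candidate pools.
#' @param alpha Entry threshold.
#' @return List with `baseline` and `extended` (`fitted_model`s) and
#'   `comparison` (a `model_comparison`, or a flagged identical-models result
#'   when stage 2 selects nothing).
#' @export
two_stage_select <- function(table, response, patient_pool, treatment_pool,
                             alpha = 0.05) {
  if (length(intersect(patient_pool, treatment_pool)) > 0L)
    stop(sprintf("pools overlap: %s",
                 paste(intersect(patient_pool, treatment_pool), collapse = ", ")),
         call. = FALSE)
  baseline <- forward_select(table, response, patient_pool, alpha)
  extended <- if (length(treatment_pool) == 0L) baseline else
    forward_select(table, response, treatment_pool, alpha,
                   locked = baseline$predictors)
  comparison <- if (identical(sort(baseline$predictors),
                              sort(extended$predictors))) {
    structure(list(identical_models = TRUE, f = NA_real_, p = NA_real_,
                   df = c(NA_integer_, NA_integer_)),
              class = "model_comparison")
  } else {
    anova_compare(baseline, extended)
  }
  list(baseline = baseline, extended = extended, comparison = comparison)
}

#' Nested-model ANOVA comparison of residual sums of squares
#'
#' F = ((RSS_small - RSS_large) / d_extra) / (RSS_large / (n - p_large - 1)),
#' with the p-value from the F distribution on (d_extra, n - p_large - 1)
#' degrees of freedom.
#'
#' @param small,large `fitted_model`s on the same rows; `small$predictors`
#'   must be a strict subset of `large$predictors`.
#' @return Object of class `model_comparison`: `f`, `p`, `df` (pair),
#'   `identical_models = FALSE`.
#' @export
anova_compare <- function(small, large) {
  stopifnot(inherits(small, "fitted_model"), inherits(large, "fitted_model"))
  if (small$n != large$n)
    stop("models were fitted on different numbers of rows", call. = FALSE)
  if (!all(small$predictors %in% large$predictors))
    stop("models are not nested", call. = FALSE)
  extra <- setdiff(large$predictors, small$predictors)
  if (length(extra) == 0L)
    stop("models have identical predictor sets; nothing to compare",
         call. = FALSE)
  df1 <- length(extra)
  df2 <- large$n - length(large$predictors) - 1L
  f <- ((small$rss - large$rss) / df1) / (large$rss / df2)
  structure(list(identical_models = FALSE,
                 f = f,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 df = c(df1, df2)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  if (isTRUE(x$identical_models)) {
    cat("model_comparison: identical models (stage 2 selected nothing)\n")
  } else {
    cat(sprintf("model_comparison: F(%d,%d) = %.3f, p = %.4g\n",
                x$df[1], x$df[2], x$f, x$p))
  }
  invisible(x)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors, length >= 3, both with nonzero SD.
#' @return List with `r`, `p`, `r_squared`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       r_squared = unname(ct$estimate)^2, n = length(x))
}
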