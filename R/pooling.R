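# Final analysis per imputed dataset and Rubin's-rules pooling.

#' Cox analysis of one (imputed or complete) dataset
#'
#' Fits the regular Cox proportional-hazards model for treatment,
#' adjusting for the same baseline covariates as the imputation model,
#' and extracts the treatment log hazard-ratio and its standard error.
#'
#' @param data a `trial_dataset` with no unimputed missing data left.
#' @param covariates baseline covariate names.
#' @param b imputation index carried through for bookkeeping.
#' @return Object of class `imputation_estimate`: list `b`, `loghr`,
#'   `se`, `events_by_arm` (named vector, placebo/active).
#' @export
analyze_imputed <- function(data, covariates = character(), b = NA_integer_) {
  stopifnot(inherits(data, "trial_dataset"))
  fit <- survival::coxph(.rd_formula(covariates), data = data$subjects,
                         ties = "efron")
  cf <- stats::coef(fit)
  if (is.na(cf["trt"])) {
    stop("final Cox model did not converge (imputation ",
         if (is.na(b)) "?" else b, ")", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))["trt"]
  ev <- tapply(data$subjects$E, data$subjects$trt, sum)
  structure(list(b = b,
                 loghr = unname(cf["trt"]),
                 se = unname(se),
                 events_by_arm = c(placebo = unname(ev["0"]),
                                   active = unname(ev["1"]))),
            class = "imputation_estimate")
}

#' Pool per-imputation estimates with Rubin's rules
#'
#' Pooled point estimate is the mean of the `B` log hazard-ratios; total
#' variance is `W + (1 + 1/B) * B_var` with `W` the mean squared standard
#' error and `B_var` the between-imputation variance. Inference uses the
#' t reference with Rubin (1987) degrees of freedom
#' `(B - 1) (1 + W / ((1 + 1/B) B_var))^2`; when `B_var = 0` the degrees
#' of freedom are infinite (normal reference).
#'
#' @param estimates list of `imputation_estimate` objects (`B >= 1`; a
#'   single estimate is passed through with a warning).
#' @param conf_level confidence level for the HR-scale interval.
#' @return Object of class `pooled_result` with `loghr`, `se`,
#'   `within_var`, `between_var`, `df`, `hr`, `ci` (HR scale),
#'   `p_value`, `B`, `events_by_arm` (mean across imputations) and
#'   `per_imputation` (data.frame of the inputs).
#' @export
rubin_pool <- function(estimates, conf_level = 0.95) {
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  if (inherits(estimates, "imputation_estimate")) estimates <- list(estimates)
  B <- length(estimates)
  loghr <- vapply(estimates, `[[`, numeric(1), "loghr")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  stopifnot(all(se > 0))
  if (B == 1) {
    warning("pooling a single imputation: between-imputation variance ",
            "cannot be estimated", call. = FALSE)
  }
  qbar <- mean(loghr)
  W <- mean(se^2)
  B_var <- if (B > 1) stats::var(loghr) else 0
  total <- W + (1 + 1 / B) * B_var
  se_pool <- sqrt(total)
  if (B_var > 0) {
    df <- (B - 1) * (1 + W / ((1 + 1 / B) * B_var))^2
  } else {
    df <- Inf
  }
  tstat <- qbar / se_pool
  p <- 2 * stats::pt(-abs(tstat), df = df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  ev <- vapply(estimates, function(e) unname(e$events_by_arm[c("placebo", "active")]),
               numeric(2))
  rownames(ev) <- c("placebo", "active")
  structure(list(loghr = qbar, se = se_pool, within_var = W,
                 between_var = B_var, df = df,
                 hr = exp(qbar),
                 ci = exp(qbar + c(-1, 1) * crit * se_pool),
                 p_value = p, B = B,
                 conf_level = conf_level,
                 events_by_arm = rowMeans(ev),
                 per_imputation = data.frame(
                   b = vapply(estimates, `[[`, numeric(1), "b"),
                   loghr = loghr, se = se)),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled result over B = %d imputation(s)\n", x$B))
  cat(sprintf("  HR %.4f (%.0f%% CI %.4f, %.4f), p = %.4g\n",
              x$hr, 100 * x$conf_level, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  log-HR %.5f (SE %.5f); W = %.3g, B_var = %.3g, df = %s\n",
              x$loghr, x$se, x$within_var, x$between_var,
              if (is.finite(x$df)) sprintf("%.1f", x$df) else "Inf"))
  cat(sprintf("  mean events: placebo %.1f, active %.1f\n",
              x$events_by_arm["placebo"], x$events_by_arm["active"]))
  invisible(x)
}

#' Run the full retrieved-dropout multiple-imputation pipeline
#'
#' End to end: classify disposition, fit the imputation model on the
#' retrieved-dropout subset, produce `B` proper parameter draws (or `B`
#' bootstrap refits), impute every missing-data subject, analyze each
#' completed dataset with the Cox model, and pool with Rubin's rules.
#' With no missing-data subjects imputation is a no-op and the result
#' equals the plain Cox analysis of the input data exactly (between-
#' imputation variance zero, normal reference).
#'
#' @param data a `trial_dataset`.
#' @param method `"bootstrap"`, `"pwe"`, `"weibull"`, `"j2r"`, or
#'   `"cph"` (no imputation: regular Cox with censoring at dropout).
#' @param B number of imputations (`>= 2` recommended).
#' @param seed master integer seed; one seed reproduces the whole run.
#' @param covariates baseline covariate names.
#' @param grid_width_days bootstrap grid spacing in days.
#' @param cutpoints piecewise-exponential cuts (see [resolve_cutpoints()]).
#' @param partial_cov piecewise-exponential only: sample regression
#'   coefficients while holding baseline hazards at the MLE.
#' @return A `pooled_result` (for `"cph"`, a `B = 1` pooled result built
#'   from the single Cox fit, no warning).
#' @export
run_mird <- function(data, method = c("bootstrap", "pwe", "weibull", "j2r",
                                      "cph"),
                     B = 100, seed = 1, covariates = character(),
                     grid_width_days = 60, cutpoints = "quartiles",
                     partial_cov = FALSE) {
  stopifnot(inherits(data, "trial_dataset"))
  method <- match.arg(method)
  part <- classify_disposition(data)
  mird_log("disposition: ", length(part$completers), " completers, ",
           length(part$retrieved_dropouts), " RDs, ",
           length(part$missing), " missing")
  plain <- function() {
    est <- analyze_imputed(data, covariates, b = 1L)
    suppressWarnings(rubin_pool(list(est)))
  }
  if (method == "cph" || length(part$missing) == 0) return(plain())
  rd <- subset_trial(data, part$retrieved_dropouts)
  if (method == "bootstrap") {
    inputs <- bootstrap_refits(rd, B, seed, covariates)
  } else if (method == "pwe") {
    fit <- fit_pwe(rd, cutpoints, covariates)
    inputs <- draw_parameters_mle(fit, B, seed, partial_cov = partial_cov)
  } else {
    fit <- fit_weibull_aft(rd, covariates)
    inputs <- draw_parameters_mle(fit, B, seed)
  }
  U <- draw_uniforms(part$missing, B, seed)
  estimates <- lapply(seq_len(B), function(b) {
    db <- impute_dataset(data, part, method, inputs[[b]], U[, b],
                         b = b, grid_width_days = grid_width_days,
                         covariates = covariates)
    analyze_imputed(db, covariates, b = b)
  })
  res <- rubin_pool(estimates)
  mird_log("pooled HR ", sprintf("%.4f", res$hr), ", p = ",
           sprintf("%.4g", res$p_value))
  res
}

#' Serialize a pooled result as JSON
#'
#' @param x a `pooled_result`.
#' @param path output path; `NULL` returns the JSON string.
#' @param meta optional named list merged into the output (seed, config).
#' @return `path` (or the JSON string), invisibly.
#' @export
pooled_result_json <- function(x, path = NULL, meta = list()) {
  stopifnot(inherits(x, "pooled_result"))
  obj <- c(meta, list(
    loghr = x$loghr, se = x$se, hr = x$hr, ci95 = x$ci,
    p_value = x$p_value, df = if (is.finite(x$df)) x$df else "Inf",
    within_var = x$within_var, between_var = x$between_var, B = x$B,
    events_by_arm = as.list(x$events_by_arm),
    per_imputation = x$per_imputation))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
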