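# Conditional-survival inversion imputers. All methods share one
# principle: given a subject censored at c with covariates Z, draw
# u ~ unif(0,1) and solve S(t | Z) / S(c | Z) = u for t. Monotonicity of
# S guarantees t > c. The bootstrap imputer inverts a gridded Cox
# survival curve by linear interpolation; the parametric imputers invert
# in closed form. Vectorized kernels do the arithmetic; the exported
# per-subject functions wrap them.

#' Per-subject uniform variates for imputation
#'
#' One variate per (subject, imputation) cell, each subject's stream
#' seeded independently from the master seed and the subject id, so
#' adding or removing a subject never perturbs the draws of the others,
#' and different imputation methods run with the same seed consume
#' identical uniforms (method comparisons are then not confounded by
#' Monte-Carlo noise). Values are strictly inside (0, 1).
#'
#' @param ids subject identifiers (character/integer vector, length `k`).
#' @param B number of imputations.
#' @param seed master integer seed.
#' @return `k x B` numeric matrix with `ids` as row names.
#' @export
draw_uniforms <- function(ids, B, seed) {
  stopifnot(B >= 1)
  out <- matrix(NA_real_, nrow = length(ids), ncol = B,
                dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    set.seed(substream_seed(seed, paste0("u:", ids[i])))
    out[i, ] <- stats::runif(B)
  }
  out
}

# Named covariate vector (trt + baseline covariates) for one subject row.
.subject_Z <- function(subject, covariates) {
  z <- c(trt = subject$trt)
  for (cv in covariates) z[cv] <- subject[[cv]]
  z
}

.check_u <- function(u) {
  if (any(!is.finite(u) | u <= 0 | u >= 1)) {
    stop("uniform variate must lie strictly in (0, 1)", call. = FALSE)
  }
}

# ---- vectorized kernels: raw inverted times, before horizon/death rules ----

# Piecewise exponential, Eq-(5)-style closed form on the baseline
# cumulative-hazard scale. Every level maps to exactly one piece;
# boundary levels resolve to the earlier (lower-index) piece.
.kernel_pwe <- function(lambda, tau, lp, cc, u) {
  if (!all(is.finite(lambda)) || !all(is.finite(lp))) {
    stop("non-finite piecewise-exponential parameters reached the ",
         "imputer (internal error)", call. = FALSE)
  }
  H_edges <- c(0, pwe_basecumhaz(tau, lambda, tau))
  edges <- c(0, tau)
  H_target <- pwe_basecumhaz(cc, lambda, tau) - log(u) * exp(-lp)
  p <- rowSums(outer(H_target, H_edges, ">"))
  edges[p] + (H_target - H_edges[p]) / lambda[p]
}

.kernel_weibull <- function(sigma, eta, cc, u) {
  (cc^(1 / sigma) - exp(eta / sigma) * log(u))^sigma
}

.kernel_j2r <- function(sigma, eta, eta0, cc, u) {
  inner <- exp((eta0 - eta) / sigma) * cc^(1 / sigma) -
    exp(eta0 / sigma) * log(u)
  # floored at c; a hair above so the imputed time stays strictly > c
  pmax(inner^sigma, cc * (1 + 1e-12))
}

# Grid interpolation against one Cox fit. Returns Inf when the target
# level falls below S(C) ("outside the grid"): finalization then censors
# at the horizon.
.kernel_bootstrap <- function(fit, lp, cc, C, u, width) {
  bh_t <- fit$basehaz$time
  bh_h <- c(0, fit$basehaz$hazard)
  n <- length(cc)
  out <- numeric(n)
  for (i in seq_len(n)) {
    grid <- seq(cc[i], C[i], by = width)
    m <- length(grid)
    if (grid[m] < C[i]) {
      grid <- c(grid, C[i])
      m <- m + 1L
    }
    S <- exp(-bh_h[findInterval(grid, bh_t) + 1] * exp(lp[i]))
    target <- S[1] * u[i]
    if (target < S[m]) {
      out[i] <- Inf
    } else {
      p <- max(which(S >= target))
      if (p == m || S[p] == target) {
        out[i] <- grid[p]
      } else {
        out[i] <- grid[p] + (grid[p + 1] - grid[p]) /
          (S[p + 1] - S[p]) * (target - S[p])
      }
    }
  }
  out
}

# Horizon/vital-status rules, vectorized (see finalize_outcome).
.finalize_vec <- function(t_raw, C, death_day) {
  no_death <- is.na(death_day)
  E <- ifelse(no_death, t_raw < C, t_raw <= pmin(death_day, C - 1))
  t <- ifelse(E, t_raw, ifelse(no_death, C, pmin(death_day + 1, C)))
  list(t = t, E = as.integer(E))
}

#' Finalize an imputed time against the horizon and vital status
#'
#' Converts a raw inverted time into the imputed (time, event) pair.
#' Without death information the outcome is an event iff `t_raw < C`,
#' otherwise administrative censoring at `C`. When a vital-status search
#' found a death, the imputed event stands only if the imputed event date
#' (randomization + `t_raw`) does not exceed the earlier of the death
#' date and the data-cut; otherwise the subject is censored at that
#' earlier date, expressed in days from randomization with the same "+1"
#' convention as `C` (i.e. at `min(death_day + 1, C)`).
#'
#' @param t_raw raw imputed time (days from randomization, `> c`).
#' @param subject one subject row (list/data.frame row with `T_obs`, `C`,
#'   `death_day`).
#' @return List with `t` (final time) and `E` (0/1).
#' @export
finalize_outcome <- function(t_raw, subject) {
  stopifnot(t_raw > subject$T_obs - 1e-9)
  fin <- .finalize_vec(t_raw, subject$C, subject$death_day)
  list(t = fin$t, E = fin$E)
}

#' Bootstrap (grid-interpolation) imputation for one subject
#'
#' Builds an arithmetic grid from the subject's censoring time `c` to the
#' administrative horizon `C`, evaluates the Cox conditional survival at
#' the grid points, and inverts the target level `S(c) * u` by linear
#' interpolation between the bracketing points; a target level landing
#' exactly on a grid point returns that point. A target level below
#' `S(C)` falls outside the grid and yields administrative censoring at
#' `C`.
#'
#' @param fit a `cox_rd_fit` (typically one bootstrap refit).
#' @param subject one subject row (needs `T_obs`, `C`, `trt`, covariates).
#' @param u uniform variate in (0, 1).
#' @param grid_width_days grid spacing in days (default 60).
#' @param covariates baseline covariate names used by the fit.
#' @return List with `t`, `E`, and `u` (see [finalize_outcome()]).
#' @export
impute_bootstrap <- function(fit, subject, u, grid_width_days = 60,
                             covariates = fit$covariates) {
  .check_u(u)
  if (subject$T_obs >= subject$C) {
    stop("degenerate grid: censoring time is at or beyond the ",
         "administrative horizon", call. = FALSE)
  }
  lp <- .lp(fit$beta, .subject_Z(subject, covariates))
  t_raw <- .kernel_bootstrap(fit, lp, subject$T_obs, subject$C, u,
                             grid_width_days)
  out <- finalize_outcome(t_raw, subject)
  out$u <- u
  out
}

#' Piecewise-exponential closed-form imputation for one subject
#'
#' Inverts the piecewise-exponential conditional survival at the level
#' `u* = S(c | Z) * u`. On the baseline cumulative-hazard scale the
#' target is `H* = H0(c) - log(u) exp(-Z'beta)`; the piece whose
#' cumulative-hazard range contains `H*` gives
#' `t = tau_{p-1} + (H* - H0(tau_{p-1})) / lambda_p`. Every level maps to
#' exactly one piece; boundary levels resolve to the earlier piece (a
#' set of measure zero).
#'
#' @param draw a `parameter_draw` of kind `"pwe"`.
#' @param subject one subject row.
#' @param u uniform variate in (0, 1).
#' @param covariates baseline covariate names.
#' @return List with `t`, `E`, `u`.
#' @export
impute_pwe <- function(draw, subject, u, covariates = character()) {
  stopifnot(inherits(draw, "parameter_draw"), draw$kind == "pwe")
  .check_u(u)
  lp <- .lp(draw$beta, .subject_Z(subject, covariates))
  t_raw <- .kernel_pwe(draw$lambda, draw$tau, lp, subject$T_obs, u)
  out <- finalize_outcome(t_raw, subject)
  out$u <- u
  out
}

#' Weibull closed-form imputation for one subject
#'
#' With AFT parameters `(sigma, gamma0, gamma)` and linear predictor
#' `eta = gamma0 + Z'gamma`, inverting `S(t)/S(c) = u` gives
#' `t = (c^(1/sigma) - exp(eta/sigma) * log u)^sigma`.
#'
#' @param draw a `parameter_draw` of kind `"weibull"`.
#' @param subject one subject row.
#' @param u uniform variate in (0, 1).
#' @param covariates baseline covariate names.
#' @return List with `t`, `E`, `u`.
#' @export
impute_weibull <- function(draw, subject, u, covariates = character()) {
  stopifnot(inherits(draw, "parameter_draw"), draw$kind == "weibull",
            draw$sigma > 0)
  .check_u(u)
  eta <- draw$gamma0 + .lp(draw$gamma, .subject_Z(subject, covariates))
  t_raw <- .kernel_weibull(draw$sigma, eta, subject$T_obs, u)
  out <- finalize_outcome(t_raw, subject)
  out$u <- u
  out
}

#' Jump-to-reference Weibull imputation for one subject
#'
#' MNAR comparator: after dropout an active-arm subject follows the
#' placebo-arm (reference) distribution. The inverted level is
#' `S(t | trt = 0, X) / S(c | trt = 1, X) = u`, which in closed form is
#' `t = max{ (exp((eta0 - eta)/sigma) c^(1/sigma)
#'            - exp(eta0/sigma) log u)^sigma, c }`
#' with `eta0` the linear predictor with treatment forced to the
#' reference. For a placebo subject `eta0 = eta` and the formula reduces
#' exactly to [impute_weibull()].
#'
#' @inheritParams impute_weibull
#' @export
impute_j2r <- function(draw, subject, u, covariates = character()) {
  stopifnot(inherits(draw, "parameter_draw"), draw$kind == "weibull",
            draw$sigma > 0)
  .check_u(u)
  Z <- .subject_Z(subject, covariates)
  Z0 <- Z
  Z0["trt"] <- 0
  eta <- draw$gamma0 + .lp(draw$gamma, Z)
  eta0 <- draw$gamma0 + .lp(draw$gamma, Z0)
  t_raw <- .kernel_j2r(draw$sigma, eta, eta0, subject$T_obs, u)
  out <- finalize_outcome(t_raw, subject)
  out$u <- u
  out
}

#' Impute all missing-data subjects of a dataset for one imputation
#'
#' Replaces `(T_obs, E)` of every missing-classified subject with the
#' imputed outcome from the requested method; retrieved dropouts and
#' completers are untouched. Audit columns `imputed` (flag) and `imp_b`
#' (imputation index) are added.
#'
#' @param data a `trial_dataset` (disposition already classified).
#' @param part the `disposition_partition` of `data`.
#' @param method one of `"bootstrap"`, `"pwe"`, `"weibull"`, `"j2r"`.
#' @param input the per-imputation model input: a `cox_rd_fit` for
#'   `"bootstrap"`, else a `parameter_draw` of the matching kind.
#' @param u named vector of uniforms, one per missing subject id (one
#'   column of [draw_uniforms()]).
#' @param b imputation index (recorded in `imp_b`).
#' @param grid_width_days bootstrap grid spacing.
#' @param covariates baseline covariate names.
#' @return A copy of `data` with imputed outcomes.
#' @export
impute_dataset <- function(data, part, method, input, u, b = 1L,
                           grid_width_days = 60, covariates = character()) {
  stopifnot(inherits(data, "trial_dataset"),
            inherits(part, "disposition_partition"))
  method <- match.arg(method, c("bootstrap", "pwe", "weibull", "j2r"))
  ok <- switch(method,
               bootstrap = inherits(input, "cox_rd_fit"),
               pwe = inherits(input, "parameter_draw") && input$kind == "pwe",
               inherits(input, "parameter_draw") && input$kind == "weibull")
  if (!ok) stop("method '", method, "' does not match the supplied fit/draw",
                call. = FALSE)
  s <- data$subjects
  s$imputed <- FALSE
  s$imp_b <- as.integer(b)
  if (length(part$missing)) {
    idx <- match(part$missing, s$id)
    uu <- u[as.character(part$missing)]
    if (anyNA(uu)) stop("uniform variate missing for some missing-data ",
                        "subjects", call. = FALSE)
    .check_u(uu)
    cc <- s$T_obs[idx]
    C <- s$C[idx]
    Zmat <- cbind(trt = s$trt[idx])
    for (cv in covariates) Zmat <- cbind(Zmat, s[[cv]][idx])
    colnames(Zmat) <- c("trt", covariates)
    t_raw <- switch(method,
      bootstrap = {
        if (any(cc >= C)) stop("degenerate grid: censoring at or beyond ",
                               "the horizon", call. = FALSE)
        lp <- as.vector(Zmat[, names(input$beta), drop = FALSE] %*%
                          input$beta)
        .kernel_bootstrap(input, lp, cc, C, uu, grid_width_days)
      },
      pwe = {
        lp <- as.vector(Zmat[, names(input$beta), drop = FALSE] %*%
                          input$beta)
        .kernel_pwe(input$lambda, input$tau, lp, cc, uu)
      },
      weibull = {
        eta <- input$gamma0 + as.vector(
          Zmat[, names(input$gamma), drop = FALSE] %*% input$gamma)
        .kernel_weibull(input$sigma, eta, cc, uu)
      },
      j2r = {
        eta <- input$gamma0 + as.vector(
          Zmat[, names(input$gamma), drop = FALSE] %*% input$gamma)
        Z0 <- Zmat
        Z0[, "trt"] <- 0
        eta0 <- input$gamma0 + as.vector(
          Z0[, names(input$gamma), drop = FALSE] %*% input$gamma)
        .kernel_j2r(input$sigma, eta, eta0, cc, uu)
      })
    fin <- .finalize_vec(t_raw, C, s$death_day[idx])
    s$T_obs[idx] <- fin$t
    s$E[idx] <- fin$E
    s$imputed[idx] <- TRUE
  }
  data$subjects <- s
  data
}
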