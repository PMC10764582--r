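# Imputation models fitted to the retrieved-dropout (RD) subset. The RD
# subset -- not RDs plus completers -- is the defining choice of the
# method: dropouts are assumed to behave like subjects who also went off
# treatment but stayed under observation in the same arm.

#' @importFrom survival Surv
NULL

# Model formula with the caller's frame as environment, so that model
# re-evaluation (survfit/basehaz on a coxph object) can find the data.
.rd_formula <- function(covariates, env = parent.frame()) {
  rhs <- paste(c("trt", covariates), collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(T_obs, E) ~", rhs))
  environment(f) <- env
  f
}

.check_rd <- function(rd, covariates, min_events = 1) {
  s <- rd$subjects
  nev <- sum(s$E)
  if (nev < min_events) {
    stop("degenerate RD subset: ", nev, " event(s), need >= ", min_events,
         ". The retrieved-dropout imputation basis requires observed ",
         "events; consider whether the RD definition or data-cut is right.",
         call. = FALSE)
  }
  for (cv in c("trt", covariates)) {
    if (length(unique(s[[cv]])) < 2) {
      stop("covariate '", cv, "' is constant in the RD subset", call. = FALSE)
    }
  }
  invisible(nev)
}

#' Fit a Cox model with baseline survival to the retrieved-dropout subset
#'
#' Semi-parametric imputation basis: a Cox proportional-hazards fit
#' (Efron ties) on the RD subset adjusting for treatment and baseline
#' covariates, together with the Breslow-type baseline cumulative hazard,
#' so that the conditional survival `S(t | Z)` can be evaluated at
#' arbitrary times.
#'
#' @param rd `trial_dataset` restricted to retrieved dropouts.
#' @param covariates baseline covariate column names (may be empty).
#' @return Object of class `cox_rd_fit` with elements `beta` (named
#'   coefficient vector), `beta_se` (model standard errors), `basehaz`
#'   (data.frame `time`, `hazard`: baseline cumulative hazard at
#'   uncentered covariates), `covariates`, `n`, `n_events`, `max_time`.
#' @export
fit_cox_rd <- function(rd, covariates = character()) {
  stopifnot(inherits(rd, "trial_dataset"))
  .check_rd(rd, covariates)
  # small bootstrap resamples can separate; the monotone survival
  # evaluator is still valid, so don't surface coxph's warning each time
  fit <- suppressWarnings(
    survival::coxph(.rd_formula(covariates), data = rd$subjects,
                    ties = "efron", x = FALSE, y = TRUE))
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit on RD subset did not converge (NA coefficients)",
         call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(beta = stats::coef(fit),
                 beta_se = sqrt(diag(as.matrix(stats::vcov(fit)))),
                 basehaz = data.frame(time = bh$time, hazard = bh$hazard),
                 covariates = covariates,
                 n = nrow(rd$subjects),
                 n_events = sum(rd$subjects$E),
                 max_time = max(rd$subjects$T_obs)),
            class = "cox_rd_fit")
}

#' @export
print.cox_rd_fit <- function(x, ...) {
  cat(sprintf("Cox RD fit: n = %d, events = %d\n", x$n, x$n_events))
  print(x$beta)
  invisible(x)
}

# Linear predictor for one subject: named Z matched against beta names.
.lp <- function(beta, Z) {
  if (!length(beta)) return(0)
  z <- Z[names(beta)]
  if (anyNA(z)) stop("covariate values missing for: ",
                     paste(names(beta)[is.na(z)], collapse = ", "),
                     call. = FALSE)
  sum(beta * z)
}

#' Conditional survival from a Cox RD fit
#'
#' Evaluates `S(t | Z) = exp(-H0(t) * exp(Z'beta))` on a time grid using
#' the stored step-function baseline cumulative hazard. `S(0) = 1`; beyond
#' the last observed RD time the last value is carried forward (imputed
#' times landing there are administratively censored downstream anyway).
#'
#' @param fit a `cox_rd_fit`.
#' @param Z named covariate vector (must cover `trt` and the fit's
#'   covariates).
#' @param times ascending non-negative time grid.
#' @return Vector of survival probabilities, non-increasing in `times`.
#' @export
predict_conditional_survival <- function(fit, Z, times) {
  stopifnot(inherits(fit, "cox_rd_fit"), all(times >= 0),
            !is.unsorted(times))
  if (length(times) && max(times) > fit$max_time) {
    mird_log("survival requested beyond last RD time ", format(fit$max_time),
             "; carrying last value forward")
  }
  h0 <- c(0, fit$basehaz$hazard)[findInterval(times, fit$basehaz$time) + 1]
  exp(-h0 * exp(.lp(fit$beta, Z)))
}

#' Bootstrap refits of the Cox RD model
#'
#' Draws `B` with-replacement resamples of the RD subset (equal size) and
#' refits the Cox model on each, giving `B` baseline-survival-plus-
#' coefficient sets for non-parametric proper imputation. A resample with
#' zero events is redrawn (at most 25 retries per slot, then an error).
#'
#' @param rd `trial_dataset` of retrieved dropouts.
#' @param B number of bootstrap fits.
#' @param seed integer seed; the fit sequence is reproducible from it.
#' @param covariates baseline covariate names.
#' @param resample set `FALSE` to refit on the original data `B` times
#'   (testing hook: then every fit equals [fit_cox_rd()]).
#' @return List of `B` `cox_rd_fit` objects.
#' @export
bootstrap_refits <- function(rd, B, seed, covariates = character(),
                             resample = TRUE) {
  stopifnot(B >= 1)
  set.seed(substream_seed(seed, "bootstrap"))
  n <- nrow(rd$subjects)
  lapply(seq_len(B), function(b) {
    if (!resample) return(fit_cox_rd(rd, covariates))
    for (try in 1:25) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- rd
      boot$subjects <- rd$subjects[idx, , drop = FALSE]
      boot$subjects$id <- seq_len(n)  # resampled rows are distinct units
      if (sum(boot$subjects$E) >= 1 &&
          all(vapply(c("trt", covariates),
                     function(cv) length(unique(boot$subjects[[cv]])) > 1,
                     logical(1)))) {
        if (try > 1) mird_log("bootstrap resample ", b, " redrawn ",
                              try - 1, " time(s)")
        return(fit_cox_rd(boot, covariates))
      }
    }
    stop("bootstrap resample ", b, " degenerate after 25 retries",
         call. = FALSE)
  })
}

# ---- piecewise exponential -------------------------------------------------

#' Resolve piecewise-exponential cut points
#'
#' `"quartiles"` places the interior cut points at the 25/50/75% quantiles
#' of the observed \emph{event} times in the RD subset (4 hazard pieces),
#' which guarantees every interval contains events whenever at least 4
#' events are available; with fewer events the number of pieces shrinks to
#' the event count. An explicit numeric vector of interior cuts is used
#' as given.
#'
#' @param rd `trial_dataset` of retrieved dropouts.
#' @param cutpoints `"quartiles"` or a strictly increasing positive
#'   numeric vector of interior cut points.
#' @return Numeric vector of interior cut points (possibly empty: a single
#'   exponential piece).
#' @export
resolve_cutpoints <- function(rd, cutpoints = "quartiles") {
  if (is.numeric(cutpoints)) {
    if (length(cutpoints) && (any(cutpoints <= 0) || is.unsorted(cutpoints, strictly = TRUE))) {
      stop("explicit cut points must be positive and strictly increasing",
           call. = FALSE)
    }
    return(as.numeric(cutpoints))
  }
  if (!identical(cutpoints, "quartiles")) {
    stop("cutpoints must be \"quartiles\" or a numeric vector", call. = FALSE)
  }
  ev <- rd$subjects$T_obs[rd$subjects$E == 1]
  if (length(ev) < 1) stop("no events in RD subset", call. = FALSE)
  m <- min(4L, length(ev))
  if (m == 1L) return(numeric(0))
  cuts <- unique(as.numeric(stats::quantile(ev, probs = seq_len(m - 1) / m)))
  cuts[cuts > 0]
}

#' Fit a piecewise-exponential proportional-hazards model
#'
#' Baseline hazard constant on intervals `[tau_{u-1}, tau_u)` (with
#' `tau_0 = 0`, last interval open-ended), proportional covariate effects.
#' Fitting uses the exact Poisson-likelihood equivalence: episodes split
#' at the cuts, one rate parameter per interval on the log scale, giving
#' the MLE and the \emph{full} observed-information covariance of
#' `(log lambda, beta)` -- including the baseline pieces, not just the
#' regression coefficients.
#'
#' @param rd `trial_dataset` of retrieved dropouts.
#' @param cutpoints see [resolve_cutpoints()].
#' @param covariates baseline covariate names.
#' @return Object of class `pwe_fit`: `lambda` (per-day hazards, length
#'   `M`), `tau` (interior cuts, length `M - 1`), `beta`, `cov`
#'   (covariance of `(log lambda, beta)`), `covariates`, `n`, `n_events`,
#'   `loglik`.
#' @export
fit_pwe <- function(rd, cutpoints = "quartiles", covariates = character()) {
  stopifnot(inherits(rd, "trial_dataset"))
  .check_rd(rd, covariates)
  tau <- resolve_cutpoints(rd, cutpoints)
  M <- length(tau) + 1L
  dat <- rd$subjects[, c("id", "T_obs", "E", "trt", covariates), drop = FALSE]
  if (length(tau)) {
    dat <- survival::survSplit(Surv(T_obs, E) ~ ., data = dat,
                               cut = tau, episode = "interval",
                               start = "tstart")
  } else {
    dat$tstart <- 0
    dat$interval <- 1L
  }
  dat$exposure <- dat$T_obs - dat$tstart
  dat <- dat[dat$exposure > 0, , drop = FALSE]
  ev_per <- tapply(dat$E, factor(dat$interval, levels = seq_len(M)), sum)
  ev_per[is.na(ev_per)] <- 0
  if (any(ev_per == 0)) {
    stop("piecewise interval(s) ", paste(which(ev_per == 0), collapse = ", "),
         " contain no events; choose wider cut points", call. = FALSE)
  }
  # interval indicators by hand (a one-level factor would break the
  # formula machinery when M = 1)
  for (m in seq_len(M)) dat[[paste0(".I", m)]] <- as.integer(dat$interval == m)
  rhs <- paste(c("0", paste0(".I", seq_len(M)), "trt", covariates),
               collapse = " + ")
  glm_fit <- stats::glm(
    stats::as.formula(paste("E ~", rhs)),
    family = stats::poisson(), data = dat,
    offset = log(dat$exposure))
  cf <- stats::coef(glm_fit)
  if (anyNA(cf)) stop("piecewise-exponential fit did not converge",
                      call. = FALSE)
  idx_l <- seq_len(M)
  lambda <- exp(unname(cf[idx_l]))
  beta <- cf[-idx_l]
  names(beta) <- c("trt", covariates)
  V <- stats::vcov(glm_fit)
  pname <- c(paste0("log_lambda", seq_len(M)), names(beta))
  dimnames(V) <- list(pname, pname)
  if (max(diag(V)) > 1e4) {
    stop("piecewise-exponential fit is not identified (degenerate ",
         "covariance); too few RD events for this cut-point layout",
         call. = FALSE)
  }
  structure(list(lambda = lambda, tau = tau, beta = beta, cov = V,
                 covariates = covariates, n = nrow(rd$subjects),
                 n_events = sum(rd$subjects$E),
                 loglik = as.numeric(stats::logLik(glm_fit))),
            class = "pwe_fit")
}

#' @export
print.pwe_fit <- function(x, ...) {
  cat(sprintf("Piecewise-exponential fit: %d piece(s), n = %d, events = %d\n",
              length(x$lambda), x$n, x$n_events))
  cat("  cuts:", if (length(x$tau)) paste(signif(x$tau, 4), collapse = ", ")
      else "(none)", "\n")
  cat("  lambda:", paste(signif(x$lambda, 4), collapse = ", "), "\n")
  print(x$beta)
  invisible(x)
}

# Baseline cumulative hazard of a piecewise-exponential model at times t.
pwe_basecumhaz <- function(t, lambda, tau) {
  edges <- c(0, tau)
  M <- length(lambda)
  vapply(t, function(ti) {
    width <- pmax(0, pmin(ti, c(tau, Inf)) - edges)
    sum(lambda * width)
  }, numeric(1))
}

#' Piecewise-exponential conditional survival
#'
#' `S(t | Z) = exp(-H0(t) exp(Z'beta))` with the piecewise-constant
#' baseline hazard; used by the imputer and exposed for checking.
#'
#' @param t times (vector).
#' @param lambda hazard pieces.
#' @param tau interior cut points (length `length(lambda) - 1`).
#' @param lp linear predictor `Z'beta` (scalar).
#' @return Survival probabilities.
#' @export
pwe_survival <- function(t, lambda, tau, lp = 0) {
  exp(-pwe_basecumhaz(t, lambda, tau) * exp(lp))
}

# ---- Weibull AFT ------------------------------------------------------------

#' Fit a Weibull accelerated failure time model
#'
#' `log T = gamma0 + Z'gamma + sigma * eps`, Gumbel errors; equivalently a
#' Weibull proportional-hazards model with shape `1/sigma` and PH
#' coefficients `beta = -gamma/sigma`. Fitted by maximum likelihood
#' ([survival::survreg()]) with the full covariance of
#' `(gamma0, gamma, log sigma)`.
#'
#' @param rd `trial_dataset` of retrieved dropouts.
#' @param covariates baseline covariate names.
#' @return Object of class `weibull_aft_fit`: `gamma0`, `gamma` (named,
#'   `trt` first), `sigma`, `cov` (order `(gamma0, gamma, log_sigma)`),
#'   `covariates`, `n`, `n_events`.
#' @export
fit_weibull_aft <- function(rd, covariates = character()) {
  stopifnot(inherits(rd, "trial_dataset"))
  .check_rd(rd, covariates, min_events = 2)
  fit <- survival::survreg(.rd_formula(covariates), data = rd$subjects,
                           dist = "weibull")
  cf <- stats::coef(fit)
  if (anyNA(cf) || !is.finite(fit$scale)) {
    stop("Weibull AFT fit did not converge", call. = FALSE)
  }
  V <- stats::vcov(fit)  # order: (Intercept), covariates, Log(scale)
  pname <- c("gamma0", names(cf)[-1], "log_sigma")
  dimnames(V) <- list(pname, pname)
  if (max(diag(V)) > 1e4) {
    stop("Weibull AFT fit is not identified (degenerate covariance); ",
         "too few RD events", call. = FALSE)
  }
  gamma <- cf[-1]
  structure(list(gamma0 = unname(cf[1]), gamma = gamma, sigma = fit$scale,
                 cov = V, covariates = covariates,
                 n = nrow(rd$subjects), n_events = sum(rd$subjects$E)),
            class = "weibull_aft_fit")
}

#' @export
print.weibull_aft_fit <- function(x, ...) {
  cat(sprintf("Weibull AFT fit: n = %d, events = %d, sigma = %.4g\n",
              x$n, x$n_events, x$sigma))
  print(c(gamma0 = x$gamma0, x$gamma))
  invisible(x)
}

#' Proportional-hazards coefficients implied by a Weibull AFT fit
#'
#' @param fit a `weibull_aft_fit` (or a parameter draw from one).
#' @return `beta = -gamma / sigma`.
#' @export
weibull_ph_coef <- function(fit) -fit$gamma / fit$sigma

#' Weibull conditional survival
#'
#' `S(t | Z) = exp(-exp(-eta/sigma) * t^(1/sigma))` with linear predictor
#' `eta = gamma0 + Z'gamma`.
#'
#' @param t times.
#' @param sigma AFT scale.
#' @param eta linear predictor (scalar).
#' @return Survival probabilities.
#' @export
weibull_survival <- function(t, sigma, eta) {
  exp(-exp(-eta / sigma) * t^(1 / sigma))
}

# ---- proper parameter draws -------------------------------------------------

#' Draw imputation parameters by MLE multivariate sampling
#'
#' Proper imputation requires a different parameter set per imputation.
#' Draws `B` vectors from `MVN(theta_hat, vcov(theta_hat))` on the fitting
#' scale -- log scale for the positivity-constrained pieces (`lambda`,
#' `sigma`), so every draw back-transforms to a valid model.
#'
#' @param fit a `pwe_fit` or `weibull_aft_fit`.
#' @param B number of draws.
#' @param seed integer seed.
#' @param partial_cov if `TRUE` (piecewise-exponential only) sample only
#'   the regression coefficients and hold the baseline hazards at their
#'   MLE, mimicking software that exposes just the coefficient block of
#'   the covariance.
#' @return List of `B` `parameter_draw` objects; each has `kind`
#'   (`"pwe"` or `"weibull"`), the back-transformed parameters, and the
#'   draw index `b`.
#' @export
draw_parameters_mle <- function(fit, B, seed, partial_cov = FALSE) {
  stopifnot(B >= 1)
  set.seed(substream_seed(seed, "mle-draws"))
  if (inherits(fit, "pwe_fit")) {
    M <- length(fit$lambda)
    mean_vec <- c(log(fit$lambda), fit$beta)
    names(mean_vec) <- rownames(fit$cov)
    V <- fit$cov
    if (partial_cov) V[seq_len(M), ] <- V[, seq_len(M)] <- 0
    draws <- .rmvnorm_psd(B, mean_vec, V)
    lapply(seq_len(B), function(b) {
      th <- draws[b, ]
      structure(list(kind = "pwe", lambda = exp(unname(th[seq_len(M)])),
                     tau = fit$tau,
                     beta = stats::setNames(th[-seq_len(M)], names(fit$beta)),
                     b = b),
                class = "parameter_draw")
    })
  } else if (inherits(fit, "weibull_aft_fit")) {
    mean_vec <- c(fit$gamma0, fit$gamma, log(fit$sigma))
    names(mean_vec) <- rownames(fit$cov)
    draws <- .rmvnorm_psd(B, mean_vec, fit$cov)
    p <- length(mean_vec)
    lapply(seq_len(B), function(b) {
      th <- draws[b, ]
      structure(list(kind = "weibull", gamma0 = unname(th[1]),
                     gamma = stats::setNames(th[seq(2, p - 1)],
                                             names(fit$gamma)),
                     sigma = exp(unname(th[p])), b = b),
                class = "parameter_draw")
    })
  } else {
    stop("draw_parameters_mle supports pwe_fit and weibull_aft_fit",
         call. = FALSE)
  }
}
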