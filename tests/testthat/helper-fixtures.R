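# Fixtures are built in code. Oracles here are written independently of
# the package internals (direct branch-by-branch formula evaluation,
# base-R simulation) so they can serve as cross-checks.

# -- hand-built datasets ------------------------------------------------------

make_trial <- function(..., D, covariates = character()) {
  trial_dataset(data.frame(...), D = D, covariates = covariates)
}

# Two-arm exponential survival data censored at a common horizon, built
# with base R only. `rate0` is the placebo per-day hazard; active hazard
# is rate0 * hr. Returns a trial_dataset with R = 0 for everyone.
sim_exp_trial <- function(n, rate0, hr, horizon_days, seed,
                          all_rd = FALSE) {
  set.seed(seed)
  trt <- rep(0:1, length.out = n)
  t_ev <- stats::rexp(n, rate = rate0 * ifelse(trt == 1, hr, 1))
  T_obs <- pmin(t_ev, horizon_days)
  E <- as.integer(t_ev <= horizon_days)
  trial_dataset(data.frame(
    id = seq_len(n), trt = trt, R = 0, T_obs = T_obs, E = E,
    trt_disc_day = if (all_rd) T_obs / 2 else NA_real_,
    study_disc_day = NA_real_, death_day = NA_real_),
    D = horizon_days - 1)  # C = D - R + 1 = horizon
}

# -- fake model objects for the imputer contracts ----------------------------

fake_pwe_draw <- function(lambda, tau = numeric(0), beta = c(trt = 0)) {
  structure(list(kind = "pwe", lambda = lambda, tau = tau, beta = beta,
                 b = 1L), class = "parameter_draw")
}

fake_weibull_draw <- function(sigma, gamma0 = 0, gamma = c(trt = 0)) {
  structure(list(kind = "weibull", sigma = sigma, gamma0 = gamma0,
                 gamma = gamma, b = 1L), class = "parameter_draw")
}

fake_subject <- function(c, C, trt = 0, death_day = NA_real_) {
  list(id = 1L, T_obs = c, C = C, trt = trt, death_day = death_day)
}

# A cox_rd_fit whose baseline survival takes prescribed values at
# prescribed times (piecewise-constant in between), no covariates.
fake_cox_fit <- function(times, surv) {
  structure(list(beta = stats::setNames(numeric(0), character(0)),
                 basehaz = data.frame(time = times, hazard = -log(surv)),
                 covariates = character(0), n = length(times),
                 n_events = length(times), max_time = max(times)),
            class = "cox_rd_fit")
}

# -- independent survival oracles --------------------------------------------

# Piecewise-exponential conditional survival, evaluated branch by branch
# (loop over pieces; deliberately not the package's vectorized form).
oracle_pwe_surv <- function(t, lambda, tau, lp = 0) {
  breaks <- c(0, tau, Inf)
  H <- 0
  for (u in seq_along(lambda)) {
    lo <- breaks[u]
    hi <- breaks[u + 1]
    if (t > lo) H <- H + lambda[u] * (min(t, hi) - lo)
  }
  exp(-H * exp(lp))
}

oracle_weibull_surv <- function(t, sigma, eta) {
  exp(-exp(-eta / sigma) * t^(1 / sigma))
}

# log survival, for conditional-probability ratios that would underflow
oracle_weibull_logsurv <- function(t, sigma, eta) {
  -exp(-eta / sigma) * t^(1 / sigma)
}

# Monte-Carlo standard error of a proportion
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
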