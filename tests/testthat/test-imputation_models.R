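rd_pool <- sim_exp_trial(n = 5000, rate0 = 0.0008, hr = exp(-0.5),
                         horizon_days = 2000, seed = 101, all_rd = TRUE)

test_that("Cox RD fit recovers a known log hazard ratio and rejects
           degenerate data", {
  fit <- fit_cox_rd(rd_pool)
  se <- 1 / sqrt(fit$n_events / 4)  # crude SE bound, events split ~1:1
  expect_lt(abs(fit$beta[["trt"]] - (-0.5)), 3 * se)

  # identical arms -> symmetry: beta approximately 0
  half <- subset_trial(rd_pool, which(rd_pool$subjects$trt == 0))
  half$subjects$trt <- rep(0:1, length.out = nrow(half$subjects))
  fit0 <- fit_cox_rd(half)
  expect_lt(abs(fit0$beta[["trt"]]), 3 / sqrt(sum(half$subjects$E) / 4))

  none <- rd_pool
  none$subjects$E <- 0
  expect_error(fit_cox_rd(none), "degenerate RD subset")
})

test_that("conditional survival evaluator is a proper survival curve", {
  fit <- fit_cox_rd(rd_pool)
  times <- c(0, sort(runif(50, 0, 2500)))
  for (z in c(0, 1)) {
    S <- predict_conditional_survival(fit, c(trt = z), times)
    expect_equal(S[1], 1)
    expect_true(all(diff(S) <= 0))
    expect_true(all(S >= 0 & S <= 1))
  }
  # exponential data, identical arms: curve close to exp(-lambda * t)
  n <- 4000
  set.seed(7)
  tev <- rexp(n, 0.001)
  tr <- make_trial(id = 1:n, trt = rep(0:1, length.out = n), R = 0,
                   T_obs = pmin(tev, 1500), E = as.integer(tev <= 1500),
                   D = 1499)
  f <- fit_cox_rd(tr)
  lam_hat <- sum(tr$subjects$E) / sum(tr$subjects$T_obs)
  tt <- c(100, 500, 1000)
  expect_equal(predict_conditional_survival(f, c(trt = 0), tt),
               exp(-lam_hat * tt), tolerance = 0.03)
})

test_that("bootstrap refits are reproducible and track the model SE", {
  rd <- sim_exp_trial(n = 500, rate0 = 0.0008, hr = 1, horizon_days = 2000,
                      seed = 33, all_rd = TRUE)
  # test hook: resampling disabled reproduces the plain fit
  f1 <- bootstrap_refits(rd, B = 1, seed = 1, resample = FALSE)[[1]]
  expect_equal(f1$beta, fit_cox_rd(rd)$beta)

  fits <- bootstrap_refits(rd, B = 200, seed = 42)
  fits2 <- bootstrap_refits(rd, B = 200, seed = 42)
  expect_identical(fits, fits2)

  bet <- vapply(fits, function(f) f$beta[["trt"]], numeric(1))
  model_se <- fit_cox_rd(rd)$beta_se[["trt"]]
  expect_lt(abs(sd(bet) - model_se) / model_se, 0.30)
})

test_that("piecewise-exponential fit matches closed forms and recovers
           truth", {
  # M = 1 with a single binary covariate is saturated: per-arm hazards
  # are exactly events / person-time (the exponential MLE)
  fit1 <- fit_pwe(rd_pool, cutpoints = numeric(0))
  s <- rd_pool$subjects
  rate_arm <- function(a) sum(s$E[s$trt == a]) / sum(s$T_obs[s$trt == a])
  expect_equal(fit1$lambda[1], rate_arm(0), tolerance = 1e-6)
  expect_equal(fit1$lambda[1] * exp(fit1$beta[["trt"]]), rate_arm(1),
               tolerance = 1e-6)

  # two-piece recovery: lambda = (1, 0.5) per day on [0,1) and [1,inf),
  # administrative cut at 3 (days), n = 5000
  set.seed(55)
  n <- 5000
  h <- -log(runif(n))                       # total hazard draw
  tev <- ifelse(h < 1, h, 1 + (h - 1) / 0.5)
  tr <- make_trial(id = 1:n, trt = rep(0:1, length.out = n), R = 0,
                   T_obs = pmin(tev, 3), E = as.integer(tev <= 3), D = 2)
  fit <- fit_pwe(tr, cutpoints = 1)
  se_log <- sqrt(diag(fit$cov))
  expect_lt(abs(log(fit$lambda[1]) - log(1)), 3 * se_log[1])
  expect_lt(abs(log(fit$lambda[2]) - log(0.5)), 3 * se_log[2])
  expect_lt(abs(fit$beta[["trt"]]), 3 * se_log[3])
  expect_true(isSymmetric(fit$cov, tol = 1e-10))
  expect_true(all(eigen(fit$cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))

  # an interval with no events is refused by name
  gap <- make_trial(id = 1:8, trt = rep(0:1, 4), R = 0,
                    T_obs = c(0.5, 0.6, 2.5, 2.6, 3, 3, 3, 3),
                    E = c(1, 1, 1, 1, 0, 0, 0, 0), D = 2)
  expect_error(fit_pwe(gap, cutpoints = c(1, 2)), "interval\\(s\\) 2")
})

test_that("quartile cut points come from RD event times", {
  cuts <- resolve_cutpoints(rd_pool, "quartiles")
  ev <- rd_pool$subjects$T_obs[rd_pool$subjects$E == 1]
  expect_equal(cuts, unname(quantile(ev, c(0.25, 0.5, 0.75))))
  expect_error(resolve_cutpoints(rd_pool, c(5, 4)), "strictly increasing")
  fit <- fit_pwe(rd_pool, "quartiles")
  expect_length(fit$lambda, 4)
})

test_that("Weibull AFT fit recovers the exponential special case and is
           scale-equivariant", {
  fit <- fit_weibull_aft(rd_pool)
  se_logsig <- sqrt(fit$cov["log_sigma", "log_sigma"])
  expect_lt(abs(log(fit$sigma)), 3 * se_logsig)       # sigma ~ 1
  # AFT gamma_trt = -sigma * beta_trt; truth beta = -0.5 -> gamma = 0.5
  expect_lt(abs(fit$gamma[["trt"]] - 0.5),
            3 * sqrt(fit$cov["trt", "trt"]))
  expect_equal(weibull_ph_coef(fit), -fit$gamma / fit$sigma)

  k <- 3.7
  scaled <- rd_pool
  scaled$subjects$T_obs <- scaled$subjects$T_obs * k
  scaled$D <- (rd_pool$D + 1) * k - 1
  scaled <- derive_horizons(scaled)
  fit_k <- fit_weibull_aft(scaled)
  expect_equal(fit_k$sigma, fit$sigma, tolerance = 1e-6)
  expect_equal(fit_k$gamma0, fit$gamma0 + log(k), tolerance = 1e-6)
})

test_that("fits are invariant to subject order", {
  perm <- sample(nrow(rd_pool$subjects))
  shuf <- rd_pool
  shuf$subjects <- rd_pool$subjects[perm, ]
  expect_equal(fit_pwe(shuf)$lambda, fit_pwe(rd_pool)$lambda,
               tolerance = 1e-8)
  expect_equal(fit_weibull_aft(shuf)$gamma, fit_weibull_aft(rd_pool)$gamma,
               tolerance = 1e-8)
  expect_equal(fit_cox_rd(shuf)$beta, fit_cox_rd(rd_pool)$beta,
               tolerance = 1e-8)
})

test_that("MLE multivariate sampling is proper, positive and reproducible", {
  fit <- fit_pwe(rd_pool, "quartiles")
  d1 <- draw_parameters_mle(fit, 5, seed = 9)
  d2 <- draw_parameters_mle(fit, 5, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(vapply(d1, function(d) all(d$lambda > 0), logical(1))))

  # degenerate covariance: every draw equals the MLE
  fit0 <- fit
  fit0$cov[] <- 0
  d0 <- draw_parameters_mle(fit0, 3, seed = 1)
  for (d in d0) {
    expect_equal(d$lambda, fit$lambda)
    expect_equal(d$beta, fit$beta)
  }

  # law of large numbers on the sampling scale
  wfit <- fit_weibull_aft(rd_pool)
  dr <- draw_parameters_mle(wfit, 10000, seed = 3)
  g0 <- vapply(dr, `[[`, numeric(1), "gamma0")
  expect_lt(abs(mean(g0) - wfit$gamma0),
            3 * sqrt(wfit$cov["gamma0", "gamma0"] / 10000))
  ls <- log(vapply(dr, `[[`, numeric(1), "sigma"))
  expect_lt(abs(mean(ls) - log(wfit$sigma)),
            3 * sqrt(wfit$cov["log_sigma", "log_sigma"] / 10000))

  # partial sampling holds the baseline hazards fixed
  dp <- draw_parameters_mle(fit, 4, seed = 2, partial_cov = TRUE)
  for (d in dp) expect_equal(d$lambda, fit$lambda)
  expect_gt(sd(vapply(dp, function(d) d$beta[["trt"]], numeric(1))), 0)
})
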