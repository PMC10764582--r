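test_that("uniform draws are reproducible, open-interval, and per-subject
           stable", {
  u1 <- draw_uniforms(c("a", "b", "c"), B = 50, seed = 11)
  u2 <- draw_uniforms(c("a", "b", "c"), B = 50, seed = 11)
  expect_identical(u1, u2)
  expect_true(all(u1 > 0 & u1 < 1))
  # adding a subject does not perturb the others' draws
  u3 <- draw_uniforms(c("a", "b", "c", "d"), B = 50, seed = 11)
  expect_identical(u3[c("a", "b", "c"), ], u1)
  # law of large numbers
  big <- draw_uniforms("x", B = 1e5, seed = 2)
  expect_lt(abs(mean(big) - 0.5), 3 * sd(big) / sqrt(1e5))
})

test_that("bootstrap imputer interpolates linearly and censors outside the
           grid", {
  # survival 1.0 at t=10, 0.5 at t=55, ~0 at t=100; grid width 45 makes
  # these the grid points exactly
  fit <- fake_cox_fit(times = c(10, 55, 100), surv = c(1, 0.5, 1e-3))
  subj <- fake_subject(c = 10, C = 100)
  out <- impute_bootstrap(fit, subj, u = 0.75, grid_width_days = 45)
  expect_equal(out$t, 32.5)
  expect_equal(out$E, 1L)
  # target level exactly at a grid point returns that point
  out2 <- impute_bootstrap(fit, subj, u = 0.5, grid_width_days = 45)
  expect_equal(out2$t, 55)
  expect_equal(out2$E, 1L)
  # target level below S(C): outside the grid -> censored at the horizon
  out3 <- impute_bootstrap(fit, subj, u = 1e-4, grid_width_days = 45)
  expect_equal(out3$t, 100)
  expect_equal(out3$E, 0L)
  expect_error(impute_bootstrap(fit, fake_subject(c = 100, C = 100), 0.5),
               "degenerate grid")
})

test_that("piecewise-exponential imputer matches the worked closed forms", {
  # one piece: S(t) = exp(-0.5 t); c = 2, u = e^-1 -> t = 4
  d1 <- fake_pwe_draw(lambda = 0.5)
  out <- impute_pwe(d1, fake_subject(c = 2, C = 1e6), u = exp(-1))
  expect_equal(out$t, 4, tolerance = 1e-12)
  expect_equal(out$E, 1L)
  # two pieces: lambda = (1, 0.5), tau = 1, c = 0.5, u = e^-1; the
  # conditional level u* = S(c) u = e^-1.5 lands in the top branch -> t = 2
  d2 <- fake_pwe_draw(lambda = c(1, 0.5), tau = 1)
  out2 <- impute_pwe(d2, fake_subject(c = 0.5, C = 1e6), u = exp(-1))
  expect_equal(out2$t, 2, tolerance = 1e-12)
  # cross-check with the independent branch-by-branch survival oracle
  expect_equal(oracle_pwe_surv(out2$t, c(1, 0.5), 1) /
                 oracle_pwe_surv(0.5, c(1, 0.5), 1),
               exp(-1), tolerance = 1e-12)
})

test_that("Weibull and jump-to-reference imputers match their closed
           forms", {
  # sigma = 1, eta = 0: exponential with rate 1; c = 2, u = e^-1 -> t = 3
  dw <- fake_weibull_draw(sigma = 1, gamma0 = 0)
  out <- impute_weibull(dw, fake_subject(c = 2, C = 1e6), u = exp(-1))
  expect_equal(out$t, 3, tolerance = 1e-12)
  # sigma = 0.5: S(t) = exp(-t^2); c = 1, u = e^-3 -> t = 2
  dh <- fake_weibull_draw(sigma = 0.5, gamma0 = 0)
  out2 <- impute_weibull(dh, fake_subject(c = 1, C = 1e6), u = exp(-3))
  expect_equal(out2$t, 2, tolerance = 1e-12)

  # J2R on placebo is exactly the Weibull imputer
  dj <- fake_weibull_draw(sigma = 0.8, gamma0 = 0.3, gamma = c(trt = -0.5))
  s0 <- fake_subject(c = 2, C = 1e6, trt = 0)
  expect_identical(impute_j2r(dj, s0, 0.37), impute_weibull(dj, s0, 0.37))

  # worked active-arm case: sigma = 1, gamma0 = 0, gamma_trt = -0.5,
  # c = 2, u = e^-1 -> t = 2 exp(0.5) + 1
  dj1 <- fake_weibull_draw(sigma = 1, gamma0 = 0, gamma = c(trt = -0.5))
  s1 <- fake_subject(c = 2, C = 1e6, trt = 1)
  outj <- impute_j2r(dj1, s1, u = exp(-1))
  expect_equal(outj$t, 2 * exp(0.5) + 1, tolerance = 1e-10)
  # independent cross-check: solve S(t | trt=0)/S(c | trt=1) = u
  f <- function(t) oracle_weibull_surv(t, 1, 0) /
    oracle_weibull_surv(2, 1, -0.5) - exp(-1)
  expect_equal(uniroot(f, c(2, 100), tol = 1e-12)$root, outj$t,
               tolerance = 1e-8)

  # reference floor: inner expression below c returns (a hair above) c
  dj2 <- fake_weibull_draw(sigma = 1, gamma0 = 0, gamma = c(trt = 2))
  s2 <- fake_subject(c = 10, C = 1e6, trt = 1)
  outf <- impute_j2r(dj2, s2, u = 0.99)
  expect_equal(outf$t, 10, tolerance = 1e-9)
  expect_gt(outf$t, 10)
})

test_that("inversion identity holds for random parametric configurations", {
  set.seed(1234)
  n <- 2000
  for (i in seq_len(n)) {
    M <- sample(1:4, 1)
    lambda <- runif(M, 1e-4, 5e-3)
    tau <- if (M > 1) sort(runif(M - 1, 10, 1500)) else numeric(0)
    beta <- c(trt = rnorm(1, 0, 0.5))
    cc <- runif(1, 1, 1000)
    u <- runif(1)
    trt <- sample(0:1, 1)
    d <- fake_pwe_draw(lambda, tau, beta)
    out <- impute_pwe(d, fake_subject(c = cc, C = Inf, trt = trt), u)
    lp <- beta[["trt"]] * trt
    expect_lt(abs(oracle_pwe_surv(out$t, lambda, tau, lp) /
                    oracle_pwe_surv(cc, lambda, tau, lp) - u), 1e-8)

    sigma <- runif(1, 0.3, 3)
    g0 <- rnorm(1, 5, 1)
    dw <- fake_weibull_draw(sigma, g0, beta)
    ow <- impute_weibull(dw, fake_subject(c = cc, C = Inf, trt = trt), u)
    eta <- g0 + beta[["trt"]] * trt
    expect_lt(abs(exp(oracle_weibull_logsurv(ow$t, sigma, eta) -
                        oracle_weibull_logsurv(cc, sigma, eta)) - u), 1e-10)
    expect_gt(out$t, cc)
    expect_gt(ow$t, cc)
  }
})

test_that("imputed time is monotone non-increasing in u", {
  us <- seq(0.02, 0.98, by = 0.04)
  d <- fake_pwe_draw(c(0.002, 0.001, 0.004), tau = c(200, 800))
  tp <- vapply(us, function(u)
    impute_pwe(d, fake_subject(c = 50, C = Inf), u)$t, numeric(1))
  expect_true(all(diff(tp) <= 0))
  dw <- fake_weibull_draw(1.4, 6)
  tw <- vapply(us, function(u)
    impute_weibull(dw, fake_subject(c = 50, C = Inf), u)$t, numeric(1))
  expect_true(all(diff(tw) <= 0))
})

test_that("imputed conditional distribution matches the analytic truncated
           law", {
  # with the true model as the draw, t - c is Exp(lambda) for the
  # exponential special case; Kolmogorov-Smirnov on vectorized draws
  n <- 20000
  lam <- 0.002
  subjects <- data.frame(id = seq_len(n), trt = rep(0:1, length.out = n),
                         R = 0, T_obs = runif(n, 10, 500), E = 0,
                         trt_disc_day = NA_real_,
                         study_disc_day = runif(n, 10, 500),
                         death_day = NA_real_)
  subjects$study_disc_day <- subjects$T_obs
  tr <- trial_dataset(subjects, D = 1e7)
  part <- classify_disposition(tr)
  expect_length(part$missing, n)
  u <- draw_uniforms(subjects$id, 1, seed = 77)[, 1]
  imp <- impute_dataset(tr, part, "pwe", fake_pwe_draw(lam), u)
  gaps <- imp$subjects$T_obs - subjects$T_obs
  expect_true(all(imp$subjects$E == 1))
  ks <- suppressWarnings(ks.test(gaps, pexp, rate = lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("vital-status refinement finalizes outcomes per the day
           conventions", {
  # no death: beyond the horizon -> censored at C
  s <- fake_subject(c = 100, C = 300)
  expect_equal(finalize_outcome(310, s), list(t = 300, E = 0L))
  expect_equal(finalize_outcome(250, s), list(t = 250, E = 1L))
  # death before the imputed date -> censored at min(death + 1, C)
  sd1 <- fake_subject(c = 50, C = 200, death_day = 80)
  expect_equal(finalize_outcome(100, sd1), list(t = 81, E = 0L))
  # death after the imputed date -> the event stands
  sd2 <- fake_subject(c = 30, C = 200, death_day = 80)
  expect_equal(finalize_outcome(50, sd2), list(t = 50, E = 1L))
  # imputed date past the cut with a late death: censored at C
  sd3 <- fake_subject(c = 30, C = 200, death_day = 500)
  expect_equal(finalize_outcome(250, sd3), list(t = 200, E = 0L))
})

test_that("dataset-level imputation touches only missing subjects and is
           deterministic", {
  spec <- scenario_spec(600, rd_frac = 0.25, disc_frac = 0.25, seed = 21)
  tr <- simulate_trial(spec)
  part <- classify_disposition(tr)
  rd <- subset_trial(tr, part$retrieved_dropouts)
  fit <- fit_weibull_aft(rd)
  draw <- draw_parameters_mle(fit, 1, seed = 5)[[1]]
  u <- draw_uniforms(part$missing, 1, seed = 5)[, 1]
  imp <- impute_dataset(tr, part, "weibull", draw, u)
  keep <- !imp$subjects$imputed
  expect_equal(imp$subjects$T_obs[keep], tr$subjects$T_obs[keep])
  expect_equal(imp$subjects$E[keep], tr$subjects$E[keep])
  was_missing <- imp$subjects$id %in% part$missing
  expect_true(all(imp$subjects$imputed == was_missing))
  expect_true(all(imp$subjects$T_obs[was_missing] >
                    tr$subjects$T_obs[was_missing]))
  expect_true(all(imp$subjects$T_obs <= imp$subjects$C))
  imp2 <- impute_dataset(tr, part, "weibull", draw, u)
  expect_identical(imp, imp2)
  # method/fit mismatch is a configuration error
  expect_error(impute_dataset(tr, part, "pwe", draw, u),
               "does not match")
})
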