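# CVOT-style trial simulator and operating-characteristic grids.
#
# The stated world: two arms 1:1, events exponential at 2% per
# person-year overall, uniform 1-year enrollment, fixed 5.5-year duration
# with a common administrative data-cut, study discontinuation
# independent of events, and retrieved dropouts designated at random
# among subjects who do not discontinue the study. Under the alternative
# the active arm runs at rate x HR except its RDs, which run at the
# attenuated rate x HR* for their whole follow-up, and the active-arm
# discontinuation fraction is shifted by an additive offset.

DAYS_PER_YEAR <- 365

#' Define a simulation scenario
#'
#' Defaults are the base CVOT configuration: 2%/person-year events,
#' 1-year uniform enrollment, 5.5-year fixed duration, two-sided
#' alpha 0.05.
#'
#' @param N_total randomized subjects across both arms (1:1).
#' @param rd_frac fraction of subjects designated retrieved dropouts.
#' @param disc_frac fraction discontinuing the study by end (placebo arm
#'   reference value).
#' @param annual_event_rate events per person-year in the placebo arm.
#' @param hr active-vs-placebo hazard ratio (1 under the null).
#' @param hr_star attenuated hazard ratio applied to active-arm RDs
#'   (between `hr` and 1; defaults to `hr`).
#' @param disc_offset_active additive change to the active-arm
#'   discontinuation fraction (e.g. `-0.02`).
#' @param enroll_years uniform enrollment window length.
#' @param duration_years fixed study duration; the data-cut is
#'   `floor(duration_years * 365)` days after first randomization.
#' @param event_dist `"exponential"` or `"weibull"`.
#' @param weibull_shape Weibull shape when `event_dist = "weibull"`
#'   (calibrated so the cumulative hazard at the full study duration
#'   matches the exponential).
#' @param disc_dist `"uniform"` (over each subject's follow-up window) or
#'   `"exponential"` (rate chosen to hit `disc_frac` on average).
#' @param reps replicate count for grid runs.
#' @param alpha two-sided significance level.
#' @param B imputations per replicate.
#' @param seed scenario master seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(N_total, rd_frac, disc_frac,
                          annual_event_rate = 0.02, hr = 1, hr_star = hr,
                          disc_offset_active = 0, enroll_years = 1,
                          duration_years = 5.5,
                          event_dist = c("exponential", "weibull"),
                          weibull_shape = 1,
                          disc_dist = c("uniform", "exponential"),
                          reps = 1000, alpha = 0.05, B = 10, seed = 1) {
  event_dist <- match.arg(event_dist)
  disc_dist <- match.arg(disc_dist)
  stopifnot(N_total >= 2, rd_frac >= 0, rd_frac <= 1,
            disc_frac >= 0, disc_frac <= 1,
            hr > 0, hr_star > 0, annual_event_rate > 0,
            enroll_years > 0, duration_years > enroll_years,
            alpha > 0, alpha < 1, B >= 1, reps >= 1)
  if (rd_frac + disc_frac > 1) {
    stop("rd_frac + disc_frac must not exceed 1 (the sets are disjoint)",
         call. = FALSE)
  }
  structure(list(N_total = as.integer(N_total), rd_frac = rd_frac,
                 disc_frac = disc_frac,
                 annual_event_rate = annual_event_rate, hr = hr,
                 hr_star = hr_star, disc_offset_active = disc_offset_active,
                 enroll_years = enroll_years,
                 duration_years = duration_years, event_dist = event_dist,
                 weibull_shape = weibull_shape, disc_dist = disc_dist,
                 reps = as.integer(reps), alpha = alpha, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Event times (days) for n subjects with per-day hazard rate `daily`.
.sim_event_times <- function(n, daily, spec) {
  if (spec$event_dist == "exponential") {
    stats::rexp(n, rate = daily)
  } else {
    # Weibull with shape k, scale set so H(Dur) matches the exponential's
    k <- spec$weibull_shape
    dur <- spec$duration_years * DAYS_PER_YEAR
    scale <- dur / (daily * dur)^(1 / k)
    stats::rweibull(n, shape = k, scale = scale)
  }
}

#' Simulate one CVOT-like trial
#'
#' @param spec a `scenario_spec`.
#' @param seed integer seed for this trial (defaults to the spec seed).
#' @return A `trial_dataset` (no baseline covariates; `trt` only).
#' @export
simulate_trial <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  n1 <- spec$N_total %/% 2L          # active
  n0 <- spec$N_total - n1            # placebo
  trt <- c(rep(0L, n0), rep(1L, n1))
  N <- spec$N_total
  # each generation stage draws from its own substream with fixed
  # consumption, so scenarios sharing a replicate seed share enrollment
  # and event randomness: scenario contrasts are then paired
  set.seed(substream_seed(seed, "enroll"))
  R <- floor(stats::runif(N, 0, spec$enroll_years * DAYS_PER_YEAR))
  D <- floor(spec$duration_years * DAYS_PER_YEAR)
  C <- D - R + 1

  # study discontinuation: fixed count per arm, times independent of events
  q <- c(spec$disc_frac, max(0, min(1, spec$disc_frac +
                                         spec$disc_offset_active)))
  set.seed(substream_seed(seed, "disposition"))
  disc <- logical(N)
  for (a in 0:1) {
    arm <- which(trt == a)
    k <- round(q[a + 1] * length(arm))
    if (k > 0) disc[sample(arm, k)] <- TRUE
  }
  t_disc_all <- if (spec$disc_dist == "uniform") {
    stats::runif(N, 0, C)
  } else {
    # exponential with mean C/2, truncated to the follow-up window
    pmin(stats::rexp(N, rate = 2 / C), C * (1 - 1e-9))
  }
  t_disc <- rep(Inf, N)
  t_disc[disc] <- t_disc_all[disc]

  # retrieved dropouts: random among non-discontinuing subjects, per arm
  rd <- logical(N)
  for (a in 0:1) {
    pool <- which(trt == a & !disc)
    k <- min(length(pool), round(spec$rd_frac * sum(trt == a)))
    if (k > 0) rd[sample(pool, k)] <- TRUE
  }
  set.seed(substream_seed(seed, "events"))

  daily <- spec$annual_event_rate / DAYS_PER_YEAR
  mult <- rep(1, N)                      # hazard multiplier vs placebo
  mult[trt == 1] <- spec$hr
  mult[trt == 1 & rd] <- spec$hr_star
  shape <- if (spec$event_dist == "weibull") spec$weibull_shape else 1
  # proportional-hazards time scaling: hazard x m <=> time x m^(-1/shape)
  t_ev <- .sim_event_times(N, daily, spec) * mult^(-1 / shape)

  T_obs <- pmin(t_ev, t_disc, C)
  T_obs <- pmax(T_obs, 1e-6)
  E <- as.integer(t_ev <= pmin(t_disc, C))
  study_disc_day <- ifelse(disc & t_disc < C, t_disc, NA_real_)
  # censored dropouts carry T_obs = study_disc_day by construction
  trt_disc_day <- ifelse(rd, stats::runif(N, 0, 1) * T_obs, NA_real_)

  subjects <- data.frame(id = seq_len(N), trt = trt, R = R, T_obs = T_obs,
                         E = E, trt_disc_day = trt_disc_day,
                         study_disc_day = study_disc_day,
                         death_day = NA_real_)
  trial_dataset(subjects, D = D, validate = FALSE)
}

#' Run a scenario grid
#'
#' For every scenario and replicate, simulates one trial and analyzes it
#' with every requested method; the trial and the per-subject uniform
#' variates are shared across methods so method contrasts are not
#' confounded by Monte-Carlo noise. Replicates use replicate-indexed
#' seed substreams, so results are identical for any worker count and a
#' grid can be resumed from a checkpoint. Replicate-level failures are
#' logged and counted, not fatal.
#'
#' @param specs a `scenario_spec` or list of them.
#' @param methods subset of `c("pwe", "bootstrap", "weibull", "j2r",
#'   "cph")`.
#' @param workers parallel workers ([parallel::mclapply()]; forked, so
#'   POSIX only -- use 1 elsewhere).
#' @param checkpoint_dir directory for per-scenario replicate-level CSV
#'   checkpoints (resumed when present); `NULL` disables.
#' @param grid_width_days,cutpoints,partial_cov passed to [run_mird()].
#' @return Object of class `simulation_summary`: list with `summary`
#'   (one row per scenario x method: rejection rate, MC-SE, average
#'   log-HR bias, mean HR, completed/failed counts) and `replicates`
#'   (per-replicate records).
#' @export
run_scenario_grid <- function(specs, methods = c("pwe", "bootstrap",
                                                 "weibull"),
                              workers = 1L, checkpoint_dir = NULL,
                              grid_width_days = 60, cutpoints = "quartiles",
                              partial_cov = FALSE) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  methods <- match.arg(methods, c("pwe", "bootstrap", "weibull", "j2r",
                                  "cph"), several.ok = TRUE)
  all_reps <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    ck <- NULL
    done <- integer(0)
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      ckfile <- file.path(checkpoint_dir, sprintf("scenario%03d.csv", si))
      if (file.exists(ckfile)) {
        ck <- utils::read.csv(ckfile)
        ck <- ck[ck$method %in% methods, , drop = FALSE]
        cnt <- table(ck$rep)
        done <- as.integer(names(cnt)[cnt == length(methods)])
        ck <- ck[ck$rep %in% done, , drop = FALSE]
      }
    }
    todo <- setdiff(seq_len(spec$reps), done)
    one_rep <- function(i) {
      rep_seed <- substream_seed(spec$seed, paste0("rep", i))
      trial <- simulate_trial(spec, seed = rep_seed)
      out <- lapply(methods, function(m) {
        res <- tryCatch(
          run_mird(trial, method = m, B = spec$B, seed = rep_seed,
                   grid_width_days = grid_width_days,
                   cutpoints = cutpoints, partial_cov = partial_cov),
          error = function(e) e)
        if (inherits(res, "error")) {
          data.frame(scenario = si, rep = i, method = m, ok = FALSE,
                     loghr = NA_real_, se = NA_real_, p = NA_real_,
                     reject = NA)
        } else {
          data.frame(scenario = si, rep = i, method = m, ok = TRUE,
                     loghr = res$loghr, se = res$se, p = res$p_value,
                     reject = res$p_value < spec$alpha)
        }
      })
      do.call(rbind, out)
    }
    new <- if (length(todo)) {
      if (workers > 1L) {
        do.call(rbind, parallel::mclapply(todo, one_rep,
                                          mc.cores = workers,
                                          mc.preschedule = TRUE))
      } else {
        do.call(rbind, lapply(todo, one_rep))
      }
    } else NULL
    recs <- rbind(ck, new)
    recs <- recs[order(recs$rep, recs$method), , drop = FALSE]
    rownames(recs) <- NULL
    if (!is.null(checkpoint_dir)) utils::write.csv(recs, ckfile,
                                                   row.names = FALSE)
    all_reps[[si]] <- recs
  }
  replicates <- do.call(rbind, all_reps)
  summary <- do.call(rbind, lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    do.call(rbind, lapply(methods, function(m) {
      r <- all_reps[[si]]
      r <- r[r$method == m, , drop = FALSE]
      ok <- r[r$ok %in% TRUE, , drop = FALSE]
      n <- nrow(ok)
      p_hat <- if (n) mean(ok$reject) else NA_real_
      data.frame(scenario = si, N_total = spec$N_total,
                 rd_frac = spec$rd_frac, disc_frac = spec$disc_frac,
                 hr = spec$hr, hr_star = spec$hr_star, method = m,
                 reps_completed = n, reps_failed = nrow(r) - n,
                 reject_rate = p_hat,
                 mc_se = if (n) sqrt(p_hat * (1 - p_hat) / n) else NA_real_,
                 avg_bias = if (n) mean(ok$loghr) - log(spec$hr)
                            else NA_real_,
                 mean_hr = if (n) mean(exp(ok$loghr)) else NA_real_)
    }))
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = replicates,
                 methods = methods),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Simulation summary\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Schoenfeld approximation to log-rank power
#'
#' `power = Phi(sqrt(d/4) |log hr| - z_{1 - alpha/2})` for `d` expected
#' events under 1:1 allocation.
#'
#' @param d expected total number of events.
#' @param hr hazard ratio under the alternative.
#' @param alpha two-sided level.
#' @return Power (equals `alpha` when `hr = 1`).
#' @export
schoenfeld_power <- function(d, hr, alpha = 0.05) {
  if (hr == 1) return(alpha)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(d / 4) * abs(log(hr)) - z)
}

#' Expected event count implied by a scenario
#'
#' Integrates the event probability over the uniform enrollment window,
#' per arm, accounting for administrative censoring and uniform study
#' discontinuation (no retrieved-dropout attenuation: the reference
#' design assumes none).
#'
#' @param spec a `scenario_spec`.
#' @return Expected total events.
#' @export
expected_events <- function(spec) {
  daily <- spec$annual_event_rate / DAYS_PER_YEAR
  D <- floor(spec$duration_years * DAYS_PER_YEAR)
  enr <- spec$enroll_years * DAYS_PER_YEAR
  q <- c(spec$disc_frac, max(0, min(1, spec$disc_frac +
                                         spec$disc_offset_active)))
  arm_events <- function(rate, n_arm, q_arm) {
    p_event <- function(r) {
      cc <- D - r + 1
      full <- 1 - exp(-rate * cc)
      # uniform disc time on (0, C): P(event < disc) = 1 - (1-e^{-rC})/(rC)
      disc <- 1 - full / (rate * cc)
      (1 - q_arm) * full + q_arm * disc
    }
    n_arm * stats::integrate(function(r) p_event(r) / enr, 0, enr)$value
  }
  n1 <- spec$N_total %/% 2L
  n0 <- spec$N_total - n1
  arm_events(daily, n0, q[1]) + arm_events(daily * spec$hr, n1, q[2])
}

#' Analytic log-rank reference power for a scenario
#'
#' @param spec a `scenario_spec` with `hr != 1` (returns `alpha` at
#'   `hr = 1`).
#' @return Power from the Schoenfeld approximation at the scenario's
#'   expected event count.
#' @export
logrank_reference_power <- function(spec) {
  schoenfeld_power(expected_events(spec), spec$hr, spec$alpha)
}

#' Wide operating-characteristics table
#'
#' Reshapes a grid summary into one row per scenario with
#' `<method>_typeI` / `<method>_bias` / `<method>_mc_se` columns,
#' mirroring the usual type-I-error report layout.
#'
#' @param x a `simulation_summary`.
#' @return data.frame, one row per scenario.
#' @export
summarize_table2 <- function(x) {
  stopifnot(inherits(x, "simulation_summary"))
  s <- x$summary
  base <- unique(s[, c("scenario", "N_total", "rd_frac", "disc_frac")])
  for (m in x$methods) {
    sm <- s[s$method == m, , drop = FALSE]
    idx <- match(base$scenario, sm$scenario)
    base[[paste0(m, "_typeI")]] <- sm$reject_rate[idx]
    base[[paste0(m, "_bias")]] <- sm$avg_bias[idx]
    base[[paste0(m, "_mc_se")]] <- sm$mc_se[idx]
  }
  rownames(base) <- NULL
  base
}
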