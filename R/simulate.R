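#' Configuration of the synthetic maintenance-trial generator
#'
#' Encodes the protocol structure the generator emulates: two 1:1
#' randomized arms; a 24-week induction (12 biweekly cures in both arms,
#' with realistic per-cycle delays); alternating chemotherapy-free
#' intervals (CFI, during which only the maintenance arm keeps receiving
#' biweekly cures, thinned by adherence) and 16-week re-treatment sequences
#' (8 biweekly cures in both arms); treatment discontinuation for
#' non-progression reasons; 8-weekly time-varying covariate assessments;
#' administrative censoring. Defaults reflect the published trial structure
#' where stated (cycle counts, assessment interval, discontinuation-reason
#' mix) and field-plausible values elsewhere (CFI length distribution,
#' adherence, dose-intensity reductions); the methods vignette discusses
#' each choice.
#'
#' @param n_patients cohort size at randomization.
#' @param allocation two positive numbers, maintenance:control ratio.
#' @param induction_cycles,cycle_days induction cures and nominal spacing.
#' @param cycle_jitter_sd sd (days) of non-negative per-cycle delays.
#' @param induction_gap_shape,induction_gap_scale gamma parameters of the
#'   extra delay between the last induction cure and the first CFI day.
#' @param early_induction_stop_prob probability that induction is stopped
#'   early (toxicity or clinical decision), so the first CFI begins before
#'   the nominal 24 weeks.
#' @param early_stop_min_cycles minimum induction cures when stopping early.
#' @param dose_intensities,dose_intensity_probs per-patient dose-intensity
#'   multipliers (protocol dose reductions) and their probabilities.
#' @param dose_cv log-normal coefficient of variation of the actually
#'   received per-cure dose around the patient's intensity (weight-based
#'   dosing and per-cure adjustments make received doses continuous).
#' @param protocol_adherence per-cure probability that a scheduled
#'   induction or re-treatment cure is received (both arms).
#' @param cfi_meanlog,cfi_sdlog log-normal CFI duration parameters
#'   (median `exp(cfi_meanlog)` days).
#' @param chemo_cycles cures per re-treatment sequence.
#' @param adherence per-cure probability that a maintenance-arm CFI cure is
#'   actually received.
#' @param adherence_ps_coef confounding-by-indication knob: logit shift of
#'   adherence per baseline performance-status level (0 disables).
#' @param disc_rate daily hazard of non-progression treatment
#'   discontinuation.
#' @param disc_weights category weights for the discontinuation reason.
#' @param update_every days between covariate assessments.
#' @param weight_sd,hgb_sd,bili_sd,bp_sd random-walk step sd of the
#'   continuous covariates per assessment.
#' @param ps_progress,ps_improve per-assessment probabilities that WHO
#'   performance status worsens / improves by one level.
#' @param tox_prob per-assessment probability that the toxicity indicator
#'   switches on when cures were received since the last assessment.
#' @param lost_prob probability of early loss to follow-up.
#' @param prog_rate daily hazard of (pre-baseline) progression.
#' @param missing_prob probability of a missing required baseline covariate.
#' @param horizon administrative censoring day (since randomization).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 488, allocation = c(1, 1),
                       induction_cycles = 12, cycle_days = 14,
                       cycle_jitter_sd = 1.5,
                       induction_gap_shape = 1.5, induction_gap_scale = 3.5,
                       early_induction_stop_prob = 0.25,
                       early_stop_min_cycles = 8,
                       dose_intensities = c(1, 0.75, 0.5),
                       dose_intensity_probs = c(0.75, 0.15, 0.10),
                       dose_cv = 0.08, protocol_adherence = 0.97,
                       cfi_meanlog = log(120), cfi_sdlog = 0.5,
                       chemo_cycles = 8,
                       adherence = 0.8, adherence_ps_coef = 0,
                       disc_rate = 1 / 900,
                       disc_weights = c(investigator = 28.7, toxicity = 8.3,
                                        other = 11.3),
                       update_every = 56,
                       weight_sd = 2, hgb_sd = 0.4, bili_sd = 1, bp_sd = 5,
                       ps_progress = 0.12, ps_improve = 0.03, tox_prob = 0.07,
                       lost_prob = 0.002, prog_rate = 0.00064,
                       missing_prob = 0.027, horizon = 1825) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 2, all(allocation > 0), horizon > 0,
            adherence >= 0, adherence <= 1,
            abs(sum(dose_intensity_probs) - 1) < 1e-8)
  class(cfg) <- "sim_config"
  cfg
}

#' True generative model for survival times
#'
#' The hazard of patient `i` on day `t` is
#' `h0(t) * exp(effect * Exposure_i(t) + gamma' Z_i + gamma_tv' Z_i(t))`
#' where the exposure metric and its effect are chosen here, so that
#' estimation can be validated against known truth.
#'
#' @param h0_induction,h0_post,h0_break piecewise-constant baseline hazard:
#'   daily rate before / after day `h0_break` (the induction period has a
#'   lower death rate than established metastatic disease on study).
#' @param h0_tail,h0_tail_start reduced daily rate from day
#'   `h0_tail_start` on, giving the long-tail survivors real cohorts
#'   show; with the defaults roughly 84% of landmarked patients die
#'   before administrative censoring, with a median near 16 months.
#' @param effect one of: `list(type = "tbc", loghr = , half_life = )`
#'   (log hazard ratio per theoretical-blood-concentration unit),
#'   `list(type = "wce", w = <function of lag days>, window = )`, or
#'   `list(type = "none")`.
#' @param arm_loghr direct (non-exposure) maintenance-arm effect; non-zero
#'   values emulate confounding of the exposure effect by arm.
#' @param gamma named log hazard ratios for baseline covariates; recognized
#'   names: `age_65_74`, `age_ge75`, `sexM`, `primary_resected`,
#'   `alk_phos_gt300`.
#' @param gamma_tv named log hazard ratios for time-varying covariates;
#'   recognized names: `who_ps` (per level), `any_toxicity`.
#' @return list of class `true_model`.
#' @export
true_model <- function(h0_induction = 0.00045, h0_post = 0.0008,
                       h0_break = 182, h0_tail = 0.00055,
                       h0_tail_start = 900,
                       effect = list(type = "tbc", loghr = -0.22,
                                     half_life = 20),
                       arm_loghr = 0,
                       gamma = c(age_65_74 = 0.10, age_ge75 = 0.25,
                                 sexM = 0, primary_resected = -0.15,
                                 alk_phos_gt300 = 0.30),
                       gamma_tv = c(who_ps = 0.35, any_toxicity = 0.10)) {
  stopifnot(h0_induction > 0, h0_post > 0, h0_tail > 0,
            h0_tail_start > h0_break,
            effect$type %in% c("tbc", "wce", "none"))
  structure(list(h0_induction = h0_induction, h0_post = h0_post,
                 h0_break = h0_break, h0_tail = h0_tail,
                 h0_tail_start = h0_tail_start, effect = effect,
                 arm_loghr = arm_loghr, gamma = gamma, gamma_tv = gamma_tv),
            class = "true_model")
}

#' Generate baseline patient records
#'
#' Baseline marginals loosely follow the published cohort description
#' (about a third women, half under 65, a sixth 75 or older, 18% with
#' elevated alkaline phosphatase, tumour sites spread over four locations).
#'
#' @param config a [sim_config()].
#' @param seed optional integer; if given, seeds the RNG.
#' @return patients data frame (see [trial-data]) plus a hidden baseline
#'   `who_ps` draw in attribute `"baseline_ps"` used downstream.
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  if (n < 2) stop("need at least 2 patients")
  n_maint <- round(n * config$allocation[1] / sum(config$allocation))
  arm <- sample(rep(c("maintenance", "control"), c(n_maint, n - n_maint)))
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    age_group = sample(c("<65", "65-74", ">=75"), n, TRUE,
                       prob = c(0.52, 0.31, 0.17)),
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.35, 0.65)),
    primary_resected = stats::runif(n) < 0.55,
    alk_phos_gt300 = stats::runif(n) < 0.18,
    tumor_site = sample(c("left", "right_transverse", "unspecified_colon",
                          "rectum"), n, TRUE,
                        prob = c(0.33, 0.23, 0.23, 0.21)),
    randomization_day = 0,
    stringsAsFactors = FALSE
  )
  if (config$missing_prob > 0) {
    na_idx <- which(stats::runif(n) < config$missing_prob)
    patients$alk_phos_gt300[na_idx] <- NA
  }
  attr(patients, "baseline_ps") <-
    sample(0:2, n, TRUE, prob = c(0.54, 0.42, 0.04))
  patients
}

#' Generate one patient's dosing timeline
#'
#' Both arms receive biweekly cures during induction and re-treatment
#' sequences; during CFIs only maintenance-arm patients continue, each
#' scheduled cure kept with the adherence probability. All dosing stops at
#' treatment discontinuation. Dose times are integer days, strictly
#' increasing; units are the patient's dose-intensity multiplier.
#'
#' @param arm `"maintenance"` or `"control"`.
#' @param baseline_ps baseline WHO performance status (feeds the optional
#'   adherence confounding knob).
#' @param config a [sim_config()].
#' @return list with `times`, `doses`, `disc_time`, `disc_reason`,
#'   `induction_end`, `cfi` (data frame of CFI start/end days).
#' @export
generate_dosing <- function(arm, baseline_ps, config) {
  cd <- config$cycle_days
  jit <- function(k) cumsum(pmax(0, stats::rnorm(k, 0, config$cycle_jitter_sd)))
  intensity <- sample(config$dose_intensities, 1,
                      prob = config$dose_intensity_probs)
  disc_time <- stats::rexp(1, config$disc_rate)
  disc_reason <- sample(names(config$disc_weights), 1,
                        prob = config$disc_weights)
  adh <- stats::plogis(stats::qlogis(config$adherence) -
                         config$adherence_ps_coef * baseline_ps)

  keep_protocol <- function(t) t[stats::runif(length(t)) < config$protocol_adherence]
  n_cycles <- if (stats::runif(1) < config$early_induction_stop_prob)
    sample(seq(config$early_stop_min_cycles, config$induction_cycles), 1)
  else config$induction_cycles
  times <- keep_protocol((seq_len(n_cycles) - 1L) * cd + jit(n_cycles))
  induction_end <- n_cycles * cd +
    stats::rgamma(1, config$induction_gap_shape,
                  scale = config$induction_gap_scale)
  cfi <- data.frame(start = numeric(), end = numeric())
  s <- induction_end
  while (s < config$horizon) {
    L <- stats::rlnorm(1, config$cfi_meanlog, config$cfi_sdlog)
    cfi <- rbind(cfi, data.frame(start = s, end = min(s + L, config$horizon)))
    if (arm == "maintenance") {
      e1 <- min(s + L, config$horizon) - 1
      sched <- if (e1 >= s) seq(s, e1, by = cd) else numeric()
      sched <- sched + jit(length(sched))
      sched <- sched[sched < s + L & stats::runif(length(sched)) < adh]
      times <- c(times, sched)
    }
    s <- s + L
    if (s >= config$horizon) break
    chemo_len <- config$chemo_cycles * cd
    sched <- s + (seq_len(config$chemo_cycles) - 1L) * cd +
      jit(config$chemo_cycles)
    times <- c(times, keep_protocol(sched[sched < min(s + chemo_len,
                                                      config$horizon)]))
    s <- s + chemo_len
  }
  times <- sort(round(times))
  times <- times[times < disc_time & times < config$horizon]
  times <- unique(times)
  doses <- intensity * exp(stats::rnorm(length(times), 0, config$dose_cv))
  during_cfi <- vapply(times, function(t)
    any(t >= cfi$start & t < cfi$end), logical(1))
  list(times = times, doses = doses, during_cfi = during_cfi,
       disc_time = disc_time, disc_reason = disc_reason,
       induction_end = induction_end, cfi = cfi)
}

#' Generate one patient's time-varying covariate path
#'
#' Assessments every `update_every` days: continuous covariates follow
#' bounded Gaussian random walks, WHO performance status a worsening-biased
#' Markov chain on \{0, 1, 2\}, and the toxicity indicator can switch on
#' (and stays on) after cures were received since the previous assessment.
#'
#' @param baseline_ps baseline WHO performance status.
#' @param dose_times the patient's dose days.
#' @param config a [sim_config()].
#' @return covariate-update data frame rows (without `patient_id`).
#' @export
generate_covariate_paths <- function(baseline_ps, dose_times, config) {
  days <- seq(0, config$horizon, by = config$update_every)
  m <- length(days)
  walk <- function(x0, sd_, lo, hi) {
    x <- x0 + cumsum(c(0, stats::rnorm(m - 1L, 0, sd_)))
    pmin(pmax(x, lo), hi)
  }
  weight <- walk(stats::rnorm(1, 70, 12), config$weight_sd, 40, 130)
  hgb <- walk(stats::rnorm(1, 12.5, 1.5), config$hgb_sd, 7, 18)
  bili <- walk(stats::rlnorm(1, log(8), 0.4), config$bili_sd, 2, 60)
  bp <- walk(stats::rnorm(1, 130, 15), config$bp_sd, 85, 200)
  ps <- integer(m); ps[1] <- baseline_ps
  tox <- logical(m)
  for (j in seq_len(m)[-1]) {
    u <- stats::runif(1)
    ps[j] <- ps[j - 1] +
      (u < config$ps_progress & ps[j - 1] < 2) -
      (u > 1 - config$ps_improve & ps[j - 1] > 0)
    dosed <- any(dose_times >= days[j - 1] & dose_times < days[j])
    tox[j] <- tox[j - 1] || (dosed && stats::runif(1) < config$tox_prob)
  }
  data.frame(day = days, who_ps = ps, any_toxicity = tox, weight_kg = weight,
             hemoglobin = hgb, bilirubin = bili, blood_pressure = bp)
}

#' Simulate death times from the true hazard
#'
#' Inversion on a daily grid: the hazard is piecewise constant per day,
#' `h_i(t) = h0(t) exp(lp_i(t))`, with the exposure term evaluated at
#' mid-day; the event time is `inf{t : H_i(t) >= E_i}` with
#' `E_i ~ Exp(1)`, interpolated exactly within the day. Administrative
#' censoring at the horizon; independent loss to follow-up and a
#' progression-time draw complete the outcome record.
#'
#' @param patients patients data frame.
#' @param dosing list of [generate_dosing()] results, one per patient.
#' @param cov_paths list of covariate-path data frames, one per patient.
#' @param model a [true_model()].
#' @param config a [sim_config()].
#' @return list with `outcomes` data frame and `lp` (list of per-day true
#'   log relative hazards, for validation only).
#' @export
simulate_event_times <- function(patients, dosing, cov_paths, model, config) {
  if (config$horizon <= 0) stop("degenerate horizon: no follow-up")
  n <- nrow(patients)
  grid <- seq_len(config$horizon) - 1L          # day t covers (t, t+1]
  h0 <- ifelse(grid < model$h0_break, model$h0_induction,
               ifelse(grid < (model$h0_tail_start %||% Inf), model$h0_post,
                      model$h0_tail %||% model$h0_post))
  outcomes <- data.frame(patient_id = patients$patient_id,
                         end_day = NA_real_, death = NA,
                         progression_day = NA_real_)
  lp_list <- vector("list", n)
  for (i in seq_len(n)) {
    expo <- daily_exposure(dosing[[i]], grid, model$effect)
    effect_term <- switch(model$effect$type,
                          none = 0,
                          tbc = model$effect$loghr * expo,
                          wce = expo)  # w(u) is already on the log-hazard scale
    lp <- model$arm_loghr * (patients$arm[i] == "maintenance") +
      fixed_lp(patients[i, ], model$gamma) +
      tv_lp(cov_paths[[i]], grid, model$gamma_tv) + effect_term
    h <- h0 * exp(lp)
    if (any(!is.finite(h))) stop("non-finite hazard")
    H <- cumsum(h)
    E <- stats::rexp(1)
    if (E < H[length(H)]) {
      day <- which(H >= E)[1L]
      H_prev <- if (day == 1L) 0 else H[day - 1L]
      t_ev <- (day - 1L) + (E - H_prev) / h[day]
      outcomes$end_day[i] <- t_ev
      outcomes$death[i] <- TRUE
    } else {
      outcomes$end_day[i] <- config$horizon
      outcomes$death[i] <- FALSE
    }
    if (stats::runif(1) < config$lost_prob) {
      lost_t <- stats::runif(1, 1, config$horizon)
      if (lost_t < outcomes$end_day[i]) {
        outcomes$end_day[i] <- lost_t
        outcomes$death[i] <- FALSE
      }
    }
    prog <- stats::rexp(1, config$prog_rate)
    if (prog < outcomes$end_day[i]) outcomes$progression_day[i] <- prog
    lp_list[[i]] <- lp
  }
  list(outcomes = outcomes, lp = lp_list)
}

# exposure effect term per day (evaluated at mid-day t + 0.5)
daily_exposure <- function(dos, grid, effect) {
  h <- dose_history(dos$times, dos$doses)
  switch(effect$type,
         none = rep(0, length(grid)),
         tbc = tbc(h, grid + 0.5, effect$half_life),
         wce = {
           w <- numeric(length(grid))
           for (k in seq_along(h$times)) {
             lag <- grid + 0.5 - h$times[k]
             ok <- lag > 0 & lag <= effect$window
             w[ok] <- w[ok] + h$doses[k] * effect$w(lag[ok])
           }
           w
         })
}

fixed_lp <- function(p, gamma) {
  g <- function(nm) if (nm %in% names(gamma)) gamma[[nm]] else 0
  g("age_65_74") * (p$age_group == "65-74") +
    g("age_ge75") * (p$age_group == ">=75") +
    g("sexM") * (p$sex == "M") +
    g("primary_resected") * isTRUE(p$primary_resected) +
    g("alk_phos_gt300") * isTRUE(p$alk_phos_gt300)
}

tv_lp <- function(path, grid, gamma_tv) {
  g <- function(nm) if (nm %in% names(gamma_tv)) gamma_tv[[nm]] else 0
  idx <- findInterval(grid, path$day)
  idx[idx == 0] <- 1L
  g("who_ps") * path$who_ps[idx] + g("any_toxicity") * path$any_toxicity[idx]
}

#' Simulate a complete synthetic maintenance-trial cohort
#'
#' Pure function of `(config, model, seed)`: generates baseline records,
#' dosing timelines, covariate paths and outcomes, truncates treatment and
#' assessment records at each patient's end of follow-up, and keeps the
#' generative truth (true per-day log relative hazards, dosing internals)
#' segregated in a `truth` element that the estimation pipeline never sees.
#'
#' @param config a [sim_config()].
#' @param model a [true_model()].
#' @param seed integer seed.
#' @return list of class `simulated_cohort` with `patients`, `doses`,
#'   `covariates`, `outcomes`, and `truth` (list: `dosing`, `lp`, `model`,
#'   `config`, `seed`).
#' @export
simulate_trial <- function(config = sim_config(), model = true_model(),
                           seed = 1) {
  set.seed(seed)
  patients <- generate_cohort(config)
  ps0 <- attr(patients, "baseline_ps")
  n <- nrow(patients)
  dosing <- cov_paths <- vector("list", n)
  for (i in seq_len(n)) {
    dosing[[i]] <- generate_dosing(patients$arm[i], ps0[i], config)
    cov_paths[[i]] <- generate_covariate_paths(ps0[i], dosing[[i]]$times,
                                               config)
  }
  ev <- simulate_event_times(patients, dosing, cov_paths, model, config)
  out <- ev$outcomes
  doses <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- dosing[[i]]$times < out$end_day[i]
    if (!any(keep)) return(NULL)
    data.frame(patient_id = patients$patient_id[i],
               day = dosing[[i]]$times[keep],
               dose_units = dosing[[i]]$doses[keep],
               during_cfi = dosing[[i]]$during_cfi[keep])
  }))
  covariates <- do.call(rbind, lapply(seq_len(n), function(i) {
    cp <- cov_paths[[i]][cov_paths[[i]]$day < out$end_day[i], , drop = FALSE]
    cbind(patient_id = patients$patient_id[i], cp)
  }))
  rownames(doses) <- rownames(covariates) <- NULL
  structure(list(patients = patients, doses = doses, covariates = covariates,
                 outcomes = out,
                 truth = list(dosing = dosing, lp = ev$lp, model = model,
                              config = config, seed = seed)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", nrow(x$patients), " patients, ",
      sum(x$outcomes$death), " deaths, ", nrow(x$doses), " doses\n", sep = "")
  invisible(x)
}

#' True exposure trajectories and linear predictors
#'
#' Recomputes, through the same exposure code paths used by estimation
#' ([tbc()] / the weight function), each patient's true exposure metric and
#' log relative hazard on a daily grid. For validating estimates only.
#'
#' @param cohort a [simulate_trial()] result.
#' @param every thin the daily grid to every `every`-th day.
#' @return data frame: `patient_id`, `day`, `exposure`, `lp`.
#' @export
truth_report <- function(cohort, every = 7L) {
  cfg <- cohort$truth$config
  model <- cohort$truth$model
  grid <- seq_len(cfg$horizon) - 1L
  keep <- (grid %% every) == 0L
  do.call(rbind, lapply(seq_len(nrow(cohort$patients)), function(i) {
    expo <- daily_exposure(cohort$truth$dosing[[i]], grid, model$effect)
    data.frame(patient_id = cohort$patients$patient_id[i],
               day = grid[keep], exposure = expo[keep],
               lp = cohort$truth$lp[[i]][keep])
  }))
}
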