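# Shared fixtures, built in code.

# three hand-written patients exercising every field
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    arm = c("maintenance", "control", "maintenance"),
    age_group = c("<65", "65-74", ">=75"),
    sex = c("F", "M", "M"),
    primary_resected = c(TRUE, FALSE, TRUE),
    alk_phos_gt300 = c(FALSE, TRUE, FALSE),
    tumor_site = c("left", "rectum", "unspecified_colon"),
    randomization_day = 0,
    stringsAsFactors = FALSE)
  doses <- data.frame(
    patient_id = c("A", "A", "A", "C", "C"),
    day = c(0, 14, 196, 0, 210),
    dose_units = c(1, 1, 1, 0.75, 0.75))
  covariates <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    day = c(0, 232, 0, 0),
    who_ps = c(0L, 1L, 1L, 2L),
    any_toxicity = c(FALSE, TRUE, FALSE, FALSE),
    weight_kg = c(70, 68, 80, 61),
    hemoglobin = c(13, 12.1, 11.5, 12.8),
    bilirubin = c(8, 9, 10, 7),
    blood_pressure = c(130, 135, 141, 120))
  outcomes <- data.frame(
    patient_id = c("A", "B", "C"),
    end_day = c(400, 500, 300),
    death = c(TRUE, FALSE, TRUE),
    progression_day = c(NA, 250, NA))
  list(patients = patients, doses = doses, covariates = covariates,
       outcomes = outcomes)
}

# the 4-subject closed-form fixture: score equation exp(2 beta) = 2
four_subject_table <- function() {
  tab <- data.frame(patient_id = c("s1", "s2", "s3", "s4"),
                    start = 0, stop = c(1, 2.5, 2, 3),
                    event = c(TRUE, FALSE, TRUE, TRUE),
                    x = c(1, 1, 0, 0))
  class(tab) <- c("counting_process", "data.frame")
  tab
}

# explicit Breslow partial log-likelihood for single-covariate
# counting-process data (the independent oracle for the Cox solver)
partial_loglik_1cov <- function(beta, tab) {
  ll <- 0
  for (t in tab$stop[tab$event]) {
    at_risk <- tab$start < t & tab$stop >= t
    xi <- tab$x[tab$event & tab$stop == t]
    ll <- ll + beta * xi - log(sum(exp(beta * tab$x[at_risk])))
  }
  ll
}

# small fast generator settings for structural tests
quick_cfg <- function(n = 80, horizon = 900, ...) {
  sim_config(n_patients = n, horizon = horizon, ...)
}

random_history <- function(max_doses = 40, horizon = 400) {
  k <- sample(1:max_doses, 1)
  dose_history(sort(sample(0:horizon, k)), stats::runif(k, 0.5, 1.5))
}

# cohort with rich dose-timing variation (the validation design of the
# weighted-cumulative-exposure literature): random administration times,
# hazard driven by a known lag weight function on [0, window]
simulate_lagged_cohort <- function(seed, w_true, window = 120, n = 350,
                                   horizon = 400, h0 = 0.004) {
  set.seed(seed)
  hists <- lapply(seq_len(n), function(i) {
    k <- 5 + stats::rpois(1, 15)
    dose_history(sort(sample(0:(horizon - 150), k)), stats::runif(k, 0.5, 1.5))
  })
  grid <- seq_len(horizon) - 1L
  end <- ev <- numeric(n)
  for (i in seq_len(n)) {
    wsum <- numeric(horizon); h <- hists[[i]]
    for (k in seq_along(h$times)) {
      lag <- grid + 0.5 - h$times[k]
      ok <- lag > 0 & lag <= window
      wsum[ok] <- wsum[ok] + h$doses[k] * w_true(lag[ok])
    }
    haz <- h0 * exp(wsum); H <- cumsum(haz); E <- stats::rexp(1)
    if (E < H[horizon]) {
      d <- which(H >= E)[1]
      end[i] <- d - 1 + (E - c(0, H)[d]) / haz[d]; ev[i] <- 1
    } else {
      end[i] <- horizon; ev[i] <- 0
    }
  }
  pat <- data.frame(patient_id = sprintf("p%03d", seq_len(n)), arm = "control",
                    age_group = "<65", sex = "F", primary_resected = TRUE,
                    alk_phos_gt300 = FALSE, tumor_site = "left",
                    randomization_day = 0)
  out <- data.frame(patient_id = pat$patient_id, end_day = pmax(end, 0.5),
                    death = ev == 1, progression_day = NA)
  doses <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient_id = pat$patient_id[i], day = hists[[i]]$times,
               dose_units = hists[[i]]$doses)))
  lmc <- structure(list(
    patients = pat, outcomes = out, doses = doses,
    covariates = data.frame(patient_id = character(), day = numeric(),
                            who_ps = integer(), any_toxicity = logical(),
                            weight_kg = numeric(), hemoglobin = numeric(),
                            bilirubin = numeric(), blood_pressure = numeric())),
    class = "landmarked_cohort")
  list(table = build_counting_process(lmc), doses = doses)
}
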