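test_that("cohort generation is a pure function of config and seed", {
  cfg <- quick_cfg(n = 40)
  a <- simulate_trial(cfg, true_model(), seed = 5)
  b <- simulate_trial(cfg, true_model(), seed = 5)
  expect_identical(a$patients, b$patients)
  expect_identical(a$doses, b$doses)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$outcomes, b$outcomes)
  c_ <- simulate_trial(cfg, true_model(), seed = 6)
  expect_false(identical(a$outcomes, c_$outcomes))
})

test_that("arms are balanced to the allocation ratio", {
  p <- generate_cohort(sim_config(n_patients = 382), seed = 3)
  expect_equal(as.integer(table(p$arm)), c(191, 191))
  p2 <- generate_cohort(sim_config(n_patients = 101, allocation = c(2, 1)),
                        seed = 3)
  expect_equal(unname(table(p2$arm)[["maintenance"]]), 67)
})

test_that("dosing follows the protocol schedule", {
  # idealized protocol: no jitter, full adherence, seamless 8-cycle CFIs
  cfg <- sim_config(cycle_jitter_sd = 0, dose_cv = 0, adherence = 1,
                    protocol_adherence = 1, early_induction_stop_prob = 0,
                    induction_gap_shape = 1e-9, induction_gap_scale = 1e-9,
                    cfi_meanlog = log(112), cfi_sdlog = 0,
                    disc_rate = 1e-12, dose_intensity_probs = c(1, 0, 0))
  set.seed(101)
  d <- generate_dosing("maintenance", 0, cfg)
  # biweekly cures: induction at 0, 14, ..., 154, then seamless CFI/chemo
  # alternation keeps the biweekly rhythm; 26 doses in the first year
  expect_equal(d$times[1:12], seq(0, 154, by = 14))
  expect_equal(d$times[d$times < 365], seq(0, 364, by = 14))
  expect_equal(sum(d$times < 52 * 7), 26)  # 26 biweekly cures per 52 weeks
  expect_equal(unique(d$doses), 1)
  # control patients receive nothing during CFIs
  set.seed(101)
  dc <- generate_dosing("control", 0, cfg)
  in_cfi <- vapply(dc$times, function(t)
    any(t >= dc$cfi$start & t < dc$cfi$end), logical(1))
  expect_false(any(in_cfi))
  expect_false(any(dc$during_cfi))
  # zero adherence: maintenance receives only induction/chemo cures
  cfg0 <- sim_config(adherence = 0, disc_rate = 1e-12)
  set.seed(7)
  d0 <- generate_dosing("maintenance", 0, cfg0)
  expect_false(any(d0$during_cfi))
})

test_that("no doses after discontinuation and times strictly increase", {
  cfg <- quick_cfg()
  set.seed(33)
  for (i in 1:20) {
    d <- generate_dosing(sample(c("maintenance", "control"), 1),
                         sample(0:2, 1), cfg)
    expect_true(all(diff(d$times) > 0))
    expect_true(all(d$times < d$disc_time))
    expect_true(d$disc_reason %in% c("investigator", "toxicity", "other"))
  }
})

test_that("covariate paths update on the assessment grid with bounded walks", {
  cfg <- sim_config(horizon = 400)
  set.seed(12)
  cp <- generate_covariate_paths(1, c(0, 14, 28), cfg)
  expect_equal(cp$day, seq(0, 400, by = 56))
  expect_equal(cp$who_ps[1], 1)
  expect_true(all(cp$who_ps %in% 0:2))
  expect_true(all(cp$weight_kg >= 40 & cp$weight_kg <= 130))
  # toxicity, once on, stays on
  expect_true(all(diff(cp$any_toxicity) >= 0))
  # zero volatility freezes the continuous covariates
  cfg0 <- sim_config(weight_sd = 0, hgb_sd = 0, bili_sd = 0, bp_sd = 0,
                     ps_progress = 0, ps_improve = 0, horizon = 400)
  set.seed(12)
  cp0 <- generate_covariate_paths(2, numeric(), cfg0)
  expect_equal(length(unique(cp0$weight_kg)), 1L)
  expect_equal(unique(cp0$who_ps), 2)
})

test_that("null-effect event times are exponential with the baseline rate", {
  # constant hazard, no covariate or exposure effects: T ~ Exp(h0)
  n <- 2000
  h0 <- 0.002
  cfg <- sim_config(n_patients = n, horizon = 5000, lost_prob = 0,
                    prog_rate = 1e-12, missing_prob = 0)
  tm <- true_model(h0_induction = h0, h0_post = h0, h0_tail = h0,
                   effect = list(type = "none"), gamma = c(), gamma_tv = c())
  set.seed(77)
  patients <- generate_cohort(cfg)
  dosing <- replicate(n, list(times = numeric(), doses = numeric()),
                      simplify = FALSE)
  paths <- replicate(n, data.frame(day = 0, who_ps = 0, any_toxicity = FALSE,
                                   weight_kg = 70, hemoglobin = 12,
                                   bilirubin = 8, blood_pressure = 130),
                     simplify = FALSE)
  ev <- simulate_event_times(patients, dosing, paths, tm, cfg)
  t_ev <- ev$outcomes$end_day[ev$outcomes$death]
  expect_gt(length(t_ev), 1900)
  ks <- suppressWarnings(ks.test(t_ev, "pexp", h0))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_event_times(patients, dosing, paths, tm,
                                    sim_config(horizon = 0)), "horizon")
})

test_that("protective exposure lengthens maintenance-arm survival", {
  tm <- true_model(effect = list(type = "tbc", loghr = -0.6, half_life = 20))
  co <- simulate_trial(quick_cfg(n = 300, horizon = 1500), tm, seed = 9)
  med <- tapply(co$outcomes$end_day, co$patients$arm, median)
  expect_gt(med[["maintenance"]], med[["control"]])
})

test_that("truth report uses the estimation code path and stays segregated", {
  co <- simulate_trial(quick_cfg(n = 15), true_model(), seed = 19)
  tr <- truth_report(co, every = 1)
  # true concentration at day 20 equals the estimation-path decay-weighted
  # sum at the mid-day evaluation point (for a patient alive past day 40,
  # whose exported doses are not truncated before then)
  id <- co$outcomes$patient_id[co$outcomes$end_day > 40][1]
  h <- dose_histories(co$doses, "overall")[[as.character(id)]]
  sub <- tr[tr$patient_id == id, ]
  d20 <- sub$exposure[sub$day == 20]
  expect_equal(d20, tbc(h, 20.5, co$truth$model$effect$half_life))
  # analysis exports carry no truth columns
  expect_false("lp" %in% names(co$doses))
  expect_false(any(c("exposure", "lp") %in% names(co$covariates)))
  expect_setequal(names(co$outcomes),
                  c("patient_id", "end_day", "death", "progression_day"))
  # all-null model gives an identically zero linear predictor
  tm0 <- true_model(effect = list(type = "none"), arm_loghr = 0,
                    gamma = c(), gamma_tv = c())
  co0 <- simulate_trial(quick_cfg(n = 5), tm0, seed = 20)
  tr0 <- truth_report(co0)
  expect_equal(unique(tr0$lp), 0)
})
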