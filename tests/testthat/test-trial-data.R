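test_that("baseline shift excludes and re-clocks patients correctly", {
  tc <- tiny_cohort()
  # patient dying before the landmark is excluded under the right category
  tc$outcomes$end_day[1] <- 150
  lm <- shift_baseline(tc$patients, tc$doses, tc$covariates, tc$outcomes)
  expect_equal(lm$exclusions$n[lm$exclusions$category == "died before baseline"], 1)
  expect_false("A" %in% lm$patients$patient_id)
  # survivor times are shifted by the landmark
  expect_equal(lm$outcomes$end_day[lm$outcomes$patient_id == "C"], 300 - 182)
  # pre-landmark doses keep negative times and are flagged
  dC <- lm$doses[lm$doses$patient_id == "C", ]
  expect_equal(dC$day, c(-182, 28))
  expect_equal(dC$pre_landmark, c(TRUE, FALSE))
  expect_error(shift_baseline(tc$patients, tc$doses, tc$covariates,
                              tc$outcomes, landmark_days = 0), "landmark")
  bad <- tc$outcomes; bad$end_day[2] <- -1
  expect_error(shift_baseline(tc$patients, tc$doses, tc$covariates, bad),
               "earlier than randomization")
})

test_that("exclusion categories partition the input cohort", {
  co <- simulate_trial(quick_cfg(n = 150), true_model(), seed = 21)
  lm <- shift_baseline(co$patients, co$doses, co$covariates, co$outcomes)
  expect_equal(nrow(co$patients), nrow(lm$patients) + sum(lm$exclusions$n))
  # progression before the landmark is an exclusion reason
  expect_setequal(lm$exclusions$category,
                  c("died before baseline", "progressed before baseline",
                    "lost before baseline", "missing covariates"))
  # no analyzed patient has an event or progression before the landmark
  expect_true(all(lm$outcomes$end_day > 0))
  expect_true(all(is.na(lm$outcomes$progression_day) |
                    lm$outcomes$progression_day > 0))
})

test_that("counting-process rows partition follow-up at the cut points", {
  pat <- data.frame(patient_id = c("A", "B"), arm = "control",
                    age_group = "<65", sex = "F", primary_resected = TRUE,
                    alk_phos_gt300 = FALSE, tumor_site = "left",
                    randomization_day = 0)
  out <- data.frame(patient_id = c("A", "B"), end_day = c(100, 40),
                    death = c(TRUE, TRUE), progression_day = NA)
  cov <- data.frame(patient_id = "A", day = c(0, 50), who_ps = c(0L, 1L),
                    any_toxicity = FALSE, weight_kg = 70, hemoglobin = 12,
                    bilirubin = 8, blood_pressure = 130)
  lm <- list(patients = pat, outcomes = out, covariates = cov,
             doses = data.frame(patient_id = character(), day = numeric(),
                                dose_units = numeric()))
  class(lm) <- "landmarked_cohort"
  tab <- build_counting_process(lm, cut_policy = "event_times")
  a <- tab[tab$patient_id == "A", ]
  expect_equal(a$start, c(0, 40))
  expect_equal(a$stop, c(40, 100))
  expect_equal(a$event, c(FALSE, TRUE))
  # union policy adds the covariate-change cut, with LOCF from the change on
  tab <- build_counting_process(lm, cut_policy = "union_of_change_times")
  a <- tab[tab$patient_id == "A", ]
  expect_equal(a$start, c(0, 40, 50))
  expect_equal(a$who_ps, c(0L, 0L, 1L))
})

test_that("counting-process invariants hold on a simulated cohort", {
  co <- simulate_trial(quick_cfg(), true_model(), seed = 8)
  lm <- shift_baseline(co$patients, co$doses, co$covariates, co$outcomes)
  tab <- build_counting_process(lm)
  expect_true(all(tab$start < tab$stop))
  expect_true(all(tab$start >= 0))
  by_pat <- split(tab, tab$patient_id)
  ends <- lm$outcomes$end_day[match(names(by_pat), lm$outcomes$patient_id)]
  died <- lm$outcomes$death[match(names(by_pat), lm$outcomes$patient_id)]
  for (i in seq_along(by_pat)) {
    p <- by_pat[[i]]
    o <- order(p$start)
    # contiguous disjoint intervals covering (0, end]
    expect_equal(p$start[o][1], 0)
    expect_equal(p$stop[o][length(o)], ends[i])
    expect_equal(p$start[o][-1], p$stop[o][-length(o)])
    # one event row at most, and only the last row
    expect_equal(sum(p$event), as.integer(died[i]))
    if (died[i]) expect_true(p$event[o][length(o)])
  }
  # every cohort event time cuts every patient at risk
  ev_times <- sort(lm$outcomes$end_day[lm$outcomes$death])
  at_risk_rows <- tab[tab$patient_id == tab$patient_id[1], ]
  inner <- ev_times[ev_times < max(at_risk_rows$stop)]
  expect_true(all(inner %in% at_risk_rows$stop))
})

test_that("time-varying covariates are carried forward from the last update", {
  co <- simulate_trial(quick_cfg(n = 30), true_model(), seed = 9)
  lm <- shift_baseline(co$patients, co$doses, co$covariates, co$outcomes)
  tab <- build_counting_process(lm)
  id <- lm$patients$patient_id[1]
  cv <- lm$covariates[lm$covariates$patient_id == id, ]
  rows <- tab[tab$patient_id == id, ]
  for (j in sample(nrow(rows), min(10, nrow(rows)))) {
    last <- max(which(cv$day <= rows$start[j]))
    expect_equal(rows$who_ps[j], cv$who_ps[last])
    expect_equal(rows$weight_kg[j], cv$weight_kg[last])
  }
})

test_that("trial CSVs round-trip through read and write", {
  tc <- tiny_cohort()
  dir <- withr::local_tempdir()
  write.csv(tc$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(tc$doses, file.path(dir, "doses.csv"), row.names = FALSE)
  write.csv(tc$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  write.csv(tc$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  rd <- read_trial_csv(dir)
  expect_equal(rd$patients, tc$patients)
  expect_equal(rd$doses, tc$doses)
  expect_equal(rd$covariates, tc$covariates)
  expect_equal(rd$outcomes, tc$outcomes)
  # a missing required column is reported by name
  write.csv(tc$patients[setdiff(names(tc$patients), "arm")],
            file.path(dir, "patients.csv"), row.names = FALSE)
  expect_error(read_trial_csv(dir), "arm")
})

test_that("long-format counting tables round-trip through CSV", {
  co <- simulate_trial(quick_cfg(n = 20), true_model(), seed = 2)
  lm <- shift_baseline(co$patients, co$doses, co$covariates, co$outcomes)
  tab <- build_counting_process(lm)
  tab <- add_exposure_column(tab, lm$doses, "ce", "overall")
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(tab, path)
  back <- read_long_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
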