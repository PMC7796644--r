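#' @title Trial data model
#' @description
#' A cohort is held as four plain data frames mirroring the trial CSVs:
#' \describe{
#'   \item{patients}{`patient_id`, `arm` ("maintenance"/"control"),
#'     `age_group` ("<65", "65-74", ">=75"), `sex` ("F"/"M"),
#'     `primary_resected`, `alk_phos_gt300` (logicals), `tumor_site`
#'     ("left", "right_transverse", "unspecified_colon", "rectum"),
#'     `randomization_day`.}
#'   \item{doses}{`patient_id`, `day`, `dose_units` (1 unit = one cure).}
#'   \item{covariates}{`patient_id`, `day`, `who_ps` (0/1/2),
#'     `any_toxicity`, `weight_kg`, `hemoglobin`, `bilirubin`,
#'     `blood_pressure`; at most one row per (patient, day), values carried
#'     forward between updates.}
#'   \item{outcomes}{`patient_id`, `end_day`, `death` (logical),
#'     `progression_day` (NA if none observed).}
#' }
#' All days are relative to randomization until [shift_baseline()] re-expresses
#' them relative to the analysis landmark.
#' @name trial-data
NULL

.patient_cols <- c("patient_id", "arm", "age_group", "sex", "primary_resected",
                   "alk_phos_gt300", "tumor_site", "randomization_day")
.dose_cols <- c("patient_id", "day", "dose_units")
.cov_cols <- c("patient_id", "day", "who_ps", "any_toxicity", "weight_kg",
               "hemoglobin", "bilirubin", "blood_pressure")
.outcome_cols <- c("patient_id", "end_day", "death", "progression_day")

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Shift the analysis baseline to a post-randomization landmark
#'
#' Maintenance protocols do not differ between arms during the induction
#' sequence, so the analysis clock is restarted at the expected start of the
#' first chemotherapy-free interval (default 182 days, i.e. 6 months).
#' Patients who died, progressed, were lost to follow-up, or have missing
#' required baseline covariates before the landmark are excluded, with
#' per-category counts. All remaining times are re-expressed relative to the
#' landmark; doses received before it are retained with negative times and
#' flagged `pre_landmark` so that "overall exposure" analyses can use them
#' while "CFI exposure" analyses drop them. Covariate updates before the
#' landmark are collapsed to a single time-0 record carrying the last value.
#'
#' @param patients,doses,covariates,outcomes the four cohort data frames.
#' @param landmark_days landmark in days after randomization (> 0).
#' @return A list of class `landmarked_cohort` with elements `patients`,
#'   `doses` (extra logical column `pre_landmark`), `covariates`, `outcomes`,
#'   `exclusions` (data frame of category counts), `landmark_days`.
#' @export
shift_baseline <- function(patients, doses, covariates, outcomes,
                           landmark_days = 182) {
  if (landmark_days <= 0) stop("landmark_days must be > 0")
  check_cols(patients, .patient_cols, "patients")
  check_cols(outcomes, .outcome_cols, "outcomes")
  if (any(outcomes$end_day <= 0)) stop("outcome earlier than randomization")
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  if (anyNA(o$patient_id)) stop("patient with no outcome record")

  died  <- o$death & o$end_day <= landmark_days
  prog  <- !died & !is.na(o$progression_day) & o$progression_day <= landmark_days
  lost  <- !died & !prog & !o$death & o$end_day <= landmark_days
  req <- c("arm", "age_group", "sex", "primary_resected", "alk_phos_gt300",
           "tumor_site")
  missing_cov <- !died & !prog & !lost &
    apply(is.na(patients[req]), 1L, any)
  keep <- !(died | prog | lost | missing_cov)

  exclusions <- data.frame(
    category = c("died before baseline", "progressed before baseline",
                 "lost before baseline", "missing covariates"),
    n = c(sum(died), sum(prog), sum(lost), sum(missing_cov))
  )
  ids <- patients$patient_id[keep]

  pat <- patients[keep, , drop = FALSE]
  out <- outcomes[outcomes$patient_id %in% ids, , drop = FALSE]
  out$end_day <- out$end_day - landmark_days
  out$progression_day <- out$progression_day - landmark_days

  dos <- doses[doses$patient_id %in% ids, , drop = FALSE]
  dos$day <- dos$day - landmark_days
  dos$pre_landmark <- dos$day < 0

  cov <- covariates[covariates$patient_id %in% ids, , drop = FALSE]
  cov$day <- cov$day - landmark_days
  # collapse pre-landmark updates to the latest one, re-dated to day 0
  if (nrow(cov)) {
    cov <- cov[order(cov$patient_id, cov$day), , drop = FALSE]
    pre <- cov$day <= 0
    last_pre <- !duplicated(cov$patient_id[pre], fromLast = TRUE)
    keep_cov <- !pre
    keep_cov[which(pre)[last_pre]] <- TRUE
    cov <- cov[keep_cov, , drop = FALSE]
    cov$day[cov$day < 0] <- 0
  }
  rownames(pat) <- rownames(dos) <- rownames(cov) <- rownames(out) <- NULL
  structure(list(patients = pat, doses = dos, covariates = cov,
                 outcomes = out, exclusions = exclusions,
                 landmark_days = landmark_days),
            class = "landmarked_cohort")
}

#' @export
print.landmarked_cohort <- function(x, ...) {
  cat("<landmarked_cohort> ", nrow(x$patients), " patients analyzed, ",
      sum(x$exclusions$n), " excluded (landmark ", x$landmark_days, " d)\n",
      sep = "")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}

#' Build the counting-process (start, stop] table
#'
#' Partitions each patient's post-landmark follow-up `(0, end_day]` at the
#' cut points implied by `cut_policy` and attaches the fixed baseline
#' covariates plus last-observation-carried-forward time-varying covariates.
#' The default policy cuts at the union of all cohort event (death) times
#' and each patient's own dose and covariate-update times, so that exposure
#' metrics appended later are exact at every time the partial likelihood
#' evaluates covariates.
#'
#' @param cohort a `landmarked_cohort` from [shift_baseline()].
#' @param cut_policy `"union_of_change_times"` (default: event, dose and
#'   update times), `"event_times"`, or `"daily"`.
#' @return A data frame of class `counting_process` with columns
#'   `patient_id`, `start`, `stop`, `event`, the fixed covariates, and the
#'   time-varying covariates; one row per interval, event only on a
#'   patient's final row.
#' @export
build_counting_process <- function(cohort,
                                   cut_policy = c("union_of_change_times",
                                                  "event_times", "daily")) {
  cut_policy <- match.arg(cut_policy)
  pat <- cohort$patients; out <- cohort$outcomes
  out <- out[match(pat$patient_id, out$patient_id), ]
  end <- out$end_day; ev <- out$death
  if (any(end <= 0)) stop("landmarked follow-up must be positive")
  # tolerance below which two times are treated as one cut: must exceed the
  # tie tolerance of the survival routines (relative sqrt(machine eps)),
  # and a 10-second gap carries no clinical information anyway
  eps <- 1e-4
  event_times <- sort(unique(end[ev]))
  if (length(event_times) > 1L)
    event_times <- event_times[c(TRUE, diff(event_times) > eps)]

  cov <- cohort$covariates
  late <- cov$day >= end[match(cov$patient_id, pat$patient_id)]
  if (any(late, na.rm = TRUE)) {
    warning(sprintf("dropping %d covariate update(s) at/after follow-up end",
                    sum(late, na.rm = TRUE)))
    cov <- cov[!late, , drop = FALSE]
  }
  dose_by <- split(cohort$doses$day[cohort$doses$day > 0],
                   cohort$doses$patient_id[cohort$doses$day > 0])
  cov_by <- split(cov, cov$patient_id)

  id_l <- start_l <- stop_l <- event_l <- vector("list", nrow(pat))
  for (i in seq_len(nrow(pat))) {
    id <- pat$patient_id[i]; e <- end[i]
    cuts <- switch(cut_policy,
      event_times = event_times,
      daily = seq_len(ceiling(e) - 1L),
      union_of_change_times = c(event_times, dose_by[[as.character(id)]],
                                cov_by[[as.character(id)]]$day))
    # drop cuts that would create effectively zero-length intervals (a
    # change time can fall within numerical tolerance of an event time or
    # of the follow-up end); event-time cuts take priority so covariate
    # evaluation stays exact where the partial likelihood looks
    other <- setdiff(cuts, event_times)
    other <- other[other > eps & other < e - eps]
    if (cut_policy == "daily") {
      cuts <- sort(unique(other))
    } else {
      ev_cuts <- event_times[event_times > eps & event_times < e - eps]
      if (length(other) && length(ev_cuts)) {
        idx <- findInterval(other, ev_cuts)
        d_lo <- ifelse(idx >= 1L, other - ev_cuts[pmax(idx, 1L)], Inf)
        d_hi <- ifelse(idx < length(ev_cuts),
                       ev_cuts[pmin(idx + 1L, length(ev_cuts))] - other, Inf)
        other <- other[pmin(d_lo, d_hi) > eps]
      }
      cuts <- sort(unique(c(ev_cuts, other)))
    }
    if (length(cuts) > 1L) cuts <- cuts[c(TRUE, diff(cuts) > eps)]
    id_l[[i]] <- rep(id, length(cuts) + 1L)
    start_l[[i]] <- c(0, cuts)
    stop_l[[i]] <- c(cuts, e)
    event_l[[i]] <- c(rep(FALSE, length(cuts)), ev[i])
  }
  tab <- data.frame(patient_id = unlist(id_l), start = unlist(start_l),
                    stop = unlist(stop_l), event = unlist(event_l))
  fixed <- pat[match(tab$patient_id, pat$patient_id),
               setdiff(.patient_cols, c("patient_id", "randomization_day"))]
  tab <- cbind(tab, fixed)

  tv_cols <- setdiff(.cov_cols, c("patient_id", "day"))
  for (cn in tv_cols) tab[[cn]] <- NA
  for (id in names(cov_by)) {
    cb <- cov_by[[id]]
    cb <- cb[order(cb$day), , drop = FALSE]
    sel <- tab$patient_id == id
    idx <- findInterval(tab$start[sel], cb$day)  # update at or before start
    for (cn in tv_cols) {
      v <- rep(NA, sum(sel)); ok <- idx > 0
      v[ok] <- cb[[cn]][idx[ok]]
      tab[[cn]][sel] <- v
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("counting_process", "data.frame")
  tab
}

#' Read the four trial CSVs
#'
#' @param dir directory containing `patients.csv`, `doses.csv`,
#'   `covariates.csv`, `outcomes.csv`; alternatively pass explicit paths.
#' @param patients,doses,covariates,outcomes optional explicit file paths.
#' @return list with the four typed data frames.
#' @export
read_trial_csv <- function(dir = NULL,
                           patients = file.path(dir, "patients.csv"),
                           doses = file.path(dir, "doses.csv"),
                           covariates = file.path(dir, "covariates.csv"),
                           outcomes = file.path(dir, "outcomes.csv")) {
  rd <- function(path, cols, what) {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop(sprintf("cannot read %s: %s", what,
                                                    conditionMessage(e))))
    check_cols(df, cols, what)
    df
  }
  p <- rd(patients, .patient_cols, "patients.csv")
  for (cn in c("primary_resected", "alk_phos_gt300"))
    p[[cn]] <- as.logical(p[[cn]])
  d <- rd(doses, .dose_cols, "doses.csv")
  if ("during_cfi" %in% names(d)) d$during_cfi <- as.logical(d$during_cfi)
  if (any(!is.finite(d$dose_units)))
    stop(sprintf("unparseable dose_units at row %s",
                 paste(which(!is.finite(d$dose_units)), collapse = ",")))
  cv <- rd(covariates, .cov_cols, "covariates.csv")
  cv$any_toxicity <- as.logical(cv$any_toxicity)
  o <- rd(outcomes, .outcome_cols, "outcomes.csv")
  o$death <- as.logical(o$death)
  list(patients = p, doses = d, covariates = cv, outcomes = o)
}

#' Write / read a long-format counting-process table
#'
#' Round-trip stable: `read_long_csv(write_long_csv(tab, f))` reproduces the
#' table field-for-field.
#'
#' @param table a `counting_process` data frame.
#' @param path CSV file path.
#' @export
write_long_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_long_csv
#' @export
read_long_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(tab, c("patient_id", "start", "stop", "event"), "long.csv")
  tab$event <- as.logical(tab$event)
  for (cn in intersect(c("primary_resected", "alk_phos_gt300", "any_toxicity"),
                       names(tab)))
    tab[[cn]] <- as.logical(tab[[cn]])
  class(tab) <- c("counting_process", "data.frame")
  tab
}
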