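#' Per-patient dose histories from a dose table
#'
#' @param doses dose data frame (`patient_id`, `day`, `dose_units`,
#'   optionally `pre_landmark` after [shift_baseline()] and/or a
#'   `during_cfi` flag).
#' @param scope `"overall"` keeps all doses (pre-landmark ones carry
#'   negative times); `"cfi_only"` keeps doses received during
#'   chemotherapy-free intervals. When the data carry a `during_cfi` flag
#'   (the generator emits one) it defines the CFI scope exactly, including
#'   cures of a CFI that began before the analysis landmark; without the
#'   flag, pre-landmark doses are treated as induction and dropped.
#' @return named list of [dose_history()] objects keyed by patient id.
#' @export
dose_histories <- function(doses, scope = c("overall", "cfi_only")) {
  scope <- match.arg(scope)
  if (scope == "cfi_only") {
    keep <- if ("during_cfi" %in% names(doses)) doses$during_cfi
            else if ("pre_landmark" %in% names(doses)) !doses$pre_landmark
            else doses$day >= 0
    doses <- doses[keep, , drop = FALSE]
  }
  sp <- split(doses, doses$patient_id)
  lapply(sp, function(d) dose_history(d$day, d$dose_units))
}

history_of <- function(histories, id) {
  h <- histories[[as.character(id)]]
  if (is.null(h)) dose_history() else h
}

# Evaluate f(history, times) per patient at each row's stop time.
# Covariates enter the partial likelihood only at event times; cutting rows
# at all cohort event times makes the stop of the row covering an event the
# event time itself, so stop-evaluation is exact there.
eval_at_stops <- function(table, histories, f) {
  out <- numeric(nrow(table))
  for (id in unique(table$patient_id)) {
    sel <- table$patient_id == id
    out[sel] <- f(history_of(histories, id), table$stop[sel])
  }
  out
}

#' Append exposure columns to a counting-process table
#'
#' Adds the time-varying exposure metric(s) needed by the model suite, each
#' evaluated exactly at the times the partial likelihood reads covariates
#' (row stop times; see [build_counting_process()]). Risk-set metrics
#' (`stce`, `ceq`) are recomputed at every evaluation time over the
#' patients still under follow-up at that time.
#'
#' @param table a `counting_process` data frame.
#' @param doses dose data frame (landmarked).
#' @param kind one of `"ce"`, `"stce"`, `"ceq"`, `"tbc"`.
#' @param scope `"overall"` or `"cfi_only"` (see [dose_histories()]).
#' @param name column name for the new metric; defaults to
#'   `<kind>_<scope abbreviation>`.
#' @param half_life TBC half-life in days.
#' @param scheme quantile scheme for `ceq` (see [quantile_categories()]).
#' @return the table with the new column appended.
#' @export
add_exposure_column <- function(table, doses,
                                kind = c("ce", "stce", "ceq", "tbc"),
                                scope = c("overall", "cfi_only"),
                                name = NULL, half_life = 20,
                                scheme = c("model3a", "model3b")) {
  kind <- match.arg(kind); scope <- match.arg(scope)
  if (is.null(name))
    name <- paste0(kind, if (scope == "cfi_only") "_cfi" else "_overall")
  histories <- dose_histories(doses, scope)
  if (kind == "ce") {
    table[[name]] <- eval_at_stops(table, histories, cumulative_exposure)
  } else if (kind == "tbc") {
    table[[name]] <- eval_at_stops(table, histories,
                                   function(h, t) tbc(h, t, half_life))
  } else {
    scheme <- match.arg(scheme)
    table[[name]] <- risk_set_metric(table, histories, kind, scheme)
  }
  table
}

# risk-set standardization / categorization at each unique stop time
risk_set_metric <- function(table, histories, kind, scheme) {
  ids <- unique(table$patient_id)
  end <- tapply(table$stop, table$patient_id, max)[as.character(ids)]
  arm <- table$arm[match(ids, table$patient_id)]
  ut <- sort(unique(table$stop))
  # cumulative dose of every patient at every evaluation time
  ce <- matrix(0, length(ids), length(ut), dimnames = list(as.character(ids)))
  for (i in seq_along(ids))
    ce[i, ] <- cumulative_exposure(history_of(histories, ids[i]), ut)

  row_pat <- match(as.character(table$patient_id), as.character(ids))
  row_t <- match(table$stop, ut)
  out <- if (kind == "ceq") character(nrow(table)) else numeric(nrow(table))
  for (j in seq_along(ut)) {
    at_risk <- which(end >= ut[j])
    rows <- which(row_t == j)
    vals <- ce[at_risk, j]
    if (kind == "stce") {
      z <- if (length(at_risk) < 2L) 0 else standardize_exposure(vals)
      names(z) <- as.character(ids)[at_risk]
      out[rows] <- z[as.character(table$patient_id[rows])]
    } else {
      lab <- quantile_categories(vals, arm = arm[at_risk], scheme = scheme,
                                 time = ut[j])
      names(lab) <- as.character(ids)[at_risk]
      out[rows] <- as.character(lab[as.character(table$patient_id[rows])])
    }
  }
  if (kind == "ceq") {
    levs <- if (scheme == "model3a")
      c("control", "maintenance_zero", "T1", "T2", "T3") else paste0("Q", 1:4)
    out <- factor(out, levels = levs)
  }
  out
}

#' Append the spline artificial covariates for WCE estimation
#'
#' Adds columns `wce_d1 .. wce_dJ` (see [wce_artificial_covariates()])
#' evaluated at each row's stop time.
#'
#' @inheritParams add_exposure_column
#' @param basis a [make_spline_basis()] object.
#' @param prefix column-name prefix.
#' @return the table with `J` new columns; the names are returned in
#'   attribute `"wce_columns"`.
#' @export
add_wce_columns <- function(table, doses, basis,
                            scope = c("overall", "cfi_only"),
                            prefix = "wce_d") {
  scope <- match.arg(scope)
  histories <- dose_histories(doses, scope)
  D <- matrix(0, nrow(table), basis$J)
  for (id in unique(table$patient_id)) {
    sel <- table$patient_id == id
    D[sel, ] <- wce_artificial_covariates(history_of(histories, id), basis,
                                          table$stop[sel])
  }
  nms <- paste0(prefix, seq_len(basis$J))
  for (j in seq_len(basis$J)) table[[nms[j]]] <- D[, j]
  attr(table, "wce_columns") <- nms
  table
}
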