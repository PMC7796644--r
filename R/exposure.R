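#' Dose history for one patient
#'
#' An ordered record of drug administrations, the raw material of every
#' cumulative-exposure metric. One dose unit corresponds to one treatment
#' cure (5 mg/kg for the motivating antibody), so metrics are expressed in
#' cure units unless multiplied by the per-cure dose.
#'
#' @param times numeric vector, days since the time origin (may be negative
#'   for doses received before an analysis landmark). Must be non-decreasing;
#'   duplicated times are collapsed by summing their doses.
#' @param doses non-negative numeric vector of dose units, recycled to
#'   `length(times)` if scalar.
#' @return An object of class `dose_history`: a list with sorted `times` and
#'   `doses`.
#' @examples
#' h <- dose_history(c(0, 14, 28), 1)
#' cumulative_exposure(h, 30)
#' @export
dose_history <- function(times = numeric(), doses = numeric()) {
  if (length(doses) == 1L) doses <- rep(doses, length(times))
  stopifnot(length(times) == length(doses))
  if (any(doses < 0)) stop("doses must be non-negative")
  o <- order(times)
  times <- times[o]; doses <- doses[o]
  if (anyDuplicated(times)) {
    doses <- as.numeric(tapply(doses, times, sum))
    times <- sort(unique(times))
  }
  structure(list(times = as.numeric(times), doses = as.numeric(doses)),
            class = "dose_history")
}

#' @export
print.dose_history <- function(x, ...) {
  cat("<dose_history> ", length(x$times), " administrations, ",
      sum(x$doses), " units total\n", sep = "")
  invisible(x)
}

as_dose_history <- function(x) {
  if (inherits(x, "dose_history")) return(x)
  dose_history(x$times, x$doses)
}

#' Updated cumulative dose CE(t)
#'
#' The sum of all doses received strictly before time `t`. A dose given
#' exactly at `t` does not count at `t` itself, only at strictly later
#' times; this boundary convention removes same-instant reverse causation
#' by construction and is used by every metric in the package.
#'
#' @param history a [dose_history()].
#' @param t numeric vector of evaluation times (days).
#' @return numeric vector, cumulative dose units at each `t`.
#' @export
cumulative_exposure <- function(history, t) {
  history <- as_dose_history(history)
  if (length(history$times) == 0L) return(rep(0, length(t)))
  cs <- c(0, cumsum(history$doses))
  # findInterval with left.open counts doses with time < t (strict)
  idx <- findInterval(t, history$times, left.open = TRUE)
  cs[idx + 1L]
}

#' Theoretical blood concentration under one-compartment decay
#'
#' Exponential-decay weighted sum of past doses,
#' \deqn{TBC(t) = \sum_{t_k < t} X(t_k)\, 0.5^{(t - t_k)/h},}
#' a pharmacokinetic exposure proxy with elimination half-life `half_life`
#' (default 20 days, the value reported for bevacizumab). As
#' `half_life` grows without bound TBC converges to the cumulative dose.
#'
#' @inheritParams cumulative_exposure
#' @param half_life elimination half-life in days, > 0.
#' @return numeric vector of concentrations in dose units (multiply by the
#'   per-cure dose, e.g. 5 mg/kg, for concentration units).
#' @examples
#' h <- dose_history(0, 1)
#' tbc(h, 20, half_life = 20) # one half-life: 0.5 units
#' @export
tbc <- function(history, t, half_life = 20) {
  stopifnot(half_life > 0)
  history <- as_dose_history(history)
  if (length(history$times) == 0L) return(rep(0, length(t)))
  lag <- outer(t, history$times, `-`)           # t - t_k
  w <- 0.5^(lag / half_life)
  w[lag <= 0] <- 0
  as.numeric(w %*% history$doses)
}

#' Risk-set z-score standardization of cumulative dose
#'
#' Converts the cumulative doses of the patients at risk at one evaluation
#' time into z-scores using the risk-set mean and sample (n - 1) standard
#' deviation, removing the systematic growth of cumulative dose over
#' follow-up. A degenerate risk set (zero standard deviation) maps to
#' all-zero scores by convention.
#'
#' @param ce_at_t numeric vector of cumulative doses of the patients at risk
#'   at a common time.
#' @return numeric vector of z-scores with mean 0 and sample sd 1 whenever
#'   the input sd is positive.
#' @export
standardize_exposure <- function(ce_at_t) {
  if (length(ce_at_t) < 2L) stop("risk set must contain at least 2 patients")
  s <- stats::sd(ce_at_t)
  if (!is.finite(s) || s == 0) return(rep(0, length(ce_at_t)))
  (ce_at_t - mean(ce_at_t)) / s
}

#' Time-varying quantile categories of cumulative dose
#'
#' Categorizes the cumulative doses of the risk set at one evaluation time.
#' Two schemes are supported, mirroring the two categorical models of the
#' analysis plan:
#' \describe{
#'   \item{`model3a`}{five labels: `control` (reference), `maintenance_zero`
#'     (maintenance-arm patients with zero cumulative dose so far), and
#'     tertiles `T1`-`T3` of the non-zero cumulative doses in the risk set.}
#'   \item{`model3b`}{quartiles `Q1`(reference)-`Q4` of the non-zero
#'     cumulative doses; zero values (rare under overall exposure) are
#'     assigned to `Q1`.}
#' }
#' Cutpoints are type-7 quantiles of the non-zero values in the risk set,
#' recomputed at every evaluation time; ties go to the lower category.
#'
#' @param ce_at_t numeric vector of risk-set cumulative doses.
#' @param arm character/factor vector, `"maintenance"` or `"control"`,
#'   required for `model3a`.
#' @param scheme `"model3a"` or `"model3b"`.
#' @param time evaluation time, used only in error messages.
#' @return factor of category labels, one per risk-set member, with the
#'   reference category as first level.
#' @export
quantile_categories <- function(ce_at_t, arm = NULL, scheme = c("model3a", "model3b"),
                                time = NA) {
  scheme <- match.arg(scheme)
  p <- if (scheme == "model3a") 3L else 4L
  nz <- ce_at_t[ce_at_t > 0]
  if (length(unique(nz)) < p) {
    stop(sprintf("degenerate risk set at t=%s: %d distinct non-zero cumulative doses, need >= %d",
                 format(time), length(unique(nz)), p))
  }
  cuts <- stats::quantile(nz, probs = seq_len(p - 1L) / p, type = 7, names = FALSE)
  if (any(duplicated(cuts))) {
    stop(sprintf("degenerate risk set at t=%s: quantile cutpoints not distinct", format(time)))
  }
  # ties to the lower category: value equal to a cutpoint stays below it
  grp <- findInterval(ce_at_t, cuts, left.open = TRUE) + 1L
  if (scheme == "model3a") {
    stopifnot(!is.null(arm))
    lab <- ifelse(arm == "control", "control",
                  ifelse(ce_at_t == 0, "maintenance_zero", paste0("T", grp)))
    factor(lab, levels = c("control", "maintenance_zero", "T1", "T2", "T3"))
  } else {
    factor(paste0("Q", grp), levels = paste0("Q", 1:4))
  }
}
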