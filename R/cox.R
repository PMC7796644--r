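#' Fit a time-varying Cox model on a counting-process table
#'
#' Thin, checked wrapper around the counting-process Cox partial likelihood:
#' `Surv(start, stop, event) ~ covariates`. Maximization is delegated to
#' [survival::coxph()]; results are repackaged with the quantities the
#' model-comparison workflow needs (log partial likelihood, deviance, AIC,
#' Wald hazard-ratio table). Character covariates are coerced to factors
#' with field-conventional reference levels (control arm, youngest age
#' group, left colon).
#'
#' @param table a `counting_process` data frame (see
#'   [build_counting_process()]); exposure columns may have been appended.
#' @param covariate_names character vector of column names to enter the
#'   linear predictor.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: list with `coefficients`, `vcov`,
#'   `loglik`, `k` (number of estimated parameters), `aic`, `deviance`,
#'   `hr` (data frame: term, coef, se, HR, CI_low, CI_high, p), `ties`,
#'   `n`, `n_events`, and the underlying `coxph` fit.
#' @export
fit_cox_tv <- function(table, covariate_names, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  miss <- setdiff(covariate_names, names(table))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  dat <- as.data.frame(table)[c("start", "stop", "event", covariate_names)]
  dat <- set_reference_levels(dat)

  const <- vapply(covariate_names, function(cn) {
    v <- dat[[cn]]
    length(unique(v[!is.na(v)])) < 2L
  }, logical(1))
  if (any(const))
    stop("singular design: covariate(s) without variation: ",
         paste(covariate_names[const], collapse = ", "))

  f <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~",
    paste(sprintf("`%s`", covariate_names), collapse = " + ")))
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, ties = ties, x = FALSE, y = TRUE,
                    model = FALSE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("singular design: coefficient(s) not estimable: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  monotone <- any(grepl("infinite|Infinite", warns))
  if (monotone)
    warning("possible monotone partial likelihood: ",
            paste(unique(warns), collapse = "; "))

  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  ll <- fit$loglik[2L]
  k <- length(beta)
  se <- sqrt(diag(V))
  z <- beta / se
  hr <- data.frame(term = names(beta), coef = unname(beta), se = unname(se),
                   HR = exp(unname(beta)),
                   CI_low = exp(unname(beta - 1.96 * se)),
                   CI_high = exp(unname(beta + 1.96 * se)),
                   p = 2 * stats::pnorm(-abs(unname(z))))
  structure(list(coefficients = beta, vcov = V, loglik = ll, k = k,
                 aic = 2 * k - 2 * ll, deviance = -2 * ll, hr = hr,
                 ties = ties, n = nrow(dat), n_events = sum(dat$event),
                 n_subjects = length(unique(table$patient_id)),
                 monotone_warning = monotone, fit = fit),
            class = "cox_fit")
}

set_reference_levels <- function(dat) {
  lv <- list(arm = c("control", "maintenance"),
             age_group = c("<65", "65-74", ">=75"),
             sex = c("F", "M"),
             tumor_site = c("left", "right_transverse", "unspecified_colon",
                            "rectum"))
  for (cn in names(dat)) {
    if (cn %in% names(lv)) {
      dat[[cn]] <- factor(dat[[cn]], levels = lv[[cn]])
    } else if (is.character(dat[[cn]])) {
      dat[[cn]] <- factor(dat[[cn]])
    }
  }
  dat
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("<cox_fit> ", x$n_events, " events / ", x$n, " intervals; k = ", x$k,
      "; loglik = ", format(x$loglik, digits = 7),
      "; AIC = ", format(x$aic, digits = 7), "\n", sep = "")
  print(format(x$hr, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Akaike information criterion of a fitted Cox model
#'
#' `AIC = 2k - 2 loglik` with `loglik` the maximized log partial likelihood
#' and `k` the number of estimated coefficients; the model-comparison scale
#' of the analysis plan (a drop of 4 is a moderate, of more than 10 an
#' important improvement).
#'
#' @param fit a `cox_fit`.
#' @return numeric scalar.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  fit$aic
}

#' @export
deviance.cox_fit <- function(object, ...) object$deviance

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Grambsch-Therneau global proportional-hazards test
#'
#' Classical scaled-Schoenfeld-residual test: the residuals of a fitted Cox
#' model are correlated with a transform `g(t)` of event time; under
#' proportional hazards the global statistic
#' \deqn{T = \frac{d\, u' V u}{\sum_k (g_k - \bar g)^2}, \qquad
#'       u = \sum_k (g_k - \bar g)\, r_k}
#' (with `r_k` the Schoenfeld residual vector at the k-th event, `V` the
#' coefficient covariance and `d` the number of events) is asymptotically
#' chi-squared with one degree of freedom per coefficient. The default
#' time transform is the left-continuous Kaplan-Meier scale
#' `g(t) = 1 - KM(t-)`; `"identity"` and `"rank"` are also available.
#'
#' @param fit a `cox_fit`.
#' @param transform `"km"`, `"identity"` or `"rank"`.
#' @return An object of class `ph_test`: list with `statistic`, `df`,
#'   `p_value`, `transform`, and a per-covariate `table` (term, chisq, df, p).
#' @export
grambsch_global_test <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events == 0L) stop("no events: proportional-hazards test undefined")

  r <- stats::residuals(fit$fit, type = "schoenfeld")
  if (is.null(dim(r))) r <- matrix(r, ncol = 1L,
                                   dimnames = list(names(r), names(fit$coefficients)))
  o <- order(as.numeric(rownames(r)))
  r <- r[o, , drop = FALSE]
  y <- fit$fit$y
  etimes <- sort(y[y[, 3L] == 1, 2L])   # sorted event times, same order as r
  d <- nrow(r)
  stopifnot(length(etimes) == d)
  g <- switch(transform,
              identity = etimes,
              rank = rank(etimes, ties.method = "average"),
              km = km_transform(y, etimes))
  gc_ <- g - mean(g)
  u <- as.numeric(crossprod(r, gc_))       # sum_k (g_k - gbar) r_k
  V <- fit$vcov
  denom <- sum(gc_^2)
  stat <- d * as.numeric(t(u) %*% V %*% u) / denom
  df <- ncol(r)
  per <- d * (u^2) * diag(V) / denom
  tab <- data.frame(term = colnames(r), chisq = per, df = 1,
                    p = 1 - stats::pchisq(per, 1))
  structure(list(statistic = stat, df = df,
                 p_value = 1 - stats::pchisq(stat, df),
                 transform = transform, table = tab),
            class = "ph_test")
}

# left-continuous 1 - KM(t-) evaluated at each sorted event time,
# from the counting-process data of the fitted model
km_transform <- function(y, etimes) {
  stopifnot(ncol(y) == 3L)
  start <- y[, 1L]; stop_ <- y[, 2L]; ev <- y[, 3L]
  ut <- unique(etimes)                         # sorted distinct event times
  nd <- vapply(ut, function(t) sum(ev == 1 & stop_ == t), numeric(1))
  nr <- vapply(ut, function(t) sum(start < t & stop_ >= t), numeric(1))
  km <- cumprod(1 - nd / nr)
  km_left <- c(1, km[-length(km)])             # KM just before each event time
  1 - km_left[findInterval(etimes, ut)]
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Grambsch-Therneau global test (", x$transform, " transform): chisq = ",
      format(x$statistic, digits = 4), ", df = ", x$df, ", p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
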