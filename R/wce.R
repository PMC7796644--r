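#' Estimate a weighted-cumulative-exposure Cox model
#'
#' Represents the lag weight function `w(u)` on `[0, window]` in a cubic
#' B-spline basis and estimates its coefficients by entering the artificial
#' covariates `D_j(t)` (see [wce_artificial_covariates()]) into the partial
#' likelihood jointly with any adjustment covariates. Interior knots are
#' placed at quantiles of the observed dose lags within the window (the
#' usual choice in the weighted-cumulative-exposure literature), unless
#' explicit knots are supplied.
#'
#' @param table a `counting_process` data frame.
#' @param doses landmarked dose data frame.
#' @param window exposure window in days.
#' @param n_interior_knots interior-knot count; a vector of candidates
#'   (default 1:3) is resolved by minimum AIC, the convention of the
#'   weighted-cumulative-exposure literature.
#' @param constrained_right_end force `w(window) = 0`; the default `NULL`
#'   compares the constrained and unconstrained variants by AIC alongside
#'   the knot candidates.
#' @param constrained_right_end force `w(window) = 0`.
#' @param adjust_covariates character vector of additional covariate columns.
#' @param scope `"overall"` or `"cfi_only"`.
#' @param ties ties method for the Cox fit.
#' @param knots optional explicit interior knot positions.
#' @return An object of class `wce_fit`: list with `fit` (the `cox_fit` of
#'   the joint model), `weight` (a `weight_estimate`: the fitted
#'   [weight_function()], its coefficient covariance block and the window),
#'   `window`, and `wce_columns`.
#' @export
fit_wce <- function(table, doses, window, n_interior_knots = 1:3,
                    constrained_right_end = NULL,
                    adjust_covariates = character(),
                    scope = c("overall", "cfi_only"),
                    ties = "efron", knots = NULL) {
  scope <- match.arg(scope)
  constr <- if (is.null(constrained_right_end)) c(FALSE, TRUE)
            else constrained_right_end
  if (is.null(knots) && (length(n_interior_knots) > 1L || length(constr) > 1L)) {
    cand <- expand.grid(k = n_interior_knots, cr = constr)
    fits <- lapply(seq_len(nrow(cand)), function(i)
      tryCatch(fit_wce(table, doses, window, cand$k[i], cand$cr[i],
                       adjust_covariates, scope, ties),
               error = function(e) e))
    ok <- !vapply(fits, inherits, logical(1), "error")
    if (!any(ok)) stop(conditionMessage(fits[[1]]))
    aics <- vapply(fits[ok], function(f) f$fit$aic, numeric(1))
    return(fits[ok][[which.min(aics)]])
  }
  constrained_right_end <- constr
  if (is.null(knots)) {
    knots <- lag_quantile_knots(table, doses, window, n_interior_knots, scope)
  }
  basis <- make_spline_basis(window, constrained_right_end = constrained_right_end,
                             interior_knots = knots)
  table <- add_wce_columns(table, doses, basis, scope = scope)
  nms <- attr(table, "wce_columns")
  fit <- fit_cox_tv(table, c(nms, adjust_covariates), ties = ties)
  theta <- fit$coefficients[nms]
  V <- fit$vcov[nms, nms, drop = FALSE]
  weight <- structure(list(wf = weight_function(unname(theta), basis),
                           vcov = V, window = window),
                      class = "weight_estimate")
  structure(list(fit = fit, weight = weight, window = window,
                 wce_columns = nms, basis = basis,
                 n_interior_knots = n_interior_knots),
            class = "wce_fit")
}

#' @export
print.wce_fit <- function(x, ...) {
  cat("<wce_fit> window ", x$window, " d, J = ", x$basis$J,
      ", AIC = ", format(x$fit$aic, digits = 7), "\n", sep = "")
  invisible(x)
}

# interior knots at quantiles of observed (event time - dose time) lags
lag_quantile_knots <- function(table, doses, window, n_interior_knots, scope) {
  histories <- dose_histories(doses, scope)
  ev_t <- table$stop[table$event]
  lags <- unlist(lapply(histories, function(h) {
    lg <- outer(ev_t, h$times, `-`)
    lg[lg > 0 & lg <= window]
  }), use.names = FALSE)
  if (length(lags) < 10L * n_interior_knots) {
    # too little exposure information to place data-driven knots
    return(window * seq_len(n_interior_knots) / (n_interior_knots + 1L))
  }
  q <- stats::quantile(lags, probs = seq_len(n_interior_knots) /
                         (n_interior_knots + 1L), names = FALSE)
  # guard against collapsed quantiles
  if (any(duplicated(q)) || any(q <= 0) || any(q >= window))
    q <- window * seq_len(n_interior_knots) / (n_interior_knots + 1L)
  q
}

#' Pointwise delta-method band for an estimated weight function
#'
#' The variance of `w_hat(u) = b(u)' theta_hat` is `b(u)' Cov(theta) b(u)`
#' with `b(u)` the basis evaluations; the band is the point estimate plus or
#' minus 1.96 standard errors at each grid point.
#'
#' @param weight_estimate the `weight` element of a [fit_wce()] result.
#' @param u_grid numeric vector of lags (days).
#' @return data frame with columns `u`, `w`, `lo`, `hi` (`lo`/`hi` are `NA`
#'   where the covariance is degenerate).
#' @export
delta_method_band <- function(weight_estimate, u_grid) {
  B <- eval_basis(weight_estimate$wf$basis, u_grid)
  w <- as.numeric(B %*% weight_estimate$wf$theta)
  v <- rowSums((B %*% weight_estimate$vcov) * B)
  se <- ifelse(v >= 0, sqrt(v), NA_real_)
  data.frame(u = u_grid, w = w, lo = w - 1.96 * se, hi = w + 1.96 * se)
}

#' Hazard-ratio curve for a dosing pattern
#'
#' Reconstructs the hazard ratio over time implied by a fitted exposure
#' model for a hypothetical dosing pattern, with patients who received no
#' doses within the window as the reference.
#'
#' For a weight-function model the log hazard ratio at time `t` is
#' `sum_k X(t_k) w_hat(t - t_k)` (doses outside the window contribute 0),
#' with a pointwise delta-method band. For a fixed-decay concentration
#' model, pass `unit_loghr` (and optionally `unit_se`) per concentration
#' unit: the hazard ratio is `exp(unit_loghr * TBC(t))` and the band
#' propagates the coefficient's confidence limits.
#'
#' @param x a `weight_estimate` (or `wce_fit`), or `NULL` when using
#'   `unit_loghr`.
#' @param pattern a [dose_history()] or data frame with `times`/`doses`.
#' @param t_grid evaluation times (days since the pattern's origin).
#' @param unit_loghr,unit_se log hazard ratio (and standard error) per
#'   exposure unit for the fixed-decay model.
#' @param half_life half-life for the fixed-decay model (days).
#' @return data frame of class `hr_pattern`: `t`, `hr`, `lo`, `hi`.
#' @export
hr_for_dose_pattern <- function(x = NULL, pattern, t_grid,
                                unit_loghr = NULL, unit_se = NULL,
                                half_life = 20) {
  pattern <- as_dose_history(pattern)
  if (!is.null(unit_loghr)) {
    conc <- tbc(pattern, t_grid, half_life)
    hr <- exp(unit_loghr * conc)
    if (!is.null(unit_se)) {
      lo <- exp((unit_loghr - 1.96 * unit_se) * conc)
      hi <- exp((unit_loghr + 1.96 * unit_se) * conc)
      sw <- lo > hi                      # protective effects flip the limits
      tmp <- lo[sw]; lo[sw] <- hi[sw]; hi[sw] <- tmp
    } else lo <- hi <- NA_real_
  } else {
    if (inherits(x, "wce_fit")) x <- x$weight
    stopifnot(inherits(x, "weight_estimate"))
    basis <- x$wf$basis
    lp <- se <- numeric(length(t_grid))
    for (i in seq_along(t_grid)) {
      b <- colSums(wce_artificial_covariates(pattern, basis, t_grid[i]))
      lp[i] <- sum(b * x$wf$theta)
      v <- as.numeric(t(b) %*% x$vcov %*% b)
      se[i] <- if (v >= 0) sqrt(v) else NA_real_
    }
    hr <- exp(lp); lo <- exp(lp - 1.96 * se); hi <- exp(lp + 1.96 * se)
  }
  out <- data.frame(t = t_grid, hr = hr, lo = lo, hi = hi)
  class(out) <- c("hr_pattern", "data.frame")
  out
}

#' Select the exposure window by AIC
#'
#' Fits one weighted-cumulative-exposure model per candidate window and
#' returns the window minimizing the AIC (ties broken toward the smaller
#' window). Candidates that fail to converge are recorded and excluded
#' from the argmin with a warning.
#'
#' Windows are compared at a common, parsimonious spline specification —
#' one interior knot and a right-end constraint by default — so every
#' candidate spends the same degrees of freedom and the AIC difference
#' reflects the window, not per-window basis re-optimization. (An
#' unconstrained basis lets each window fit a free weight at its own right
#' end, which blurs the comparison.) Knot-count selection belongs to the
#' estimation stage, after the window is chosen.
#'
#' @inheritParams fit_wce
#' @param candidate_windows numeric vector of at least two windows (days).
#' @param ... further arguments passed to [fit_wce()].
#' @return list with `best_window`, `aic_table` (window, J, loglik, aic,
#'   converged, error), and `best_fit` (the `wce_fit` at the selected
#'   window).
#' @export
select_window <- function(table, doses, candidate_windows,
                          n_interior_knots = 1,
                          constrained_right_end = TRUE, ...) {
  stopifnot(length(candidate_windows) >= 2L)
  fits <- vector("list", length(candidate_windows))
  tab <- data.frame(window = candidate_windows, J = NA_integer_,
                    loglik = NA_real_, aic = NA_real_, converged = FALSE,
                    error = NA_character_)
  for (i in seq_along(candidate_windows)) {
    res <- tryCatch(fit_wce(table, doses, candidate_windows[i],
                            n_interior_knots = n_interior_knots,
                            constrained_right_end = constrained_right_end,
                            ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      tab$error[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      tab$J[i] <- res$basis$J
      tab$loglik[i] <- res$fit$loglik
      tab$aic[i] <- res$fit$aic
      tab$converged[i] <- TRUE
    }
  }
  if (!any(tab$converged)) stop("no candidate window converged")
  if (any(!tab$converged))
    warning("window(s) excluded after fitting failure: ",
            paste(tab$window[!tab$converged], collapse = ", "))
  ok <- which(tab$converged)
  # ties toward the smaller window: order by (aic, window)
  best <- ok[order(tab$aic[ok], tab$window[ok])][1L]
  list(best_window = tab$window[best], aic_table = tab,
       best_fit = fits[[best]])
}
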