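#' Cubic B-spline basis for a weight function on an exposure window
#'
#' Builds the clamped cubic B-spline basis on `[0, window]` used to
#' represent the lag weight function `w(u)` of the weighted cumulative
#' exposure model. With `k` interior knots the unconstrained basis has
#' `k + 4` functions (degree + 1 + interior knots) forming a partition of
#' unity. With `constrained_right_end = TRUE` the two rightmost basis
#' functions are dropped, so every representable weight function satisfies
#' `w(window) = 0` (and a vanishing first derivative there), encoding the
#' assumption that doses at the edge of the window have no residual effect.
#'
#' @param window positive lag horizon in days beyond which past doses are
#'   assumed to have no effect.
#' @param n_interior_knots number of interior knots (1, 2 or 3).
#' @param constrained_right_end logical; force `w(window) = 0`.
#' @param interior_knots optional explicit interior knot positions in
#'   `(0, window)`; overrides the default equally spaced placement. Fits
#'   place them at quantiles of the observed dose lags.
#' @return An object of class `spline_basis`: list with the full knot
#'   vector, `J` (number of retained basis functions), `window`, `degree`
#'   and the constraint flag.
#' @export
make_spline_basis <- function(window, n_interior_knots = 2,
                              constrained_right_end = FALSE,
                              interior_knots = NULL) {
  stopifnot(window > 0)
  if (is.null(interior_knots)) {
    stopifnot(n_interior_knots %in% 1:3)
    interior_knots <- window * seq_len(n_interior_knots) / (n_interior_knots + 1L)
  } else {
    n_interior_knots <- length(interior_knots)
  }
  interior_knots <- sort(as.numeric(interior_knots))
  if (any(interior_knots <= 0) || any(interior_knots >= window))
    stop("interior knots must lie strictly inside (0, window)")
  if (min(diff(c(0, interior_knots, window))) < window * 1e-6)
    stop("window too small for the requested knot spacing")
  degree <- 3L
  knots <- c(rep(0, degree + 1L), interior_knots, rep(window, degree + 1L))
  J_full <- n_interior_knots + degree + 1L
  J <- if (constrained_right_end) J_full - 2L else J_full
  structure(list(knots = knots, J = J, J_full = J_full, window = window,
                 degree = degree, constrained = constrained_right_end),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> cubic, window ", x$window, " d, ", x$J, " functions",
      if (x$constrained) " (right end constrained to 0)", "\n", sep = "")
  invisible(x)
}

#' Evaluate the basis functions at lags `u`
#'
#' @param basis a [make_spline_basis()] object.
#' @param u numeric vector of lags (days since a dose). Lags outside
#'   `[0, window]` evaluate to zero rows.
#' @return numeric matrix `length(u) x basis$J`.
#' @export
eval_basis <- function(basis, u) {
  u <- as.numeric(u)
  inside <- u >= 0 & u <= basis$window
  out <- matrix(0, length(u), basis$J_full)
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(basis$knots, u[inside],
                                           ord = basis$degree + 1L)
  }
  out[, seq_len(basis$J), drop = FALSE]
}

#' Weight function w(u) as a spline-coefficient expansion
#'
#' @param theta coefficient vector of length `basis$J`.
#' @param basis a [make_spline_basis()] object.
#' @return An object of class `weight_function`.
#' @export
weight_function <- function(theta, basis) {
  stopifnot(length(theta) == basis$J)
  structure(list(theta = as.numeric(theta), basis = basis),
            class = "weight_function")
}

#' Evaluate a weight function at lags `u`
#' @param wf a [weight_function()].
#' @param u numeric vector of lags (days).
#' @return numeric vector `w(u)`; zero outside `[0, window]`.
#' @export
eval_weight <- function(wf, u) {
  as.numeric(eval_basis(wf$basis, u) %*% wf$theta)
}

#' Least-squares projection of a lag function onto the basis
#'
#' Finds coefficients minimizing the squared error between
#' `f(u)` and the spline expansion on a dense grid; used to express a
#' parametric weight shape (e.g. exponential decay) in the basis, for
#' instance to compare weighted-cumulative-exposure and fixed-half-life
#' concentration models on a common footing.
#'
#' @param basis a [make_spline_basis()] object.
#' @param f function of lag `u` in days.
#' @param n_grid number of grid points on `[0, window]`.
#' @return a [weight_function()].
#' @export
project_onto_basis <- function(basis, f, n_grid = 401) {
  u <- seq(0, basis$window, length.out = n_grid)
  B <- eval_basis(basis, u)
  theta <- stats::lsfit(B, f(u), intercept = FALSE)$coefficients
  weight_function(theta, basis)
}

#' Artificial covariates for weighted-cumulative-exposure estimation
#'
#' For a dose history and spline basis, computes
#' \deqn{D_j(t) = \sum_{0 < t - t_k \le \mathrm{window}} X(t_k)\,B_j(t - t_k)}
#' so that for any coefficient vector `theta` the weighted cumulative
#' exposure with `w = sum_j theta_j B_j` equals `sum_j theta_j D_j(t)`.
#' Entering the `D_j` as covariates in a Cox model therefore estimates the
#' weight function by unpenalized partial likelihood. Doses older than the
#' window, or not strictly in the past, contribute nothing.
#'
#' @inheritParams cumulative_exposure
#' @param basis a [make_spline_basis()] object.
#' @return numeric matrix `length(t) x basis$J`.
#' @export
wce_artificial_covariates <- function(history, basis, t) {
  history <- as_dose_history(history)
  D <- matrix(0, length(t), basis$J)
  if (length(history$times) == 0L) return(D)
  lag <- outer(t, history$times, `-`)
  keep <- lag > 0 & lag <= basis$window
  if (!any(keep)) return(D)
  B <- matrix(0, length(lag), basis$J)
  B[keep, ] <- eval_basis(basis, lag[keep])
  dim(B) <- c(length(t), length(history$times) * basis$J)
  # accumulate X_k * B_j(t - t_k) over doses k for each j
  for (j in seq_len(basis$J)) {
    cols <- (j - 1L) * length(history$times) + seq_along(history$times)
    D[, j] <- as.numeric(B[, cols, drop = FALSE] %*% history$doses)
  }
  D
}
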