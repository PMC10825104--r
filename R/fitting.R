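#' Frame weights for weighted NLLS fitting
#'
#' Inverse-variance weights for PET measurement error: each frame's weight is
#' proportional to the frame duration divided by the whole-brain activity
#' concentration in that frame, normalized so the largest weight is 1.
#' Frames where the whole-brain value is non-positive get weight 0.
#'
#' @param grid a [time_grid].
#' @param wb_tac whole-brain [tac] on that grid.
#' @return Numeric weight vector (max 1).
#' @export
make_weights <- function(grid, wb_tac) {
  stopifnot(inherits(grid, "time_grid"), inherits(wb_tac, "tac"))
  if (!same_grid(grid, wb_tac$grid)) stop("grid mismatch")
  w <- ifelse(wb_tac$values > 0, grid$frame_duration / wb_tac$values, 0)
  if (max(w) <= 0) stop("all frame weights are zero")
  w / max(w)
}

std_bounds <- function() {
  list(lower = c(K1 = 0, k2 = 0, k3 = 0, Vb = 0),
       upper = c(K1 = 0.5, k2 = 0.5, k3 = 0.2, Vb = 1))
}

#' Standalone weighted 2TCM fit of one TAC
#'
#' Fits a single time-activity curve to the irreversible 2TCM
#' ([twotcm_forward]) against a given input function by weighted nonlinear
#' least squares (bound-constrained Levenberg-Marquardt). Bounds: upper
#' (0.5 mL/g/min, 0.5 1/min, 0.2 1/min, 1 mL/g), lower 0; no
#' distribution-volume constraint. The weighted residual sum of squares
#' (WRSS) is reported in full and over the 0-3 min and 0-60 min windows
#' (frames selected by mid-time), along with the `(K1, k2, k3)` covariance
#' approximation `gamma = (J'J)^-1 WRSS / T` and the error-propagation CV of
#' Ki ([cv_ki]).
#'
#' @param region_tac the [tac] to fit.
#' @param cp plasma input function [tac] (MDIF, IDIF or measured AIF).
#' @param cb whole-blood [tac]; derived as `R * cp` when `NULL`.
#' @param weights frame weights (see [make_weights]); must not be all zero.
#' @param R blood-to-plasma ratio used when `cb` is `NULL`.
#' @param start starting values `c(K1, k2, k3, Vb)`.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return An object of class `fit_result`: `params` ([micro_params]),
#'   `wrss`, `wrss_0_3min`, `wrss_0_60min`, `covariance`, `cv_ki` (percent),
#'   `fitted_curve` ([tac]), `converged`.
#' @export
fit_standalone <- function(region_tac, cp, cb = NULL, weights, R = 1,
                           start = c(0.1, 0.15, 0.05, 0.05), maxiter = 1024) {
  stopifnot(inherits(region_tac, "tac"), inherits(cp, "tac"))
  stop_if_grid_mismatch(region_tac, cp)
  if (is.null(cb)) cb <- tac(cp$grid, R * cp$values)
  else stop_if_grid_mismatch(region_tac, cb)
  weights <- as.numeric(weights)
  if (length(weights) != length(region_tac$grid))
    stop("weights must have one value per frame")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all weights are zero")
  sw <- sqrt(weights)
  resid_fn <- function(th) {
    p <- micro_params(th[1L], th[2L], th[3L], th[4L])
    sw * (twotcm_forward(p, cp, cb)$values - region_tac$values)
  }
  b <- std_bounds()
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(start, b$lower), b$upper),
    lower = b$lower, upper = b$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-9, ptol = 1e-9))
  th <- fit$par
  params <- micro_params(th[1L], th[2L], th[3L], th[4L])
  fitted <- twotcm_forward(params, cp, cb)
  r2 <- weights * (fitted$values - region_tac$values)^2
  tm <- region_tac$grid$mid_time
  wrss <- sum(r2)
  # (K1, k2, k3) block of the weighted-residual Jacobian, forward differences
  J <- vapply(1:3, function(i) {
    h <- max(1e-6, 1e-6 * abs(th[i]))
    thp <- th; thp[i] <- thp[i] + h
    (resid_fn(thp) - resid_fn(th)) / h
  }, numeric(length(tm)))
  res <- structure(list(
    params = params, wrss = wrss,
    wrss_0_3min = sum(r2[tm <= 3]),
    wrss_0_60min = sum(r2[tm <= 60]),
    jtj = crossprod(J),
    covariance = NULL, cv_ki = NA_real_,
    fitted_curve = fitted,
    weights = weights,
    converged = fit$info %in% 1:4,
    n_iterations = fit$niter),
    class = "fit_result")
  res$covariance <- fit_covariance(res)
  res$cv_ki <- cv_ki(res)
  res
}

fit_covariance <- function(fit) {
  T <- length(fit$fitted_curve$grid)
  jtj_inv <- tryCatch(solve(fit$jtj), error = function(e) {
    MASS_ginv(fit$jtj)
  })
  jtj_inv * fit$wrss / T
}

# Moore-Penrose fallback for a singular J'J (e.g. parameters at a bound)
MASS_ginv <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> K1=%.4g k2=%.4g k3=%.4g Vb=%.4g  Ki=%.4g mL/g/min\n  WRSS=%.4g (0-3 min %.4g)  CV(Ki)=%.3g%%  converged=%s\n",
    x$params$K1, x$params$k2, x$params$k3, x$params$Vb, x$params$Ki,
    x$wrss, x$wrss_0_3min, x$cv_ki, x$converged))
  invisible(x)
}

#' Error-propagation coefficient of variation of Ki
#'
#' `CV(%) = 100 sigma / Ki`, where `sigma^2 = g' gamma g` with the gradient
#' `g = (dKi/dK1, dKi/dk2, dKi/dk3) = (k3/kf, -K1 k3/kf^2, K1 k2/kf^2)` and
#' `gamma = (J'J)^-1 WRSS / T` the covariance approximation over the
#' `(K1, k2, k3)` block of the weighted-residual Jacobian.
#'
#' @param fit a `fit_result` from [fit_standalone].
#' @param grid optional [time_grid]; defaults to the fitted curve's grid
#'   (sets `T`, the number of frames).
#' @return CV of Ki in percent.
#' @export
cv_ki <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  p <- fit$params
  if (p$Ki <= 0) {
    if (fit$wrss == 0) return(0)
    stop("CV undefined for Ki <= 0")
  }
  T <- if (is.null(grid)) length(fit$fitted_curve$grid) else length(grid)
  gamma <- tryCatch(solve(fit$jtj), error = function(e) MASS_ginv(fit$jtj)) *
    fit$wrss / T
  g <- ki_gradient(p)
  s2 <- drop(t(g) %*% gamma %*% g)
  100 * sqrt(max(s2, 0)) / p$Ki
}

ki_gradient <- function(p) {
  kf <- p$kf
  c(p$k3 / kf, -p$K1 * p$k3 / kf^2, p$K1 * p$k2 / kf^2)
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of `C(t)/Cp(t)` against `int_0^t Cp(s) ds / Cp(t)`
#' over frames with mid-time beyond `t_star`; for an irreversible tracer the
#' slope estimates the net clearance Ki. The plasma integral is the
#' trapezoid of the piecewise-linear input starting from `(0, 0)`. The slope
#' is reported as `Ki` in mL/100 g/min (x 100); when a [cmrglu_config] is
#' supplied the slope is also converted to CMRGlu.
#'
#' @param region_tac tissue [tac].
#' @param cp plasma input [tac] on the same grid.
#' @param t_star start of the linear phase, minutes (default 20).
#' @param cmrglu optional [cmrglu_config] for the CMRGlu conversion.
#' @return An object of class `patlak_result`: `Ki` (mL/100 g/min),
#'   `intercept` (mL/g), `t_star`, `points_used`, `CMRGlu` (µmol/100 g/min
#'   or `NA`).
#' @export
patlak <- function(region_tac, cp, t_star = 20, cmrglu = NULL) {
  stopifnot(inherits(region_tac, "tac"), inherits(cp, "tac"))
  stop_if_grid_mismatch(region_tac, cp)
  tm <- region_tac$grid$mid_time
  cum <- conv_exp_pl(tm, cp$values, 0)$e
  sel <- tm > t_star & cp$values > 0
  if (sum(sel) < 3L)
    stop("Patlak needs at least 3 frames beyond t* = ", t_star, " min")
  x <- cum[sel] / cp$values[sel]
  y <- region_tac$values[sel] / cp$values[sel]
  co <- stats::coef(stats::lm(y ~ x))
  ki100 <- 100 * unname(co[2L])
  structure(list(Ki = ki100, intercept = unname(co[1L]), t_star = t_star,
                 points_used = sum(sel),
                 CMRGlu = if (is.null(cmrglu)) NA_real_
                          else cmrglu_from_ki(ki100, cmrglu)),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf(
    "<patlak_result> Ki=%.3f mL/100 g/min  intercept=%.4g mL/g  (t*=%g min, %d points)%s\n",
    x$Ki, x$intercept, x$t_star, x$points_used,
    if (is.na(x$CMRGlu)) "" else sprintf("  CMRGlu=%.2f umol/100 g/min", x$CMRGlu)))
  invisible(x)
}

#' Constants for the CMRGlu conversion
#'
#' @param lumped_constant dimensionless lumped constant relating FDG net
#'   uptake to glucose consumption (default 0.52).
#' @param plasma_glucose plasma glucose concentration, µmol/mL.
#' @return An object of class `cmrglu_config`.
#' @export
cmrglu_config <- function(lumped_constant = 0.52, plasma_glucose) {
  if (!is.finite(lumped_constant) || lumped_constant <= 0)
    stop("lumped_constant must be > 0")
  if (!is.finite(plasma_glucose) || plasma_glucose <= 0)
    stop("plasma_glucose must be > 0")
  structure(list(lumped_constant = lumped_constant,
                 plasma_glucose = plasma_glucose),
            class = "cmrglu_config")
}

#' Convert a Patlak slope to CMRGlu
#'
#' `CMRGlu = Ki * plasma_glucose / lumped_constant`, mapping the FDG net
#' clearance (mL/100 g/min) to the cerebral metabolic rate of glucose
#' (µmol/100 g/min).
#'
#' @param ki net clearance in mL/100 g/min.
#' @param cfg a [cmrglu_config].
#' @return CMRGlu in µmol/100 g/min.
#' @export
cmrglu_from_ki <- function(ki, cfg) {
  stopifnot(inherits(cfg, "cmrglu_config"))
  ki * cfg$plasma_glucose / cfg$lumped_constant
}

auc_window <- function(x, lo, hi) {
  tm <- x$grid$mid_time
  v <- x$values
  if (tm[1L] > 0) { tm <- c(0, tm); v <- c(0, v) }
  lo <- max(lo, tm[1L]); hi <- min(hi, tm[length(tm)])
  if (hi <= lo) return(0)
  tt <- sort(unique(c(lo, hi, tm[tm > lo & tm < hi])))
  vv <- stats::approx(tm, v, xout = tt)$y
  sum(diff(tt) * (vv[-1L] + vv[-length(vv)]) / 2)
}

#' Compare two input functions by windowed AUC
#'
#' Trapezoid areas under both curves over each window (defaults 0-5, 5-10,
#' 10-30 and 30-60 min), the per-window and overall `c1/c2` AUC ratios, and
#' the overall percent difference `100 |A1 - A2| / mean(A1, A2)`.
#'
#' @param c1,c2 two [tac]s on the same grid.
#' @param windows list of `c(t_lo, t_hi)` pairs, minutes.
#' @return A list with `windows` (data.frame: `t_lo`, `t_hi`, `auc1`, `auc2`,
#'   `ratio`), `overall_ratio` and `percent_difference`.
#' @export
compare_curves <- function(c1, c2,
                           windows = list(c(0, 5), c(5, 10),
                                          c(10, 30), c(30, 60))) {
  stopifnot(inherits(c1, "tac"), inherits(c2, "tac"))
  stop_if_grid_mismatch(c1, c2)
  wdf <- do.call(rbind, lapply(windows, function(w) {
    a1 <- auc_window(c1, w[1L], w[2L]); a2 <- auc_window(c2, w[1L], w[2L])
    data.frame(t_lo = w[1L], t_hi = w[2L], auc1 = a1, auc2 = a2,
               ratio = a1 / a2)
  }))
  full <- c(min(wdf$t_lo), max(wdf$t_hi))
  A1 <- auc_window(c1, full[1L], full[2L])
  A2 <- auc_window(c2, full[1L], full[2L])
  list(windows = wdf, overall_ratio = A1 / A2,
       percent_difference = 100 * abs(A1 - A2) / ((A1 + A2) / 2))
}
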