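#' Simultaneous-estimation problem
#'
#' Bundles everything a SIME fit needs: the whole-brain TAC, `n >= 2`
#' regional (cluster) TACs with distinct kinetics, one or more late
#' blood-sample anchors, the blood-to-plasma ratio `R`, and the estimator
#' mode (`"mdif"` or `"idif"`).
#'
#' @param wb_tac whole-brain [tac].
#' @param region_tacs list of [tac]s on the same grid (whole brain excluded).
#' @param anchors data.frame with columns `time_min` (mid-draw time, minutes,
#'   inside the scan window) and `conc` (plasma activity concentration,
#'   kBq/mL, > 0); optional `weight` column (defaults: 1 for MDIF-SIME, 10
#'   for IDIF-SIME, applied to the anchor terms of the cost).
#' @param R dimensionless blood-to-plasma ratio.
#' @param mode `"mdif"` (input from the 2TCM inversion of the whole-brain
#'   TAC) or `"idif"` (input as a fitted exponential model).
#' @return An object of class `sime_problem`.
#' @export
sime_problem <- function(wb_tac, region_tacs, anchors, R = 0.9,
                         mode = c("mdif", "idif")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wb_tac, "tac"), is.list(region_tacs))
  if (length(region_tacs) < 2L) stop("SIME needs at least 2 regional TACs")
  for (x in region_tacs) stopifnot(inherits(x, "tac"))
  do.call(stop_if_grid_mismatch, c(list(wb_tac), region_tacs))
  anchors <- as.data.frame(anchors)
  if (!all(c("time_min", "conc") %in% names(anchors)))
    stop("anchors need columns time_min and conc")
  if (nrow(anchors) < 1L) stop("at least one anchor is required")
  if (any(anchors$conc <= 0)) stop("anchor concentrations must be positive")
  t_end <- max(wb_tac$grid$frame_start + wb_tac$grid$frame_duration)
  if (any(anchors$time_min < 0 | anchors$time_min > t_end))
    stop("anchor times must lie inside the scan window [0, ", t_end, "] min")
  if (is.null(anchors$weight))
    anchors$weight <- if (mode == "idif") 10 else 1
  structure(list(wb_tac = wb_tac, region_tacs = region_tacs,
                 anchors = anchors, R = R, mode = mode),
            class = "sime_problem")
}

# default box bounds for tissue parameters (per fitted TAC)
tissue_bounds <- function() {
  list(lower = c(s = 0.01, k2 = 0.01, k3 = 0.01, Vb = 0.01),
       upper = c(s = 0.999, k2 = 0.4, k3 = 0.2, Vb = 0.10))
}

# K1 is reparameterized as K1 = s * (k2 + k3), s in (0, 1), which enforces
# the distribution-volume constraint K1 < k2 + k3 smoothly.
unpack_tissue <- function(v) {
  micro_params(K1 = v[1L] * (v[2L] + v[3L]), k2 = v[2L], k3 = v[3L], Vb = v[4L])
}

pack_tissue <- function(p) {
  kf <- p$k2 + p$k3
  c(s = if (kf > 0) p$K1 / kf else 0, k2 = p$k2, k3 = p$k3, Vb = p$Vb)
}

sime_region_residuals <- function(region_params, region_tacs, cp, cb) {
  unlist(lapply(seq_along(region_tacs), function(j) {
    pred <- twotcm_forward(region_params[[j]], cp, cb)
    pred$values - region_tacs[[j]]$values
  }), use.names = FALSE)
}

#' SIME cost function (residual sum of squares)
#'
#' Evaluates the SIME objective at given parameters: the unweighted residual
#' sum of squares over all regional TACs plus the (optionally weighted)
#' squared differences between the candidate input function, interpolated at
#' the anchor times, and the anchor concentrations. Useful for optimality
#' checks and diagnostics.
#'
#' @param problem a [sime_problem].
#' @param input_params a [micro_params] (whole brain; `mode = "mdif"`) or a
#'   [feng_params] (`mode = "idif"`).
#' @param region_params list of [micro_params], one per regional TAC.
#' @return The scalar cost.
#' @export
sime_cost <- function(problem, input_params, region_params) {
  cp <- sime_input_curve(problem, input_params)
  cb <- tac(cp$grid, problem$R * cp$values)
  rr <- sime_region_residuals(region_params, problem$region_tacs, cp, cb)
  av <- interp_tac(cp, problem$anchors$time_min)
  sum(rr^2) + sum(problem$anchors$weight * (av - problem$anchors$conc)^2)
}

sime_input_curve <- function(problem, input_params) {
  if (inherits(input_params, "micro_params"))
    mdif_from_wb(mdif_model(input_params, problem$R), problem$wb_tac)
  else if (inherits(input_params, "feng_params"))
    feng_input(input_params, problem$wb_tac$grid)
  else stop("input_params must be micro_params or feng_params")
}

# residual vector for nls.lm; theta layout:
#   mdif: (s, k2, k3, Vb)_WB, then (s, k2, k3, Vb) per region  -> 4n + 4
#   idif: (A1, A2, A3, l1, l2, l3, delta), then 4 per region   -> 4n + 7
sime_residuals <- function(theta, problem) {
  n <- length(problem$region_tacs)
  if (problem$mode == "mdif") {
    ip <- unpack_tissue(theta[1:4])
    off <- 4L
  } else {
    ip <- feng_params(theta[1L], theta[2L], theta[3L],
                      theta[4L], theta[5L], theta[6L], theta[7L])
    off <- 7L
  }
  cp <- sime_input_curve(problem, ip)
  cb <- tac(cp$grid, problem$R * cp$values)
  rp <- lapply(seq_len(n), function(j)
    unpack_tissue(theta[off + 4L * (j - 1L) + 1:4]))
  rr <- sime_region_residuals(rp, problem$region_tacs, cp, cb)
  av <- interp_tac(cp, problem$anchors$time_min)
  c(rr, sqrt(problem$anchors$weight) * (av - problem$anchors$conc))
}

sime_bounds <- function(problem) {
  n <- length(problem$region_tacs)
  tb <- tissue_bounds()
  if (problem$mode == "mdif") {
    list(lower = c(tb$lower, rep(tb$lower, n)),
         upper = c(tb$upper, rep(tb$upper, n)))
  } else {
    d0 <- estimate_delay(problem$wb_tac)
    ten_s <- 10 / 60
    list(lower = c(rep(0, 6), max(0, d0 - ten_s), rep(tb$lower, n)),
         upper = c(4000, 100, 50, 25, 1, 0.1, d0 + ten_s, rep(tb$upper, n)))
  }
}

# Multi-start schedule over the *input-model* parameters only (4 for the
# MDIF whole-brain set, 7 for the exponential IDIF): Latin-hypercube draws
# inside that box plus its geometric and arithmetic midpoints. The tissue
# parameters of every start are then profiled out: each regional TAC is
# fitted separately against the candidate input function (a cheap,
# well-behaved 4-parameter fit), which places the start on the
# variable-projection manifold. The joint fit is strongly multimodal when
# all 4n + 4 parameters are randomized at once, but very reliable from
# manifold starts.
sime_input_box <- function(problem) {
  tb <- tissue_bounds()
  if (problem$mode == "mdif") {
    list(lower = tb$lower, upper = tb$upper)
  } else {
    d0 <- estimate_delay(problem$wb_tac)
    ten_s <- 10 / 60
    list(lower = c(rep(0, 6), max(0, d0 - ten_s)),
         upper = c(4000, 100, 50, 25, 1, 0.1, d0 + ten_s))
  }
}

sime_input_starts <- function(problem, n_starts, seed) {
  box <- sime_input_box(problem)
  lo <- pmax(box$lower, box$upper * 1e-3)
  geo <- sqrt(lo * box$upper)
  ari <- (box$lower + box$upper) / 2
  draws <- if (n_starts >= 1L) local_seed(seed, {
    u <- lhs::randomLHS(n_starts, length(box$lower))
    lapply(seq_len(n_starts), function(i)
      box$lower + u[i, ] * (box$upper - box$lower))
  }) else list()
  structured <- if (problem$mode == "idif")
    idif_structured_starts(problem, box) else list()
  c(structured, list(geo, ari), draws)
}

# Data-driven starting points for the exponential input model, built from
# the measurements themselves:
#   - tail rate/amplitude (lambda3, A3) from the log-slope through the
#     anchors (the anchors are late plasma samples, so they sit on the
#     slowest exponential);
#   - first-pass rate lambda1 from the whole-brain peak lag (the input
#     A1 t e^{-l1 t} term peaks at 1/lambda1 after arrival);
#   - amplitude A1 from the whole-brain peak scaled by candidate blood
#     volume fractions (early WB signal ~ Vb R Cp).
idif_structured_starts <- function(problem, box) {
  a <- problem$anchors[order(problem$anchors$time_min), ]
  if (nrow(a) >= 2L) {
    l3 <- log(a$conc[1L] / a$conc[nrow(a)]) /
      (a$time_min[nrow(a)] - a$time_min[1L])
    l3 <- min(max(l3, 1e-4), box$upper[6L])
  } else l3 <- sqrt(1e-4 * box$upper[6L])
  A3 <- min(a$conc[1L] * exp(l3 * a$time_min[1L]), box$upper[3L])
  d0 <- (box$lower[7L] + box$upper[7L]) / 2
  tm <- problem$wb_tac$grid$mid_time
  early <- tm <= 2
  tpk <- tm[early][which.max(problem$wb_tac$values[early])]
  wb_pk <- max(problem$wb_tac$values[early])
  l1 <- min(max(1 / max(tpk - d0, 0.05), 0.5), box$upper[4L])
  out <- list()
  for (vb in c(0.03, 0.05, 0.08)) for (l2 in c(0.05, 0.2)) {
    A1 <- min(exp(1) * l1 * wb_pk / (problem$R * vb), box$upper[1L])
    st <- c(A1, A3, A3, l1, l2, l3, d0)
    out[[length(out) + 1L]] <- pmin(pmax(st, box$lower), box$upper)
  }
  out
}

# profile the tissue parameters: independent bounded LM fit of each region
# against the candidate input curve
sime_profile_regions <- function(problem, input_theta) {
  ip <- if (problem$mode == "mdif") unpack_tissue(input_theta)
        else feng_params(input_theta[1L], input_theta[2L], input_theta[3L],
                         input_theta[4L], input_theta[5L], input_theta[6L],
                         input_theta[7L])
  cp <- sime_input_curve(problem, ip)
  cb <- tac(cp$grid, problem$R * cp$values)
  tb <- tissue_bounds()
  st <- (tb$lower + tb$upper) / 2
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                     ptol = 1e-12)
  unlist(lapply(problem$region_tacs, function(tc) {
    rf <- function(th)
      twotcm_forward(unpack_tissue(th), cp, cb)$values - tc$values
    fit <- tryCatch(
      minpack.lm::nls.lm(st, tb$lower, tb$upper, fn = rf, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) st else fit$par
  }), use.names = FALSE)
}

sime_fit <- function(problem, n_starts, seed, maxiter) {
  b <- sime_bounds(problem)
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter,
                                     ftol = 1e-9, ptol = 1e-9)
  # screening: profile a larger candidate pool (cheap per-region fits) and
  # rank the manifold starts by their joint cost; only the most promising
  # go through the expensive full joint fit
  n_pool <- if (n_starts >= 1L) max(4L * n_starts, 24L) else 0L
  starts <- lapply(sime_input_starts(problem, n_pool, seed), function(inp) {
    th0 <- c(inp, sime_profile_regions(problem, inp))
    list(theta = th0, cost = sum(sime_residuals(th0, problem)^2))
  })
  starts <- starts[order(vapply(starts, `[[`, 0, "cost"))]
  n_polish <- min(length(starts), n_starts + 2L)
  best <- NULL
  for (st in starts[seq_len(n_polish)]) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st$theta, lower = b$lower, upper = b$upper,
                         fn = sime_residuals, problem = problem,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all SIME starts failed")
  best
}

sime_result <- function(problem, fit) {
  n <- length(problem$region_tacs)
  th <- fit$par
  if (problem$mode == "mdif") {
    ip <- unpack_tissue(th[1:4]); off <- 4L
  } else {
    ip <- feng_params(th[1L], th[2L], th[3L], th[4L], th[5L], th[6L], th[7L])
    off <- 7L
  }
  rp <- lapply(seq_len(n), function(j)
    unpack_tissue(th[off + 4L * (j - 1L) + 1:4]))
  cp <- sime_input_curve(problem, ip)
  av <- interp_tac(cp, problem$anchors$time_min)
  pd <- 100 * abs(av - problem$anchors$conc) /
    ((av + problem$anchors$conc) / 2)
  structure(list(
    mode = problem$mode,
    wb_params = if (problem$mode == "mdif") ip else NULL,
    feng = if (problem$mode == "idif") ip else NULL,
    region_params = rp,
    input_function = cp,
    cost = fit$deviance,
    anchor_residuals = pd,
    converged = fit$info %in% 1:4,
    n_parameters = length(th),
    n_iterations = fit$niter,
    message = fit$message),
    class = "sime_result")
}

#' @export
print.sime_result <- function(x, ...) {
  cat(sprintf(
    "<sime_result> mode=%s  %d parameters, %d regions\n  cost=%.6g  converged=%s (%d iterations)\n",
    x$mode, x$n_parameters, length(x$region_params), x$cost,
    x$converged, x$n_iterations))
  cat(sprintf("  anchor %% difference: %s\n",
              paste(sprintf("%.2f", x$anchor_residuals), collapse = ", ")))
  invisible(x)
}

#' Fit the MDIF-SIME estimator
#'
#' Jointly estimates the four whole-brain microparameters that define the
#' model-derived input function (via the closed-form 2TCM inversion of the
#' whole-brain TAC) and four tissue parameters per regional TAC, by
#' minimizing the residual sum of squares over all regional TACs plus the
#' squared anchor mismatches. Tissue boxes: upper (0.2 mL/g/min, 0.4, 0.2
#' 1/min, 0.10 mL/g), lower 0.01 on all parameters, with the distribution-
#' volume constraint `K1 < k2 + k3` enforced by reparameterization. The fit
#' uses bound-constrained Levenberg-Marquardt over a seeded multi-start
#' schedule (Latin-hypercube draws plus the geometric midpoint of the box);
#' the best final cost wins.
#'
#' @param problem a [sime_problem] with `mode = "mdif"`.
#' @param n_starts number of Latin-hypercube starts (default 8; the bounds
#'   midpoint is always added).
#' @param seed integer seed for the start schedule.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `sime_result`: recovered whole-brain [micro_params], regional
#'   [micro_params], the input function [tac], final cost, per-anchor percent
#'   differences and convergence metadata.
#' @export
fit_sime_mdif <- function(problem, n_starts = 8, seed = 1L, maxiter = 1024) {
  stopifnot(inherits(problem, "sime_problem"))
  if (problem$mode != "mdif") stop("problem mode must be 'mdif'")
  sime_result(problem, sime_fit(problem, n_starts, seed, maxiter))
}

#' Fit the exponential-IDIF SIME comparator
#'
#' The original SIME formulation: the input function is a four-exponential-
#' coefficient model ([feng_params]; 7 free parameters including a delay)
#' fitted jointly with four tissue parameters per regional TAC. The anchor
#' terms of the cost carry an extra weight (default 10). Input-model upper
#' bounds: 4000 kBq/mL/min, 100, 50 kBq/mL, 25, 1, 0.1 1/min; lower bounds
#' zero; the delay is constrained to +/- 10 s around an initial estimate from
#' the whole-brain TAC rise ([estimate_delay]).
#'
#' @inheritParams fit_sime_mdif
#' @param problem a [sime_problem] with `mode = "idif"`.
#' @return A `sime_result` with `feng` holding the fitted input model.
#' @export
fit_sime_idif <- function(problem, n_starts = 8, seed = 1L, maxiter = 1024) {
  stopifnot(inherits(problem, "sime_problem"))
  if (problem$mode != "idif") stop("problem mode must be 'idif'")
  sime_result(problem, sime_fit(problem, n_starts, seed, maxiter))
}

#' Initial tracer-arrival delay from the whole-brain TAC
#'
#' Returns the time at which the whole-brain TAC first exceeds 5% of its
#' early (first 2 minutes) maximum, with linear back-interpolation to the
#' crossing. Used to centre the delay box of the IDIF-SIME fit.
#'
#' @param wb_tac whole-brain [tac] with a rising early phase.
#' @return Arrival delay in minutes.
#' @export
estimate_delay <- function(wb_tac) {
  stopifnot(inherits(wb_tac, "tac"))
  tm <- wb_tac$grid$mid_time
  v <- wb_tac$values
  early <- v[tm <= 2]
  if (!length(early)) early <- v[1:min(2L, length(v))]
  peak <- max(early)
  if (peak <= 0 || diff(range(v)) == 0)
    stop("flat whole-brain TAC: cannot estimate arrival delay")
  thr <- 0.05 * peak
  i <- which(v > thr)[1L]
  if (is.na(i)) stop("whole-brain TAC never exceeds the rise threshold")
  if (i == 1L) {
    if (v[1L] <= 0) return(tm[1L])
    # back-interpolate towards the implied zero at t = 0
    return(tm[1L] * thr / v[1L])
  }
  t0 <- tm[i - 1L]; v0 <- v[i - 1L]
  t0 + (thr - v0) * (tm[i] - t0) / (v[i] - v0)
}
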