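# Exact convolution of exponential kernels with a piecewise-linear interpolant
# of a sampled curve, on an arbitrary (non-uniform) time grid.
#
# Both the forward tissue model and the input-function inversion convolve sums
# of decaying exponentials with a sampled curve. Clinical frame schedules are
# strongly non-uniform (2 s early, 300 s late), so discrete/FFT convolution
# biases the result. Instead the sampled curve f is interpolated linearly
# between its sample times (with an implied node f(0) = 0: no tracer before
# injection) and the convolutions
#
#   E(t) = int_0^t exp(-a (t-s)) f(s) ds
#   T(t) = int_0^t (t-s) exp(-a (t-s)) f(s) ds
#
# are accumulated exactly per interval by the recursion
#
#   E_i = e * E_{i-1} + f_i M0 - m M1
#   T_i = e * (T_{i-1} + h E_{i-1}) + f_i M1 - m M2
#
# where h is the interval width, e = exp(-a h), m the interval slope, and
# Mk = int_0^h v^k exp(-a v) dv. Mk switch to series for small a*h to avoid
# cancellation. a = 0 reduces E to the running trapezoid integral.

exp_moments <- function(a, h) {
  x <- a * h
  if (abs(x) < 1e-3) {
    m0 <- h * (1 - x / 2 + x^2 / 6 - x^3 / 24)
    m1 <- h^2 * (1 / 2 - x / 3 + x^2 / 8 - x^3 / 30)
    m2 <- h^3 * (1 / 3 - x / 4 + x^2 / 10 - x^3 / 36)
  } else {
    e <- exp(-x)
    m0 <- (1 - e) / a
    m1 <- (1 - e * (1 + x)) / a^2
    m2 <- (2 - e * (2 + 2 * x + x^2)) / a^3
  }
  c(m0, m1, m2)
}

# t: strictly increasing sample times (> 0 allowed; node (0,0) is prepended
# when t[1] > 0); f: samples. Returns list(e = E(t), t1 = T(t)) at the
# original sample times.
conv_exp_pl <- function(t, f, a, need_t1 = FALSE) {
  stopifnot(length(t) == length(f), a >= 0)
  if (t[1L] > 0) { tt <- c(0, t); ff <- c(0, f); drop1 <- TRUE }
  else { tt <- t; ff <- f; drop1 <- FALSE }
  n <- length(tt)
  E <- numeric(n); T1 <- numeric(n)
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1L]
    m <- (ff[i] - ff[i - 1L]) / h
    mo <- exp_moments(a, h)
    e <- exp(-a * h)
    Eprev <- E[i - 1L]
    E[i] <- e * Eprev + ff[i] * mo[1L] - m * mo[2L]
    if (need_t1)
      T1[i] <- e * (T1[i - 1L] + h * Eprev) + ff[i] * mo[2L] - m * mo[3L]
  }
  if (drop1) { E <- E[-1L]; T1 <- T1[-1L] }
  if (need_t1) list(e = E, t1 = T1) else list(e = E)
}
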