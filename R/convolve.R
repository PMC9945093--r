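# Fine-grid convolution and frame-averaging helpers shared by the forward
# simulators and the SRTM basis-function fitter. All kinetic convolutions in
# the package go through conv_exp() so that forward simulation and fitting
# use one discretization contract: uniform grid (step <= 0.05 min),
# trapezoidal quadrature.

# (f ⊗ e^{-k t})(t) on a uniform grid t starting at 0.
# Uses e^{-k t} * cumtrapz(f e^{k s}); the integrand peaks at s = t so the
# product never loses precision to cancellation.
conv_exp <- function(t, f, k) {
  if (k < 0) stop("rate constant must be nonnegative")
  g <- pracma::cumtrapz(t, f * exp(k * t))
  as.vector(exp(-k * t) * g)
}

# Mean of a sampled curve over [a, b], with linear interpolation at the
# interval endpoints so frame boundaries need not sit on grid points.
integrate_mean <- function(t, y, a, b) {
  if (b <= a) stop("empty integration interval")
  inside <- t > a & t < b
  ya <- stats::approx(t, y, xout = a, rule = 2)$y
  yb <- stats::approx(t, y, xout = b, rule = 2)$y
  tt <- c(a, t[inside], b)
  yy <- c(ya, y[inside], yb)
  pracma::trapz(tt, yy) / (b - a)
}

# Average a fine-grid curve within every frame of a schedule: one cumulative
# trapezoid integral, evaluated at all frame boundaries by interpolation
# (exact when boundaries sit on grid points).
frame_average <- function(t, y, schedule) {
  cum <- pracma::cumtrapz(t, y)
  ia <- stats::approx(t, cum, xout = schedule$start, rule = 2)$y
  ib <- stats::approx(t, cum, xout = schedule$end, rule = 2)$y
  (ib - ia) / schedule$dur
}

# Uniform simulation grid covering a schedule.
fine_grid <- function(schedule, step = 0.025) {
  t_end <- schedule$end[n_frames(schedule)]
  seq(0, t_end, by = step)
}

# A frame-sampled TAC as a fine-grid curve: linear interpolation through
# (0, 0) and the frame mid-points, held constant beyond the last mid-time.
tac_on_grid <- function(tac, t) {
  stats::approx(c(0, tac$schedule$mid), c(0, tac$values), xout = t,
                rule = 2)$y
}
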