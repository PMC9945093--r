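#' Fit the simplified reference tissue model
#'
#' Estimates `(R1, k2, BP_ND)` of the simplified reference tissue model
#' (SRTM) for a target-region TAC against a reference-region TAC, without
#' arterial sampling. The default estimator is the basis-function method
#' (BFM): for each candidate apparent efflux rate `k2a` on a log-spaced
#' grid, the basis `B(t) = C_R ⊗ exp(-k2a t)` is computed by fine-grid
#' trapezoidal convolution and frame-averaged, the two-parameter linear
#' least-squares problem `C_T ~ theta1 C_R + theta2 B` is solved, and the
#' grid point with minimal residual sum of squares is selected (ties go to
#' the smallest `k2a`). Parameters are then recovered as `R1 = theta1`,
#' `k2 = theta2 + theta1 k2a` and `BP_ND = k2/k2a - 1`; the distribution
#' volume ratio is `DVR = 1 + BP_ND`. `method = "nls"` refines the BFM
#' solution by Levenberg-Marquardt nonlinear least squares on
#' `(R1, k2, BP_ND)` directly.
#'
#' @param target target-region [tac].
#' @param reference reference-region [tac] on the same schedule.
#' @param method `"bfm"` (default) or `"nls"` (BFM-initialized refinement).
#' @param k2a_grid candidate `k2a` values, 1/min; default 200 log-spaced
#'   points on \[0.006, 0.6\].
#' @param weights `"none"` (default, ordinary least squares) or
#'   `"duration"` (weights proportional to frame duration).
#' @param step fine-grid step for the basis convolution, minutes.
#' @param basis optional precomputed [srtm_basis()] for this reference and
#'   grid (used by [fit_subject()] to share work across regions).
#' @return An object of class `srtm_fit` with components `R1`, `k2`, `k2a`,
#'   `bp` (BP_ND), `dvr`, `rss`, `method`, `boundary` (TRUE when the RSS
#'   minimum sat on the grid edge), `fitted`, and the data. Supports
#'   `print()`, `summary()`, `coef()`, `fitted()`, `residuals()`,
#'   `predict()` and `plot()`.
#' @examples
#' cp <- input_function()
#' sched <- default_schedule()
#' ref <- onetc_forward(cp, 0.45, 0.09, sched, region = "BS")
#' hc <- srtm_forward(ref, R1 = 0.95, k2 = 0.2, bp = 0.55, region = "HC")
#' fit <- fit_srtm(hc, ref)
#' coef(fit)
#' @export
fit_srtm <- function(target, reference, method = c("bfm", "nls"),
                     k2a_grid = default_k2a_grid(),
                     weights = c("none", "duration"),
                     step = 0.025, basis = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  method <- match.arg(method)
  weights <- match.arg(weights)
  if (!same_schedule(target$schedule, reference$schedule))
    stop("target and reference must share one frame schedule")
  if (max(abs(reference$values)) < 1e-12)
    stop("reference TAC is identically zero")
  if (is.null(basis)) basis <- srtm_basis(reference, k2a_grid, step)
  sched <- target$schedule
  w <- if (weights == "duration") sched$dur / mean(sched$dur)
       else rep(1, n_frames(sched))

  y <- target$values
  cr <- reference$values
  sw <- sqrt(w)
  best <- bfm_scan(y, cr, basis$frames, sw)
  k2a <- basis$k2a_grid[best$idx]
  R1 <- best$theta[1L]
  k2 <- best$theta[2L] + R1 * k2a
  bp <- k2 / k2a - 1
  fit <- structure(list(
    region = target$region, R1 = R1, k2 = k2, k2a = k2a, bp = bp,
    dvr = 1 + bp, rss = best$rss, method = "BFM",
    boundary = best$idx %in% c(1L, length(basis$k2a_grid)),
    fitted = best$fitted, target = target, reference = reference,
    weights = weights, w = w, step = step), class = "srtm_fit")
  if (fit$boundary)
    warning("SRTM RSS minimum at the k2a grid boundary (region ",
            target$region, ")")

  if (method == "nls") fit <- srtm_nls_refine(fit, basis)
  fit
}

#' @rdname fit_srtm
#' @export
default_k2a_grid <- function() exp(seq(log(0.006), log(0.6), length.out = 200))

#' Precompute SRTM basis functions for a reference TAC
#'
#' Computes the frame-averaged basis `C_R ⊗ exp(-k2a t)` for every grid
#' value once, so that all regions of one subject can be fitted against the
#' same reference without repeating the convolutions.
#'
#' @inheritParams fit_srtm
#' @return An object of class `srtm_basis`.
#' @export
srtm_basis <- function(reference, k2a_grid = default_k2a_grid(),
                       step = 0.025) {
  stopifnot(inherits(reference, "tac"))
  if (any(diff(k2a_grid) <= 0) || any(k2a_grid <= 0))
    stop("k2a_grid must be positive and strictly increasing")
  if (length(k2a_grid) < 3L) stop("k2a_grid needs at least 3 points")
  sched <- reference$schedule
  t <- fine_grid(sched, step)
  cr_fine <- tac_on_grid(reference, t)
  frames <- vapply(k2a_grid, function(k)
    frame_average(t, conv_exp(t, cr_fine, k), sched),
    numeric(n_frames(sched)))
  structure(list(k2a_grid = k2a_grid, frames = frames,
                 schedule = sched, step = step),
            class = "srtm_basis")
}

# Linear scan over the k2a grid; returns index, two thetas, rss, fitted.
# which.min() takes the first of exactly tied minima, i.e. the smallest k2a.
bfm_scan <- function(y, cr, basis_frames, sw) {
  yw <- y * sw
  crw <- cr * sw
  rss <- vapply(seq_len(ncol(basis_frames)), function(j) {
    sum(stats::lm.fit(cbind(crw, basis_frames[, j] * sw), yw)$residuals^2)
  }, numeric(1))
  idx <- which.min(rss)
  X <- cbind(crw, basis_frames[, idx] * sw)
  ls <- stats::lm.fit(X, yw)
  list(rss = rss[idx], idx = idx, theta = unname(ls$coefficients),
       fitted = (X %*% ls$coefficients)[, 1L] / sw)
}

# Levenberg-Marquardt refinement on (R1, k2, bp), started from a BFM fit.
srtm_nls_refine <- function(fit, basis) {
  target <- fit$target
  reference <- fit$reference
  sched <- target$schedule
  t <- fine_grid(sched, fit$step)
  cr_fine <- tac_on_grid(reference, t)
  sw <- sqrt(fit$w)
  model_frames <- function(p) {
    k2a <- p[2L] / (1 + p[3L])
    b <- frame_average(t, conv_exp(t, cr_fine, k2a), sched)
    p[1L] * reference$values + (p[2L] - p[1L] * k2a) * b
  }
  res_fun <- function(p) (target$values - model_frames(p)) * sw
  start <- c(R1 = fit$R1, k2 = fit$k2, bp = fit$bp)
  nls <- minpack.lm::nls.lm(
    par = start, fn = res_fun,
    lower = c(1e-4, 1e-5, -0.999), upper = c(10, 5, 50),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- nls$par
  fit$R1 <- unname(p[1L]); fit$k2 <- unname(p[2L]); fit$bp <- unname(p[3L])
  fit$k2a <- fit$k2 / (1 + fit$bp)
  fit$dvr <- 1 + fit$bp
  fit$fitted <- model_frames(p)
  fit$rss <- sum((target$values - fit$fitted)^2 * fit$w)
  fit$method <- "NLS"
  fit
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf(
    "SRTM fit (%s), region %s vs reference %s\n  R1 = %.4f, k2 = %.4f /min, BP_ND = %.4f, DVR = %.4f, RSS = %.4g%s\n",
    x$method, x$region, x$reference$region, x$R1, x$k2, x$bp, x$dvr, x$rss,
    if (x$boundary) " [grid boundary]" else ""))
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) {
  c(R1 = object$R1, k2 = object$k2, BP_ND = object$bp, DVR = object$dvr)
}

#' @export
fitted.srtm_fit <- function(object, ...) object$fitted

#' @export
residuals.srtm_fit <- function(object, ...) object$target$values - object$fitted

#' @param newdata optional [frame_schedule] on which to evaluate the fitted
#'   model (defaults to the fitted schedule).
#' @rdname fit_srtm
#' @param object,x an `srtm_fit`.
#' @param ... unused.
#' @export
predict.srtm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(inherits(newdata, "frame_schedule"))
  srtm_forward(object$reference, object$R1, object$k2, object$bp,
               schedule = newdata, region = object$region,
               step = object$step)$values
}

#' @export
summary.srtm_fit <- function(object, ...) {
  n <- n_frames(object$target$schedule)
  sigma <- sqrt(object$rss / max(1, n - 3))
  structure(list(fit = object, n = n, sigma = sigma), class = "summary.srtm_fit")
}

#' @export
print.summary.srtm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d frames, residual sigma = %.4g\n", x$n, x$sigma))
  invisible(x)
}

#' @export
plot.srtm_fit <- function(x, ...) {
  mid <- mid_times(x$target$schedule)
  graphics::plot(mid, x$target$values, xlab = "time (min)",
                 ylab = paste0("activity (", x$target$units, ")"),
                 main = sprintf("SRTM fit: %s (DVR %.2f)", x$region, x$dvr),
                 ...)
  graphics::lines(mid, x$fitted, col = "firebrick", lwd = 2)
  graphics::points(mid, x$reference$values, pch = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = c(x$region, "fit", x$reference$region),
                   pch = c(1, NA, 3), lty = c(NA, 1, NA),
                   col = c("black", "firebrick", "grey50"))
  invisible(x)
}
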