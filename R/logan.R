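#' Reference Logan graphical analysis
#'
#' Estimates the distribution volume ratio (DVR) as the late-time slope of
#' the reference Logan plot. Running integrals are computed by trapezoid
#' over the frame mid-times (with the origin prepended), and the ordinary
#' least-squares line of
#' `y(T) = int_0^T C_T dt / C_T(T)` on
#' `x(T) = [int_0^T C_R dt + C_R(T)/k2prime] / C_T(T)`
#' is fitted over frames with mid-time at or beyond `t_star`. The
#' `C_R/k2prime` term is omitted when `k2prime` is `NULL` (the default);
#' a scalar population efflux rate of the reference region may be supplied.
#'
#' @param target target-region [tac].
#' @param reference reference-region [tac] on the same schedule.
#' @param t_star start of the linear segment, minutes; frames with mid-time
#'   `>= t_star` enter the regression (at least 3 required).
#' @param k2prime optional reference-region efflux rate, 1/min.
#' @return An object of class `logan_fit` with `dvr` (the slope),
#'   `intercept`, `t_star`, `k2prime`, `n_points` and `r_squared`.
#'   Supports `print()`, `coef()` and `plot()`.
#' @examples
#' cp <- input_function()
#' sched <- default_schedule()
#' ref <- onetc_forward(cp, 0.45, 0.09, sched, region = "BS")
#' hc <- onetc_forward(cp, 0.45, 0.06, sched, region = "HC")
#' fit_ref_logan(hc, ref, t_star = 10)
#' @export
fit_ref_logan <- function(target, reference, t_star = 10, k2prime = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_schedule(target$schedule, reference$schedule))
    stop("target and reference must share one frame schedule")
  if (t_star < 0) stop("t_star must be nonnegative")
  if (!is.null(k2prime) && (!is.finite(k2prime) || k2prime <= 0))
    stop("k2prime must be a positive scalar or NULL")
  mid <- mid_times(target$schedule)
  int_t <- running_integral(mid, target$values)
  int_r <- running_integral(mid, reference$values)
  keep <- mid >= t_star
  if (sum(keep) < 3L)
    stop("need at least 3 frames with mid-time >= t_star")
  ct <- target$values
  degenerate <- keep & abs(ct) < 1e-10 * max(abs(ct))
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate),
            " frame(s) with near-zero target activity from the Logan plot")
    keep <- keep & !degenerate
    if (sum(keep) < 3L)
      stop("fewer than 3 usable frames remain after dropping near-zero ones")
  }
  xr <- int_r[keep] + if (is.null(k2prime)) 0 else reference$values[keep] / k2prime
  x <- xr / ct[keep]
  y <- int_t[keep] / ct[keep]
  ls <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(ls$coefficients[2L])
  r2 <- 1 - sum(ls$residuals^2) / sum((y - mean(y))^2)
  structure(list(region = target$region, dvr = slope,
                 intercept = unname(ls$coefficients[1L]), t_star = t_star,
                 k2prime = k2prime, n_points = sum(keep), r_squared = r2,
                 x = x, y = y), class = "logan_fit")
}

# Trapezoidal running integral from time 0 through each sample point.
running_integral <- function(t, v) {
  pracma::cumtrapz(c(0, t), c(0, v))[-1L]
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "Reference Logan fit, region %s (t* = %g min%s)\n  DVR (slope) = %.4f, intercept = %.4g, R^2 = %.4f, %d points\n",
    x$region, x$t_star,
    if (is.null(x$k2prime)) "" else sprintf(", k2' = %.3g", x$k2prime),
    x$dvr, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.logan_fit <- function(object, ...) {
  c(DVR = object$dvr, intercept = object$intercept)
}

#' @export
plot.logan_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "normalized reference integral",
                 ylab = "normalized target integral",
                 main = sprintf("Reference Logan: %s (DVR %.2f)",
                                x$region, x$dvr), ...)
  graphics::abline(x$intercept, x$dvr, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Fit every region of a subject scan
#'
#' Fits the SRTM (and optionally reference Logan) for every non-reference
#' region of a scan against its reference region, sharing one precomputed
#' basis across regions. The reference region itself is reported with
#' `DVR = 1` by definition. A failing region is dropped with a warning; it
#' does not abort the other regions.
#'
#' @param scan a [subject_scan].
#' @param method SRTM estimator passed to [fit_srtm()].
#' @param logan also run [fit_ref_logan()] per region.
#' @param t_star Logan linearity start, minutes.
#' @param k2prime optional Logan reference efflux term.
#' @param k2a_grid,weights,step passed to [fit_srtm()].
#' @return An object of class `subject_fits`: a list with `srtm` and
#'   (optionally) `logan` per-region fit lists plus the subject metadata.
#'   `as.data.frame()` flattens it to a per-region table; `dvrs()` extracts
#'   the named DVR vector.
#' @export
fit_subject <- function(scan, method = "bfm", logan = FALSE, t_star = 10,
                        k2prime = NULL, k2a_grid = default_k2a_grid(),
                        weights = "none", step = 0.025) {
  stopifnot(inherits(scan, "subject_scan"))
  ref_lab <- scan$reference_region
  reference <- scan$tacs[[ref_lab]]
  basis <- srtm_basis(reference, k2a_grid = k2a_grid, step = step)
  srtm_fits <- list()
  logan_fits <- list()
  for (r in setdiff(names(scan$tacs), ref_lab)) {
    srtm_fits[[r]] <- tryCatch(
      fit_srtm(scan$tacs[[r]], reference, method = method, basis = basis,
               k2a_grid = k2a_grid, weights = weights, step = step),
      error = function(e) {
        warning("SRTM fit failed for region ", r, ": ", conditionMessage(e))
        NULL
      })
    if (logan)
      logan_fits[[r]] <- tryCatch(
        fit_ref_logan(scan$tacs[[r]], reference, t_star = t_star,
                      k2prime = k2prime),
        error = function(e) {
          warning("Logan fit failed for region ", r, ": ", conditionMessage(e))
          NULL
        })
  }
  srtm_fits <- Filter(Negate(is.null), srtm_fits)
  logan_fits <- Filter(Negate(is.null), logan_fits)
  structure(list(subject_id = scan$subject_id, genotype = scan$genotype,
                 reference_region = ref_lab, srtm = srtm_fits,
                 logan = if (logan) logan_fits else NULL),
            class = "subject_fits")
}

#' @rdname fit_subject
#' @param fits a `subject_fits` object.
#' @param method_tag which estimate to extract: `"srtm"` or `"logan"`.
#' @export
dvrs <- function(fits, method_tag = c("srtm", "logan")) {
  stopifnot(inherits(fits, "subject_fits"))
  method_tag <- match.arg(method_tag)
  src <- fits[[method_tag]]
  if (is.null(src)) stop("no ", method_tag, " fits present")
  out <- vapply(src, function(f) f$dvr, numeric(1))
  c(out, stats::setNames(1, fits$reference_region))
}

#' @rdname fit_subject
#' @description `ref_k2prime()` extracts a population estimate of the
#'   reference-region efflux rate from a subject's SRTM fits — the median of
#'   `k2 / R1` across regions — suitable as the `k2prime` argument of
#'   [fit_ref_logan()].
#' @export
ref_k2prime <- function(fits) {
  stopifnot(inherits(fits, "subject_fits"))
  if (length(fits$srtm) == 0L) stop("no SRTM fits present")
  stats::median(vapply(fits$srtm, function(f) f$k2 / f$R1, numeric(1)))
}

#' @export
print.subject_fits <- function(x, ...) {
  cat(sprintf("<subject_fits> %s (%s): %d SRTM fits%s, ref %s\n",
              x$subject_id, x$genotype, length(x$srtm),
              if (!is.null(x$logan)) sprintf(" + %d Logan", length(x$logan))
              else "", x$reference_region))
  invisible(x)
}

#' @export
as.data.frame.subject_fits <- function(x, ...) {
  rows <- lapply(names(x$srtm), function(r) {
    f <- x$srtm[[r]]
    data.frame(subject = x$subject_id, genotype = x$genotype, region = r,
               R1 = f$R1, k2 = f$k2, BP_ND = f$bp, DVR = f$dvr,
               rss = f$rss, method = f$method,
               logan_dvr = if (!is.null(x$logan) && !is.null(x$logan[[r]]))
                 x$logan[[r]]$dvr else NA_real_)
  })
  ref_row <- data.frame(subject = x$subject_id, genotype = x$genotype,
                        region = x$reference_region, R1 = 1, k2 = NA_real_,
                        BP_ND = 0, DVR = 1, rss = 0, method = "reference",
                        logan_dvr = if (!is.null(x$logan)) 1 else NA_real_)
  do.call(rbind, c(rows, list(ref_row)))
}
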