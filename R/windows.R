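#' Static imaging window
#'
#' @param start,end window bounds in minutes post-injection,
#'   `0 <= start < end`.
#' @return An object of class `pet_window`.
#' @export
pet_window <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) || start < 0 || end <= start)
    stop("window must satisfy 0 <= start < end")
  structure(list(start = start, end = end), class = "pet_window")
}

#' @export
print.pet_window <- function(x, ...) {
  cat(sprintf("<pet_window> %g-%g min\n", x$start, x$end))
  invisible(x)
}

#' @export
format.pet_window <- function(x, ...) sprintf("%g-%g", x$start, x$end)

#' Windowed SUV of a TAC
#'
#' Duration-weighted mean of the frame values over a static window: every
#' frame whose intersection with the window has positive length contributes
#' its value weighted by the intersection length, so windows need not align
#' with frame boundaries.
#'
#' @param tac a [tac].
#' @param window a [pet_window] overlapping the schedule.
#' @return Scalar windowed mean activity.
#' @examples
#' fs <- frame_schedule(c(60, 70), c(70, 90))
#' window_suv(tac(fs, c(2, 1), "HC"), pet_window(60, 90)) # 4/3
#' @export
window_suv <- function(tac, window) {
  stopifnot(inherits(tac, "tac"), inherits(window, "pet_window"))
  w <- pmax(0, pmin(tac$schedule$end, window$end) -
               pmax(tac$schedule$start, window$start))
  if (sum(w) <= 0)
    stop("window ", format(window), " min does not overlap the schedule")
  sum(w * tac$values) / sum(w)
}

#' Regional SUVRs of a scan over a static window
#'
#' Windowed SUV of every region divided by the windowed SUV of the scan's
#' reference region. The reference region's SUVR is exactly 1, and the
#' ratio is invariant to any global rescaling of the TACs (so kBq/mL and
#' SUV inputs give identical SUVRs).
#'
#' @param scan a [subject_scan].
#' @param window a [pet_window].
#' @return An object of class `suvr_table`: named SUVR vector plus subject
#'   metadata. `as.data.frame()` gives a long-format table.
#' @export
compute_suvr <- function(scan, window) {
  stopifnot(inherits(scan, "subject_scan"))
  ref_suv <- window_suv(scan$tacs[[scan$reference_region]], window)
  if (ref_suv <= 0)
    stop("non-positive reference-region uptake in window ", format(window))
  suvr <- vapply(scan$tacs, window_suv, numeric(1), window = window) / ref_suv
  suvr[scan$reference_region] <- 1
  structure(list(subject_id = scan$subject_id, genotype = scan$genotype,
                 window = window, reference_region = scan$reference_region,
                 suvr = suvr),
            class = "suvr_table")
}

#' @export
print.suvr_table <- function(x, ...) {
  cat(sprintf("<suvr_table> %s (%s), window %s min, ref %s\n",
              x$subject_id, x$genotype, format(x$window),
              x$reference_region))
  print(round(x$suvr, 3))
  invisible(x)
}

#' @export
as.data.frame.suvr_table <- function(x, ...) {
  data.frame(subject = x$subject_id, genotype = x$genotype,
             window_start = x$window$start, window_end = x$window$end,
             region = names(x$suvr), suvr = unname(x$suvr),
             row.names = NULL)
}

#' SUVR-versus-DVR agreement over a cohort
#'
#' Pools (subject, region) pairs across a cohort — excluding the reference
#' region, where both quantities are identically 1 — and quantifies how well
#' windowed SUVRs agree with kinetic-model DVRs: the ordinary least-squares
#' line of SUVR on DVR (slope, intercept, R^2) and the first two moments of
#' the percent difference `100 (SUVR - DVR) / DVR`.
#'
#' @param suvr_tables list of [compute_suvr()] results, one per subject,
#'   all for the same window.
#' @param fits list of [fit_subject()] results (or named DVR vectors) with
#'   matching subjects and regions.
#' @return An object of class `agreement_stats` with `slope`, `intercept`,
#'   `r_squared`, `mean_pct_diff`, `sd_pct_diff`, `n_pairs`, `window` and
#'   the pooled pairs.
#' @export
suvr_dvr_agreement <- function(suvr_tables, fits) {
  if (length(suvr_tables) < 1L) stop("no SUVR tables supplied")
  stopifnot(all(vapply(suvr_tables, inherits, logical(1), "suvr_table")))
  dvr_list <- lapply(fits, function(f)
    if (inherits(f, "subject_fits")) dvrs(f) else f)
  ids_s <- vapply(suvr_tables, function(s) s$subject_id, character(1))
  ids_f <- if (!is.null(names(fits)) && all(nzchar(names(fits)))) names(fits)
           else vapply(fits, function(f) f$subject_id, character(1))
  names(dvr_list) <- ids_f
  missing <- setdiff(ids_s, ids_f)
  if (length(missing) > 0L)
    stop("no DVR fits for subject(s): ", paste(missing, collapse = ", "))

  pairs <- do.call(rbind, lapply(suvr_tables, function(s) {
    dvr <- dvr_list[[s$subject_id]]
    regs <- setdiff(intersect(names(s$suvr), names(dvr)),
                    s$reference_region)
    lost <- setdiff(setdiff(names(s$suvr), s$reference_region), names(dvr))
    if (length(lost) > 0L)
      stop("subject ", s$subject_id, ": region(s) without DVR: ",
           paste(lost, collapse = ", "))
    data.frame(subject = s$subject_id, region = regs,
               suvr = unname(s$suvr[regs]), dvr = unname(dvr[regs]))
  }))
  if (nrow(pairs) < 3L) stop("need at least 3 pooled (subject, region) pairs")

  ls <- stats::lm.fit(cbind(1, pairs$dvr), pairs$suvr)
  r2 <- 1 - sum(ls$residuals^2) / sum((pairs$suvr - mean(pairs$suvr))^2)
  pct <- 100 * (pairs$suvr - pairs$dvr) / pairs$dvr
  structure(list(window = suvr_tables[[1L]]$window,
                 slope = unname(ls$coefficients[2L]),
                 intercept = unname(ls$coefficients[1L]),
                 r_squared = r2, mean_pct_diff = mean(pct),
                 sd_pct_diff = stats::sd(pct), n_pairs = nrow(pairs),
                 pairs = pairs),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "SUVR-DVR agreement, window %s min (%d pairs)\n  SUVR = %.3f x DVR %+.3f, R^2 = %.3f\n  pct diff (SUVR vs DVR): %.1f +/- %.1f %%\n",
    format(x$window), x$n_pairs, x$slope, x$intercept, x$r_squared,
    x$mean_pct_diff, x$sd_pct_diff))
  invisible(x)
}

#' Select the optimal static imaging window
#'
#' Computes SUVR-versus-DVR agreement for each candidate window over a
#' cohort and ranks the windows by smallest absolute mean percent
#' difference, breaking ties by higher R^2 and then toward the later
#' window.
#'
#' @param candidates list of [pet_window] candidates (>= 1).
#' @param scans list of [subject_scan] objects.
#' @param fits list of [fit_subject()] results for the same subjects.
#' @return A list of class `window_selection`: `best` (the chosen
#'   [pet_window]), `ranking` (data frame ordered best first) and
#'   `agreement` (per-window `agreement_stats`).
#' @export
select_window <- function(candidates, scans, fits) {
  if (length(candidates) < 1L) stop("at least one candidate window required")
  stopifnot(all(vapply(candidates, inherits, logical(1), "pet_window")))
  ag <- lapply(candidates, function(w)
    suvr_dvr_agreement(lapply(scans, compute_suvr, window = w), fits))
  tab <- data.frame(
    window = vapply(ag, function(a) format(a$window), character(1)),
    window_start = vapply(ag, function(a) a$window$start, numeric(1)),
    window_end = vapply(ag, function(a) a$window$end, numeric(1)),
    slope = vapply(ag, function(a) a$slope, numeric(1)),
    intercept = vapply(ag, function(a) a$intercept, numeric(1)),
    r_squared = vapply(ag, function(a) a$r_squared, numeric(1)),
    mean_pct_diff = vapply(ag, function(a) a$mean_pct_diff, numeric(1)),
    sd_pct_diff = vapply(ag, function(a) a$sd_pct_diff, numeric(1)))
  ord <- order(abs(tab$mean_pct_diff), -tab$r_squared, -tab$window_start)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(best = candidates[[ord[1L]]], ranking = tab,
                 agreement = ag[ord]),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat("Selected static window:", format(x$best), "min\n")
  print(x$ranking[, c("window", "slope", "intercept", "r_squared",
                      "mean_pct_diff", "sd_pct_diff")], digits = 3)
  invisible(x)
}
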