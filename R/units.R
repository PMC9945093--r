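#' SUV conversion
#'
#' Converts a concentration TAC (kBq/mL) to standardized uptake value,
#' SUV = C \[kBq/mL\] x body weight \[g\] / (injected activity \[MBq\] x 1000),
#' under the usual 1 g/mL tissue-density convention. `from_suv()` is the
#' algebraic inverse.
#'
#' @param tac a [tac] in kBq/mL (for `to_suv`) or SUV (for `from_suv`).
#' @param injected_activity injected activity in MBq (decay-corrected to
#'   injection time).
#' @param body_weight body weight in grams.
#' @return A [tac] in the converted units; the schedule is unchanged.
#' @examples
#' fs <- frame_schedule(c(0, 1), c(1, 2))
#' t_kbq <- tac(fs, c(100, 50), "HC")
#' to_suv(t_kbq, injected_activity = 10, body_weight = 25)$values # 0.25 0.125
#' @export
to_suv <- function(tac, injected_activity, body_weight) {
  stopifnot(inherits(tac, "tac"))
  if (tac$units == "SUV")
    stop("unit mismatch: TAC is already in SUV")
  check_dose_weight(injected_activity, body_weight)
  out <- tac
  out$values <- tac$values * body_weight / (injected_activity * 1000)
  out$units <- "SUV"
  out
}

#' @rdname to_suv
#' @export
from_suv <- function(tac, injected_activity, body_weight) {
  stopifnot(inherits(tac, "tac"))
  if (tac$units != "SUV")
    stop("unit mismatch: TAC is not in SUV")
  check_dose_weight(injected_activity, body_weight)
  out <- tac
  out$values <- tac$values * injected_activity * 1000 / body_weight
  out$units <- "kBq/mL"
  out
}

check_dose_weight <- function(injected_activity, body_weight) {
  if (!is.numeric(injected_activity) || length(injected_activity) != 1L ||
      !is.finite(injected_activity) || injected_activity <= 0)
    stop("invalid metadata: injected_activity must be a positive scalar (MBq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("invalid metadata: body_weight must be a positive scalar (g)")
  invisible(TRUE)
}

#' Convert every TAC of a scan to SUV
#'
#' @param scan a [subject_scan] whose TACs are in kBq/mL.
#' @return The scan with all TACs in SUV.
#' @export
scan_to_suv <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  scan$tacs <- lapply(scan$tacs, to_suv,
                      injected_activity = scan$injected_activity,
                      body_weight = scan$body_weight)
  scan
}

#' Radioactive decay correction
#'
#' Rescales per-frame activity to a common reference time using the physical
#' half-life: value(i) * 2^((mid_time(i) - reference_time) / half_life).
#' With the default `reference_time = 0` this corrects frame activities back
#' to injection time.
#'
#' @param values numeric activity per frame.
#' @param schedule a [frame_schedule].
#' @param half_life physical half-life in minutes (> 0).
#' @param reference_time time the values are corrected to, minutes.
#' @return Numeric vector of corrected values.
#' @examples
#' fs <- frame_schedule(c(0, 100), c(19.54, 119.54))
#' decay_correct(c(1, 1), fs, half_life = 109.77)
#' @export
decay_correct <- function(values, schedule, half_life, reference_time = 0) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.finite(half_life) || half_life <= 0)
    stop("half_life must be positive")
  lambda <- log(2) / half_life
  values * exp(lambda * (mid_times(schedule) - reference_time))
}
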