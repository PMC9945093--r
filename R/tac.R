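#' Regional time-activity curve
#'
#' A time-activity curve (TAC) holds one decay-corrected activity value per
#' frame for a single brain region, either in concentration units (kBq/mL)
#' or dose/weight-normalized standardized uptake value (SUV).
#'
#' @param schedule a [frame_schedule].
#' @param values numeric vector, one activity value per frame.
#' @param region region label (e.g. `"HC"`).
#' @param units `"kBq/mL"` or `"SUV"`.
#' @param noisy logical; `TRUE` marks curves carrying an additive noise
#'   realisation, which are permitted to dip below zero.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region, units = c("kBq/mL", "SUV"),
                noisy = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule))
    stop("values length (", length(values), ") must equal frame count (",
         n_frames(schedule), ")")
  if (any(!is.finite(values)))
    stop("TAC values must be finite")
  if (!noisy && any(values < 0))
    stop("negative activity in a noiseless TAC; pass noisy = TRUE for ",
         "noise realisations")
  structure(list(schedule = schedule, values = values,
                 region = as.character(region), units = units,
                 noisy = isTRUE(noisy)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region %s, %s [%s]%s, peak %.3g at %.1f min\n",
              x$region, format(x$schedule), x$units,
              if (x$noisy) " (noisy)" else "",
              max(x$values), x$schedule$mid[which.max(x$values)]))
  invisible(x)
}

#' Canonical brain region set
#'
#' The eleven atlas regions quantified for mouse-brain SV2A PET, with their
#' integer atlas codes: brain stem (BS), cerebellum (CB), cingulate cortex
#' (CCX), cortex (CX), hippocampus (HC), inferior colliculi (IC), mid brain
#' (MB), striatum (ST), superior colliculi (SC), thalamus (TH) and whole
#' brain (WB). The whole brain is the union of the other regions, not a
#' separate atlas mask.
#'
#' @param labels character vector of region labels.
#' @param codes positive integer atlas codes, one per label (WB carries a
#'   conventional code but is resolved as the union of the others during
#'   ROI extraction).
#' @return An object of class `region_set`.
#' @export
region_set <- function(labels = c("BS", "CB", "CCX", "CX", "HC", "IC",
                                  "MB", "ST", "SC", "TH", "WB"),
                       codes = seq_along(labels)) {
  labels <- as.character(labels)
  codes <- as.integer(codes)
  if (length(labels) != length(codes))
    stop("labels and codes must have equal length")
  if (anyDuplicated(labels))
    stop("region labels must be unique")
  if (anyDuplicated(codes))
    stop("atlas codes must be unique")
  if (any(codes <= 0L))
    stop("atlas codes must be positive integers")
  structure(list(labels = labels, codes = stats::setNames(codes, labels)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' One animal's scan: regional TACs plus metadata
#'
#' Bundles all regional TACs of one dynamic scan with the dose, weight and
#' genotype metadata needed for SUV conversion and group analysis. All TACs
#' must share a single frame schedule and the reference region must be among
#' them.
#'
#' @param subject_id subject identifier.
#' @param genotype `"WT"` or `"APP/PS1"`.
#' @param injected_activity injected activity in MBq, decay-corrected to
#'   injection time.
#' @param body_weight body weight in grams.
#' @param tacs named list of [tac] objects (names are region labels).
#' @param reference_region label of the (pseudo) reference region,
#'   default `"BS"`.
#' @param tracer tracer name (free text).
#' @param half_life tracer physical half-life in minutes (default F-18,
#'   109.77 min).
#' @param injected_mass optional injected tracer mass (microgram/kg), used by
#'   [mass_association()].
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, genotype = c("WT", "APP/PS1"),
                         injected_activity, body_weight, tacs,
                         reference_region = "BS", tracer = "F18-tracer",
                         half_life = 109.77, injected_mass = NA_real_) {
  genotype <- match.arg(genotype)
  if (!is.list(tacs) || length(tacs) == 0L || is.null(names(tacs)))
    stop("tacs must be a non-empty named list of tac objects")
  if (!all(vapply(tacs, inherits, logical(1), "tac")))
    stop("every element of tacs must be a tac object")
  regions <- vapply(tacs, function(t) t$region, character(1))
  if (!identical(unname(regions), names(tacs)))
    stop("tac list names must match the region label of each TAC")
  if (!(reference_region %in% names(tacs)))
    stop("reference region '", reference_region, "' not present in tacs")
  sched <- tacs[[1L]]$schedule
  ok <- vapply(tacs, function(t) same_schedule(t$schedule, sched), logical(1))
  if (!all(ok))
    stop("all TACs of a scan must share one frame schedule")
  if (!is.finite(injected_activity) || injected_activity <= 0)
    stop("injected_activity must be positive (MBq)")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be positive (g)")
  if (!is.finite(half_life) || half_life <= 0)
    stop("half_life must be positive (minutes)")
  structure(list(subject_id = as.character(subject_id), genotype = genotype,
                 injected_activity = injected_activity,
                 body_weight = body_weight, tracer = as.character(tracer),
                 half_life = half_life, tacs = tacs,
                 reference_region = reference_region,
                 injected_mass = injected_mass,
                 schedule = sched),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s (%s): %d regions [%s], ref %s, %s\n",
              x$subject_id, x$genotype, length(x$tacs),
              x$tacs[[1L]]$units, x$reference_region, format(x$schedule)))
  invisible(x)
}

#' Regions of a subject scan
#' @param scan a [subject_scan].
#' @return Character vector of region labels.
#' @export
scan_regions <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  names(scan$tacs)
}
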