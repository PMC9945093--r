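#' Read and write TAC tables
#'
#' A subject's regional TACs travel as a CSV table with header
#' `frame_start_min,frame_end_min,<region1>,<region2>,...`, one row per
#' frame, accompanied by a JSON sidecar `<stem>.meta.json` holding
#' `subject_id`, `genotype`, `injected_activity_MBq`, `body_weight_g`,
#' `tracer`, `half_life_min`, `units` ("kBq/mL" or "SUV") and
#' `reference_region` (plus optional `injected_mass_ugkg` and `noisy`).
#' Values are printed with 9 significant digits, so a write/read round trip
#' reproduces the numbers bit-for-bit.
#'
#' @param path CSV file path; the sidecar path is derived by replacing the
#'   `.csv` extension with `.meta.json`.
#' @param scan a [subject_scan].
#' @return `read_tacs()` returns a [subject_scan]; `write_tacs()` returns
#'   `path` invisibly.
#' @export
read_tacs <- function(path) {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("subject_id", "genotype", "injected_activity_MBq",
                "body_weight_g", "tracer", "half_life_min", "units",
                "reference_region")
  absent <- setdiff(required, names(meta))
  if (length(absent) > 0L)
    stop("sidecar missing required field(s): ", paste(absent, collapse = ", "))
  if (!(meta$units %in% c("kBq/mL", "SUV")))
    stop("unknown units in sidecar: '", meta$units, "'")

  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 3L ||
      !identical(names(tab)[1:2], c("frame_start_min", "frame_end_min")))
    stop("TAC table must start with columns frame_start_min, frame_end_min")
  sched <- frame_schedule(tab$frame_start_min, tab$frame_end_min)
  region_cols <- names(tab)[-(1:2)]
  noisy <- isTRUE(meta$noisy)
  tacs <- lapply(region_cols, function(r)
    tac(sched, tab[[r]], region = r, units = meta$units, noisy = noisy))
  names(tacs) <- region_cols
  subject_scan(subject_id = meta$subject_id, genotype = meta$genotype,
               injected_activity = meta$injected_activity_MBq,
               body_weight = meta$body_weight_g, tacs = tacs,
               reference_region = meta$reference_region,
               tracer = meta$tracer, half_life = meta$half_life_min,
               injected_mass = if (is.null(meta$injected_mass_ugkg))
                 NA_real_ else meta$injected_mass_ugkg)
}

#' @rdname read_tacs
#' @export
write_tacs <- function(scan, path) {
  stopifnot(inherits(scan, "subject_scan"))
  sched <- scan$schedule
  tab <- data.frame(frame_start_min = fmt9(sched$start),
                    frame_end_min = fmt9(sched$end),
                    check.names = FALSE)
  for (r in names(scan$tacs)) tab[[r]] <- fmt9(scan$tacs[[r]]$values)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = scan$subject_id, genotype = scan$genotype,
               injected_activity_MBq = scan$injected_activity,
               body_weight_g = scan$body_weight, tracer = scan$tracer,
               half_life_min = scan$half_life,
               units = scan$tacs[[1L]]$units,
               reference_region = scan$reference_region,
               noisy = any(vapply(scan$tacs, function(t) t$noisy, logical(1))))
  if (is.finite(scan$injected_mass))
    meta$injected_mass_ugkg <- scan$injected_mass
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".meta.json", path)

# 9 significant digits: enough for a bit-identical numeric round trip of
# values produced at double precision from single-precision-scale PET data
fmt9 <- function(x) formatC(x, digits = 9, format = "g")
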