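#' Extract regional TACs from a dynamic volume and a label atlas
#'
#' Computes, for every region in `regions`, the unweighted mean voxel value
#' per frame over the voxels carrying that region's atlas code. The whole
#' brain ("WB", when present in `regions`) is the mean over the union of all
#' other listed region codes rather than a code of its own. No
#' partial-volume correction is applied.
#'
#' @param image 4D numeric array (x, y, z, frame) or a path to a 4D NIfTI
#'   file (read with the RNifti package).
#' @param atlas 3D integer label array with the same spatial dimensions, or
#'   a path to a NIfTI label volume.
#' @param regions a [region_set].
#' @param schedule a [frame_schedule] with one frame per image volume
#'   (NIfTI stores no frame durations, so the schedule is always supplied
#'   separately).
#' @param units units of the image values.
#' @return Named list of [tac] objects, one per region.
#' @export
extract_roi_tacs <- function(image, atlas, regions, schedule,
                             units = "kBq/mL") {
  stopifnot(inherits(regions, "region_set"), inherits(schedule, "frame_schedule"))
  if (is.character(image)) image <- read_nifti_array(image)
  if (is.character(atlas)) atlas <- read_nifti_array(atlas)
  if (length(dim(image)) != 4L)
    stop("image must be a 4D array (x, y, z, frame)")
  atlas <- as.array(atlas)
  if (!identical(dim(image)[1:3], dim(atlas)[1:3]))
    stop("atlas spatial dimensions must match the image")
  nf <- dim(image)[4L]
  if (nf != n_frames(schedule))
    stop("schedule has ", n_frames(schedule), " frames but image has ", nf)
  atlas_vec <- as.integer(round(atlas))
  nvox <- length(atlas_vec)
  mat <- matrix(image, nrow = nvox, ncol = nf)  # voxels x frames

  wb_label <- "WB"
  plain <- setdiff(regions$labels, wb_label)
  missing <- plain[!(regions$codes[plain] %in% atlas_vec)]
  if (length(missing) > 0L)
    stop("region code(s) not found in atlas: ",
         paste(sprintf("%s (%d)", missing, regions$codes[missing]),
               collapse = ", "))

  out <- list()
  for (lab in plain) {
    sel <- atlas_vec == regions$codes[[lab]]
    out[[lab]] <- tac(schedule, colMeans(mat[sel, , drop = FALSE]),
                      region = lab, units = units)
  }
  if (wb_label %in% regions$labels) {
    sel <- atlas_vec %in% regions$codes[plain]
    out[[wb_label]] <- tac(schedule, colMeans(mat[sel, , drop = FALSE]),
                           region = wb_label, units = units)
  }
  out
}

read_nifti_array <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI files requires the RNifti package")
  as.array(RNifti::readNifti(path))
}
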