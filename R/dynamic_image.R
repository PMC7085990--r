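#' 4D dynamic PET image
#'
#' In-memory container for a dynamic acquisition: a 4D array of
#' decay-corrected activity concentrations (x, y, z, frame) in kBq/mL, its
#' frame schedule, and the voxel size in mm.
#'
#' @param data 4D numeric array; the 4th axis must match the schedule length.
#' @param schedule a [frame_schedule()].
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_mm = c(3.9, 3.9, 3.27)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(data)
  if (length(d) != 4) stop("data must be a 4D array (x, y, z, frame)")
  if (d[4] != schedule$n) stop("frame axis length must equal schedule length")
  if (any(!is.finite(data))) stop("image values must be finite")
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0)) stop("voxel_mm must be 3 positive values")
  structure(list(data = data, schedule = schedule,
                 voxel_mm = as.numeric(voxel_mm)),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d frames over %.3g min\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              d[4], x$schedule$end[x$schedule$n]))
  invisible(x)
}

#' Mean time-activity curve over a labelled region
#'
#' @param dyn a [dynamic_image()].
#' @param labels 3D integer label array matching the image geometry.
#' @param label region label to average over.
#' @return A [time_activity_curve()] of the region-mean values.
#' @export
voi_tac <- function(dyn, labels, label) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  if (!identical(dim(labels), d[1:3])) stop("labels geometry must match the image")
  sel <- which(labels == label)
  if (length(sel) == 0) stop("empty label: ", label)
  M <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4])
  time_activity_curve(dyn$schedule, colMeans(M[sel, , drop = FALSE]))
}
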