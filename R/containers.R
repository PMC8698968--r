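# Lightweight S3 containers for volumetric inputs. Velocities are stored
# in cm/s (the phase-contrast convention); geometry is in world mm with
# voxel centers at (index - 1) * spacing + origin.

#' Time-resolved three-component velocity field
#'
#' @param frames list (length n_frames) of lists of three 3D arrays
#'   (vx, vy, vz), velocities in cm/s.
#' @param spacing voxel spacing (mm), length 3.
#' @param origin world coordinate of the first voxel center (mm).
#' @param frame_times acquisition time of each frame (ms).
#' @param units velocity unit string (only `"cm/s"` is produced).
#' @return object of class `velocity_field`
#' @export
velocity_field <- function(frames, spacing, origin = c(0, 0, 0),
                           frame_times = NULL, units = "cm/s") {
  stopifnot(length(frames) >= 1, length(spacing) == 3, all(spacing > 0))
  d <- dim(frames[[1]][[1]])
  for (fr in frames) {
    stopifnot(length(fr) == 3)
    for (comp in fr) stopifnot(identical(dim(comp), d))
  }
  if (is.null(frame_times)) frame_times <- seq_along(frames) - 1
  structure(list(frames = frames, spacing = spacing, origin = origin,
                 dim = d, n_frames = length(frames),
                 frame_times = frame_times, units = units),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field:", paste(x$dim, collapse = " x "),
      "voxels,", x$n_frames, "frames, spacing",
      paste(signif(x$spacing, 3), collapse = "/"), "mm,", x$units, "\n")
  invisible(x)
}

#' Time-resolved binary lumen segmentation
#'
#' @param data 3D integer/logical array (static mask) or list of 3D arrays
#'   (one per frame). Nonzero marks lumen.
#' @param spacing voxel spacing (mm), length 3.
#' @param origin world coordinate of the first voxel center (mm).
#' @param branch_flags optional array of the same shape marking branch
#'   ostium voxels to exclude from volume / wall analysis.
#' @return object of class `lumen_mask`
#' @export
lumen_mask <- function(data, spacing, origin = c(0, 0, 0),
                       branch_flags = NULL) {
  frames <- if (is.list(data)) data else list(data)
  d <- dim(frames[[1]])
  stopifnot(length(d) == 3, length(spacing) == 3, all(spacing > 0))
  frames <- lapply(frames, function(m) {
    stopifnot(identical(dim(m), d))
    array(as.integer(m != 0), d)
  })
  structure(list(frames = frames, spacing = spacing, origin = origin,
                 dim = d, n_frames = length(frames),
                 branch_flags = branch_flags),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat("lumen_mask:", paste(x$dim, collapse = " x "), "voxels,",
      x$n_frames, "frame(s),",
      sum(x$frames[[1]]), "lumen voxels in frame 1\n")
  invisible(x)
}

#' Time-averaged occupancy of a lumen mask (values in [0, 1])
#' @param mask a [lumen_mask()]
#' @return 3D numeric array
#' @export
mask_average <- function(mask) {
  stopifnot(inherits(mask, "lumen_mask"))
  Reduce(`+`, mask$frames) / mask$n_frames
}
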