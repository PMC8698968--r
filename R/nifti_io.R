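# NIfTI reading/writing for velocity fields (5D: x, y, z, time, component)
# and lumen masks (3D or 4D). Voxel spacing travels in the pixdim header;
# velocities are stored in cm/s.

#' Write a velocity field to a 5D NIfTI file
#'
#' Dimensions are (x, y, z, frame, component) with the three velocity
#' components in the fifth dimension; spacing is recorded in the header.
#'
#' @param velocity a [velocity_field()]
#' @param path output file (`.nii` or `.nii.gz`)
#' @export
write_velocity <- function(velocity, path) {
  stopifnot(inherits(velocity, "velocity_field"))
  d <- velocity$dim
  arr <- array(0, c(d, velocity$n_frames, 3))
  for (k in seq_len(velocity$n_frames))
    for (c in 1:3) arr[, , , k, c] <- velocity$frames[[k]][[c]]
  img <- RNifti::asNifti(arr)
  dt <- if (velocity$n_frames > 1) diff(velocity$frame_times)[1] else 1
  RNifti::pixdim(img) <- c(velocity$spacing, dt, 1)  # one value per dim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a velocity field from a 5D NIfTI file
#'
#' @param path NIfTI file with dimensions (x, y, z, frame, component);
#'   exactly 3 components are required.
#' @param origin world coordinate of the first voxel center (mm).
#' @param frame_times optional frame times (ms); defaults to the header's
#'   temporal step.
#' @return a [velocity_field()]
#' @export
read_velocity <- function(path, origin = c(0, 0, 0), frame_times = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 5 || d[5] != 3)
    stop("expected a 5D NIfTI with 3 velocity components in dimension 5, got dims: ",
         paste(d, collapse = " x "))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("velocity NIfTI is missing positive voxel spacing in its header")
  arr <- as.array(img)
  dt <- RNifti::pixdim(img)[4]
  if (is.null(frame_times))
    frame_times <- (seq_len(d[4]) - 1) * (if (is.finite(dt) && dt > 0) dt else 1)
  frames <- lapply(seq_len(d[4]), function(k)
    lapply(1:3, function(c) arr[, , , k, c]))
  velocity_field(frames, spacing = spacing, origin = origin,
                 frame_times = frame_times)
}

#' Write a lumen mask to NIfTI (3D if static, 4D if time-resolved)
#' @param mask a [lumen_mask()]
#' @param path output file
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lumen_mask"))
  arr <- if (mask$n_frames == 1) {
    mask$frames[[1]]
  } else {
    a <- array(0L, c(mask$dim, mask$n_frames))
    for (k in seq_len(mask$n_frames)) a[, , , k] <- mask$frames[[k]]
    a
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(mask$spacing, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lumen mask from a 3D or 4D NIfTI file
#' @param path NIfTI file; nonzero voxels mark lumen
#' @param origin world coordinate of the first voxel center (mm)
#' @return a [lumen_mask()]
#' @export
read_mask <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("mask NIfTI is missing positive voxel spacing in its header")
  arr <- as.array(img)
  data <- if (length(d) == 3) arr else
    lapply(seq_len(d[4]), function(k) arr[, , , k])
  lumen_mask(data, spacing = spacing, origin = origin)
}
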