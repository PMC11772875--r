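#' Multi-channel 3D(+time) image stack
#'
#' The canonical in-memory image container. Data are stored as a 5-D numeric
#' array with dimensions ordered `(T, C, Z, Y, X)`; physical voxel sizes are
#' carried as a `(z, y, x)` vector in micrometres. Voxel indices are 1-based
#' in R; the physical coordinate of voxel `i` along an axis with pitch `h` is
#' `(i - 0.5) * h` (voxel centers). On disk the canonical dtype is unsigned
#' 16-bit; in memory everything is numeric.
#'
#' @param data numeric array. Dimensions `(T, C, Z, Y, X)`; lower-dimensional
#'   arrays are promoted by inserting singleton `T`/`C` axes on the left.
#' @param voxel_size_um numeric length-3, voxel pitch `(z, y, x)` in um.
#' @param frame_interval_s time between frames in seconds, or `NA` for
#'   single-timepoint stacks.
#' @param channel_roles character vector naming the role of each channel;
#'   one of `"condensate"`, `"organelle"`, `"spot_5utr"`, `"spot_3utr"`,
#'   `"other"`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size_um, frame_interval_s = NA_real_,
                        channel_roles = NULL) {
  d <- dim(data)
  if (is.null(d)) stop("`data` must be an array")
  if (length(d) == 3) dim(data) <- c(1L, 1L, d)
  else if (length(d) == 4) dim(data) <- c(1L, d)
  else if (length(d) != 5) stop("`data` must have 3, 4 or 5 dimensions")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 strictly positive values (z, y, x)")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  nc <- dim(data)[2]
  if (is.null(channel_roles)) channel_roles <- rep("other", nc)
  if (length(channel_roles) != nc)
    stop("channel_roles declares ", length(channel_roles),
         " channels but data has ", nc)
  ok <- c("condensate", "organelle", "spot_5utr", "spot_3utr", "other")
  if (!all(channel_roles %in% ok))
    stop("unknown channel role(s): ",
         paste(setdiff(channel_roles, ok), collapse = ", "))
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_roles = channel_roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> T=%d C=%d Z=%d Y=%d X=%d\n", d[1], d[2], d[3],
              d[4], d[5]))
  cat(sprintf("  voxel size (z,y,x): %s um\n",
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  if (!is.na(x$frame_interval_s))
    cat(sprintf("  frame interval: %g s\n", x$frame_interval_s))
  cat("  channel roles:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Extract one 3D volume (Z, Y, X) from a stack
#'
#' @param stack an [image_stack].
#' @param frame 1-based time index.
#' @param channel 1-based channel index, or a role name (must be unique).
#' @return numeric 3-D array `(Z, Y, X)`.
#' @export
get_volume <- function(stack, channel, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- resolve_channel(stack, channel)
  d <- dim(stack$data)
  if (frame < 1 || frame > d[1]) stop("frame out of range")
  v <- stack$data[frame, channel, , , , drop = FALSE]
  dim(v) <- d[3:5]
  v
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    hit <- which(stack$channel_roles == channel)
    if (length(hit) == 0) stop("no channel with role '", channel, "'")
    if (length(hit) > 1) stop("role '", channel, "' is ambiguous")
    return(hit)
  }
  channel <- as.integer(channel)
  if (channel < 1 || channel > dim(stack$data)[2]) stop("channel out of range")
  channel
}

# physical centers (um) of 1-based voxel indices along (z, y, x)
voxel_centers_um <- function(idx_zyx, voxel_size_um) {
  sweep(idx_zyx - 0.5, 2, voxel_size_um, `*`)
}
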