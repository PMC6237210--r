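#' Multi-channel time-lapse image stack
#'
#' Container for a T x C x Y x X array of nonnegative intensities with named
#' channels and physical metadata. This is the common currency of the
#' pipeline: the simulator produces one, segmentation and the resorption
#' index consume its channels.
#'
#' @param data Numeric array with dimensions T x C x Y x X (frames, channels,
#'   rows, columns). All intensities must be >= 0.
#' @param channels Character vector of channel names, one per channel, e.g.
#'   `c("reporter", "ph_probe", "bone")`.
#' @param pixel_size Pixel edge length in micrometres.
#' @param frame_interval Time between frames in minutes.
#'
#' @return An object of class `image_stack`: a list with elements `data`,
#'   `channels`, `pixel_size`, `frame_interval`.
#' @export
#' @examples
#' arr <- array(runif(2 * 1 * 8 * 8), c(2, 1, 8, 8))
#' stk <- image_stack(arr, channels = "reporter")
#' n_frames(stk)
image_stack <- function(data, channels, pixel_size = 1, frame_interval = 1) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4-dimensional T x C x Y x X array.")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    abort("All intensities must be finite and >= 0.")
  }
  channels <- as.character(channels)
  if (length(channels) != dim(data)[2L]) {
    abort(sprintf(
      "Channel count mismatch: %d names for %d channels.",
      length(channels), dim(data)[2L]
    ))
  }
  if (dim(data)[1L] < 1L) abort("Stack must contain at least one frame.")
  if (anyDuplicated(channels)) abort("Channel names must be unique.")
  structure(
    list(
      data = data, channels = channels,
      pixel_size = pixel_size, frame_interval = frame_interval
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d frame(s) x %d channel(s) x %d x %d px\n",
    d[1], d[2], d[3], d[4]
  ))
  cat("  channels:      ", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  pixel size:     %g um;  frame interval: %g min\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$data)[1L]
}

#' Extract one channel frame as a Y x X matrix
#'
#' @param stack An `image_stack`.
#' @param channel Channel name or index.
#' @param frame Frame index (1-based).
#' @return A Y x X numeric matrix.
#' @export
get_frame <- function(stack, channel, frame) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) {
      abort(sprintf(
        "Unknown channel '%s'. Available: %s.",
        channel, paste(stack$channels, collapse = ", ")
      ))
    }
  } else {
    ci <- as.integer(channel)
  }
  t <- as.integer(frame)
  if (t < 1L || t > dim(stack$data)[1L]) abort("Frame index out of range.")
  stack$data[t, ci, , , drop = TRUE]
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are written frame-major, channel-minor (frame 1 channel 1, frame 1
#' channel 2, ...). Dimensions, channel names and physical metadata go to a
#' `<path>.json` sidecar so [read_stack_tiff()] can round-trip the object.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- stack$data[t, c, , ] / mx
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(
      n_frames = d[1], channels = stack$channels,
      height = d[3], width = d[4],
      pixel_size = stack$pixel_size, frame_interval = stack$frame_interval,
      intensity_scale = mx
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must be present.
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("Missing sidecar '%s'.", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$n_frames
  nc <- length(meta$channels)
  arr <- array(0, c(nt, nc, meta$height, meta$width))
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      arr[t, c, , ] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  image_stack(arr, meta$channels,
    pixel_size = meta$pixel_size, frame_interval = meta$frame_interval
  )
}
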