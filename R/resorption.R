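#' Bone-resorbing index of one frame
#'
#' Ratio of the mean pH-probe intensity inside the binarized osteoclast
#' areas (the probe signal) to the mean intensity outside them (the probe
#' noise). An index near 1 means no detectable acidification. To keep
#' boundary bleed-through out of the noise estimate, the mask is dilated by
#' `exclusion_ring` pixels before defining the outside region; a ring of 0
#' reproduces the literal inside/outside definition.
#'
#' @param ph_channel Y x X matrix of pH-probe intensities.
#' @param cell_mask Logical Y x X osteoclast mask (any foreground pixel set).
#' @param exclusion_ring Dilation radius in pixels excluded from the noise
#'   region (default 2).
#' @return A one-row tibble: `signal_mean`, `noise_mean`, `inside_px`,
#'   `outside_px`, `index`.
#' @export
#' @examples
#' img <- matrix(10, 20, 20); mask <- matrix(FALSE, 20, 20)
#' mask[8:12, 8:12] <- TRUE; img[mask] <- 20
#' bone_resorbing_index(img, mask, exclusion_ring = 0)$index
bone_resorbing_index <- function(ph_channel, cell_mask, exclusion_ring = 2) {
  ph <- as.matrix(ph_channel)
  mask <- as.logical(cell_mask)
  dim(mask) <- dim(cell_mask)
  if (!identical(dim(ph), dim(mask))) {
    abort("`ph_channel` and `cell_mask` must have identical shape.")
  }
  if (!any(mask)) abort("Empty cell mask: the probe signal region is undefined.")
  if (exclusion_ring > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(exclusion_ring) + 1L,
                                shape = "disc")
    excluded <- as.matrix(EBImage::dilate(mask * 1, brush)) > 0
  } else {
    excluded <- mask
  }
  outside <- !excluded
  if (!any(outside)) {
    abort("No background pixels remain after the exclusion ring.")
  }
  signal_mean <- mean(ph[mask])
  noise_mean <- mean(ph[outside])
  if (noise_mean <= 0) {
    abort("Probe noise mean is zero; the bone-resorbing index is undefined.")
  }
  tibble::tibble(
    signal_mean = signal_mean,
    noise_mean = noise_mean,
    inside_px = sum(mask),
    outside_px = sum(outside),
    index = signal_mean / noise_mean
  )
}

#' Bone-resorbing index along a stack
#'
#' For each frame, takes the union of all labeled osteoclast regions as the
#' cell mask and computes the bone-resorbing index on the pH-probe channel.
#' Frames with no segmented cells are skipped with a message. The movie-level
#' summary is the mean over frames.
#'
#' @param stack An [image_stack()] containing a pH-probe channel.
#' @param label_maps Label maps from [segment_stack()], derived from the
#'   same stack's reporter channel.
#' @param exclusion_ring Noise-region exclusion radius in pixels (default 2).
#' @param ph_channel Name of the probe channel (default `"ph_probe"`).
#' @return A list: `per_frame` (tibble with `frame` plus the
#'   [bone_resorbing_index()] columns) and `movie` (one-row tibble with
#'   `n_frames_used` and `index`, the mean per-frame index).
#' @export
compute_stack_resorption <- function(stack, label_maps, exclusion_ring = 2,
                                     ph_channel = "ph_probe") {
  stopifnot(inherits(stack, "image_stack"))
  if (length(label_maps) != n_frames(stack)) {
    abort("One label map per frame is required.")
  }
  rows <- list()
  for (t in seq_len(n_frames(stack))) {
    lab <- label_maps[[t]]
    if (max(lab) == 0L) {
      message(sprintf("Frame %d has no segmented cells; skipped.", t))
      next
    }
    rec <- bone_resorbing_index(
      get_frame(stack, ph_channel, t), lab > 0L, exclusion_ring
    )
    rec <- dplyr::mutate(rec, frame = t, .before = 1)
    rows[[length(rows) + 1L]] <- rec
  }
  per_frame <- dplyr::bind_rows(rows)
  if (nrow(per_frame) == 0L) {
    abort("No frame contained a segmented cell; cannot compute the index.")
  }
  list(
    per_frame = per_frame,
    movie = tibble::tibble(
      n_frames_used = nrow(per_frame),
      index = mean(per_frame$index)
    )
  )
}
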