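#' Segmentation parameters
#'
#' Controls the automatic extraction of osteoclast areas from a reporter
#' channel: threshold, morphological opening, minimum region area, and the
#' border policy.
#'
#' @param threshold_method `"otsu"` (automatic, default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold, used only when
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum region area in pixels; smaller components are
#'   discarded.
#' @param opening_radius Radius of the disc structuring element for
#'   morphological opening; 0 skips opening.
#' @param clear_border Drop regions touching the field border (default
#'   `TRUE`), since their areas would be censored.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_area = 50,
                                opening_radius = 1,
                                clear_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold)) {
    abort("`fixed_threshold` must be set when `threshold_method = 'fixed'`.")
  }
  if (min_area < 0 || opening_radius < 0) {
    abort("`min_area` and `opening_radius` must be >= 0.")
  }
  structure(
    list(
      threshold_method = threshold_method,
      fixed_threshold = fixed_threshold,
      min_area = min_area,
      opening_radius = opening_radius,
      clear_border = isTRUE(clear_border)
    ),
    class = "segmentation_params"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged afterwards with a small union-find pass.
label_components_8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  k <- max(lab)
  if (k < 2L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(k)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- pairs[r, 1]; rb <- pairs[r, 2]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }, integer(1))
  remap <- c(0L, match(root, sort(unique(root))))
  out <- matrix(remap[lab + 1L], nr, nc)
  storage.mode(out) <- "integer"
  out
}

#' Segment one frame into labeled osteoclast regions
#'
#' Binarizes the image (Otsu or fixed threshold), applies morphological
#' opening, labels 8-connected components, discards regions below
#' `min_area`, optionally drops border-touching regions, and relabels the
#' survivors contiguously 1..K (0 = background).
#'
#' @param channel_image Y x X nonnegative intensity matrix.
#' @param params A [segmentation_params()].
#' @return An integer Y x X label matrix. A constant image under Otsu yields
#'   an empty (all-zero) label map, not an error.
#' @export
#' @examples
#' img <- matrix(0, 40, 40); img[10:25, 10:25] <- 100
#' max(segment_frame(img, segmentation_params(min_area = 20)))
segment_frame <- function(channel_image, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  img <- as.matrix(channel_image)
  if (length(img) == 0L) abort("Image must be nonempty.")
  if (any(img < 0)) abort("Image intensities must be >= 0.")

  if (params$threshold_method == "otsu") {
    rng <- range(img)
    if (diff(rng) < 1e-12) {
      return(matrix(0L, nrow(img), ncol(img)))
    }
    norm <- (img - rng[1]) / diff(rng)
    thr_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr_norm
  } else {
    mask <- img > params$fixed_threshold
  }
  if (params$opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(params$opening_radius) + 1L,
                                shape = "disc")
    mask <- as.matrix(EBImage::opening(mask * 1, brush)) > 0
  }
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  lab <- label_components_8(mask)

  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= params$min_area)
  if (params$clear_border && length(keep)) {
    border_labels <- unique(c(
      lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]
    ))
    keep <- setdiff(keep, border_labels[border_labels > 0L])
  }
  remap <- integer(max(lab) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  out <- matrix(remap[lab + 1L], nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

#' Segment every frame of a stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel to binarize (default `"reporter"`, since osteoclast
#'   areas are defined on the cell-reporter signal).
#' @param params A [segmentation_params()].
#' @return A list of integer label matrices, one per frame.
#' @export
segment_stack <- function(stack, channel = "reporter",
                          params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(seq_len(n_frames(stack)), function(t) {
    segment_frame(get_frame(stack, channel, t), params)
  })
}

# Overlap table between two label maps: tibble(label_prev, label_cur,
# intersection, iou).
overlap_table <- function(lab_prev, lab_cur) {
  sel <- lab_prev > 0L & lab_cur > 0L
  if (!any(sel)) {
    return(tibble::tibble(
      label_prev = integer(), label_cur = integer(),
      intersection = integer(), iou = numeric()
    ))
  }
  tab <- table(prev = lab_prev[sel], cur = lab_cur[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  area_prev <- tabulate(lab_prev[lab_prev > 0L], nbins = max(lab_prev))
  area_cur <- tabulate(lab_cur[lab_cur > 0L], nbins = max(lab_cur))
  lp <- as.integer(df$prev); lc <- as.integer(df$cur)
  inter <- as.integer(df$Freq)
  union <- area_prev[lp] + area_cur[lc] - inter
  tibble::tibble(
    label_prev = lp, label_cur = lc,
    intersection = inter, iou = inter / union
  )
}

#' Link labeled regions across frames into cell tracks
#'
#' Greedy frame-to-frame matching by pixel overlap: candidate pairs are
#' accepted in decreasing IoU order (ties broken by larger intersection,
#' then by smaller previous/current label id), a match requires IoU >=
#' `min_iou`, and every unmatched region starts a new track. Tracks have no
#' gaps: a cell lost for one frame starts a new track when it reappears.
#'
#' @param label_maps List of integer label matrices, ordered by frame.
#' @param min_iou Minimum intersection-over-union in \[0, 1\] for a link
#'   (default 0.3).
#' @return A tibble with one row per (track, frame): columns `track_id`,
#'   `frame`, `label`, `area_px`, `centroid_y`, `centroid_x`.
#' @export
track_cells <- function(label_maps, min_iou = 0.3) {
  if (length(label_maps) == 0L) abort("`label_maps` must not be empty.")
  if (length(label_maps) < 2L) abort("Tracking needs at least 2 frames.")
  if (min_iou < 0 || min_iou > 1) abort("`min_iou` must lie in [0, 1].")

  region_rows <- function(lab, frame) {
    k <- max(lab)
    if (k == 0L) {
      return(tibble::tibble(
        frame = integer(), label = integer(), area_px = integer(),
        centroid_y = numeric(), centroid_x = numeric()
      ))
    }
    idx <- which(lab > 0L, arr.ind = TRUE)
    labs <- lab[idx]
    tibble::tibble(
      frame = frame,
      label = seq_len(k),
      area_px = tabulate(labs, nbins = k),
      centroid_y = as.numeric(tapply(idx[, 1], labs, mean)),
      centroid_x = as.numeric(tapply(idx[, 2], labs, mean))
    )
  }

  n_t <- length(label_maps)
  # track id carried by each label of the previous frame
  prev_tracks <- setNames(integer(0), character(0))
  next_track <- 1L
  rows <- vector("list", n_t)

  for (t in seq_len(n_t)) {
    lab <- label_maps[[t]]
    k <- max(lab)
    assign_t <- integer(k)
    if (t > 1L && k > 0L) {
      ot <- overlap_table(label_maps[[t - 1L]], lab)
      ot <- ot[ot$iou >= min_iou, , drop = FALSE]
      if (nrow(ot)) {
        ord <- order(-ot$iou, -ot$intersection, ot$label_prev, ot$label_cur)
        ot <- ot[ord, ]
        used_prev <- logical(max(label_maps[[t - 1L]], 1L))
        for (r in seq_len(nrow(ot))) {
          lp <- ot$label_prev[r]; lc <- ot$label_cur[r]
          if (!used_prev[lp] && assign_t[lc] == 0L) {
            assign_t[lc] <- prev_tracks[[as.character(lp)]]
            used_prev[lp] <- TRUE
          }
        }
      }
    }
    new <- which(assign_t == 0L)
    if (length(new)) {
      assign_t[new] <- next_track + seq_along(new) - 1L
      next_track <- next_track + length(new)
    }
    rr <- region_rows(lab, t)
    rr$track_id <- assign_t[rr$label]
    rows[[t]] <- rr
    prev_tracks <- setNames(assign_t, as.character(seq_len(k)))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(
    out[, c("track_id", "frame", "label", "area_px", "centroid_y", "centroid_x")],
    .data$track_id, .data$frame
  )
}

#' Write label maps as a 16-bit multi-page TIFF
#' @param label_maps List of integer label matrices.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels_tiff <- function(label_maps, path) {
  pages <- lapply(label_maps, function(l) l / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
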