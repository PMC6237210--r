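#' Overlap areas between two masks of one cell
#'
#' Given a cell's binary mask at the initial and final time point, computes
#' the three areas underlying the deformation index: A = pixels only in the
#' initial mask, B = pixels in both, C = pixels only in the final mask.
#' A + B is the initial area; B + C the final area.
#'
#' @param mask_initial,mask_final Logical Y x X matrices of identical shape.
#' @return Named numeric vector `c(area_A, area_B, area_C)` in pixels.
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' overlap_areas(m, m)
overlap_areas <- function(mask_initial, mask_final) {
  if (!identical(dim(mask_initial), dim(mask_final))) {
    abort("Masks must have identical shape.")
  }
  mi <- as.logical(mask_initial)
  mf <- as.logical(mask_final)
  c(
    area_A = sum(mi & !mf),
    area_B = sum(mi & mf),
    area_C = sum(!mi & mf)
  )
}

#' Cell deformation index
#'
#' The ratio of the area changed over the interval to the initial area:
#' \deqn{(A + C) / (A + B)} where A is the initial-only area, B the overlap,
#' and C the final-only area. A static cell scores 0; a cell that relocates
#' completely while keeping its size scores 2.
#'
#' @param area_A,area_B,area_C Areas in pixels, all >= 0; `area_A + area_B`
#'   (the initial area) must be positive.
#' @return The dimensionless index, >= 0.
#' @export
#' @examples
#' deformation_index(0, 100, 0)   # static
#' deformation_index(50, 50, 50)  # square shifted by half its width
deformation_index <- function(area_A, area_B, area_C) {
  if (any(c(area_A, area_B, area_C) < 0)) abort("Areas must be >= 0.")
  if (area_A + area_B <= 0) {
    abort("Deformation index undefined for an empty initial mask (A + B = 0).")
  }
  (area_A + area_C) / (area_A + area_B)
}

#' Deformation records along tracked cells
#'
#' For every tracked cell and every start frame `t` such that `t + window`
#' is still inside the movie, compares the cell's mask at `t` and at
#' `t + window` and records areas A, B, C and the index. With the default
#' 1-min frame interval and `window = 5` this is the standard 5-min
#' deformation window. Windows slide by one frame, so records overlap.
#'
#' If the track has ended before `t + window` (the cell vanished or was
#' lost), the final mask is empty: the record carries A = initial area,
#' B = C = 0, index 1, and `disappeared = TRUE`.
#'
#' @param tracks Tibble from [track_cells()].
#' @param label_maps The label maps the tracks were built from.
#' @param window Interval length in frames (default 5).
#' @return A tibble with columns `track_id`, `t_start`, `t_end`, `area_A`,
#'   `area_B`, `area_C`, `index`, `disappeared`, ordered by track and
#'   start frame. Tracks shorter than `window + 1` frames that also end at
#'   the movie's last frame contribute no records.
#' @export
compute_track_deformation <- function(tracks, label_maps, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) abort("`window` must be >= 1 frame.")
  n_t <- length(label_maps)
  empty <- tibble::tibble(
    track_id = integer(), t_start = integer(), t_end = integer(),
    area_A = numeric(), area_B = numeric(), area_C = numeric(),
    index = numeric(), disappeared = logical()
  )
  if (nrow(tracks) == 0L) return(empty)

  split_tracks <- split(tracks, tracks$track_id)
  recs <- lapply(split_tracks, function(tr) {
    tr <- tr[order(tr$frame), ]
    frames <- tr$frame
    starts <- frames[frames + window <= n_t]
    if (!length(starts)) return(NULL)
    lab_of <- setNames(tr$label, as.character(frames))
    out <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      t0 <- starts[i]; t1 <- t0 + window
      m0 <- label_maps[[t0]] == lab_of[[as.character(t0)]]
      if (t1 %in% frames) {
        m1 <- label_maps[[t1]] == lab_of[[as.character(t1)]]
        ab <- as.numeric(overlap_areas(m0, m1))
        names(ab) <- c("area_A", "area_B", "area_C")
        gone <- FALSE
      } else {
        ab <- c(area_A = sum(m0) * 1.0, area_B = 0, area_C = 0)
        gone <- TRUE
      }
      out[[i]] <- tibble::tibble(
        track_id = tr$track_id[1], t_start = t0, t_end = t1,
        area_A = ab[["area_A"]], area_B = ab[["area_B"]],
        area_C = ab[["area_C"]],
        index = deformation_index(ab[["area_A"]], ab[["area_B"]], ab[["area_C"]]),
        disappeared = gone
      )
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$track_id, .data$t_start)
}

#' Per-cell deformation summary
#'
#' One row per track: the mean of that track's window records (the per-cell
#' aggregation used when comparing groups), the record count, and whether
#' the cell disappeared during any window.
#'
#' @param records Tibble from [compute_track_deformation()].
#' @return Tibble with columns `track_id`, `n_records`, `mean_index`,
#'   `any_disappeared`.
#' @export
summarize_deformation <- function(records) {
  records |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      mean_index = mean(.data$index),
      any_disappeared = any(.data$disappeared),
      .groups = "drop"
    )
}

#' Ground-truth deformation indices from simulated masks
#'
#' Applies the deformation window directly to the simulator's per-cell
#' ground-truth masks, bypassing segmentation and tracking. Used to validate
#' the generator and as the reference in pipeline tests.
#'
#' @param truth A `ground_truth` from [simulate_timelapse()].
#' @param window Interval in frames (default 5).
#' @return Tibble with columns `cell`, `t_start`, `t_end`, `area_A`,
#'   `area_B`, `area_C`, `index`.
#' @export
truth_deformation <- function(truth, window = 5L) {
  stopifnot(inherits(truth, "ground_truth"))
  window <- as.integer(window)
  n_t <- length(truth$masks)
  n_c <- length(truth$masks[[1]])
  rows <- list()
  for (i in seq_len(n_c)) {
    for (t0 in seq_len(max(0L, n_t - window))) {
      ab <- overlap_areas(truth$masks[[t0]][[i]], truth$masks[[t0 + window]][[i]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell = i, t_start = t0, t_end = t0 + window,
        area_A = ab[["area_A"]], area_B = ab[["area_B"]],
        area_C = ab[["area_C"]],
        index = deformation_index(ab[["area_A"]], ab[["area_B"]], ab[["area_C"]])
      )
    }
  }
  dplyr::bind_rows(rows)
}
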