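disc_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("blank and constant images yield empty label maps", {
  p <- segmentation_params(min_area = 10)
  expect_equal(max(segment_frame(matrix(0, 30, 30), p)), 0)
  expect_equal(max(segment_frame(matrix(7, 30, 30), p)), 0)  # otsu, constant
})

test_that("a bright disc is extracted with the right area", {
  m <- disc_mask(60, 60, 30, 30, 10)
  img <- matrix(0, 60, 60); img[m] <- 100
  lab <- segment_frame(img, segmentation_params(min_area = 20))
  expect_equal(max(lab), 1)
  area <- sum(lab == 1)
  expect_lt(abs(area - pi * 10^2) / (pi * 10^2), 0.05)
})

test_that("disjoint discs give separate labels, small ones are dropped", {
  img <- matrix(0, 80, 80)
  img[disc_mask(80, 80, 20, 20, 8)] <- 100
  img[disc_mask(80, 80, 60, 60, 8)] <- 100
  lab <- segment_frame(img, segmentation_params(min_area = 20))
  expect_equal(max(lab), 2)
  # third tiny blob below min_area disappears
  img[disc_mask(80, 80, 20, 60, 2)] <- 100
  lab2 <- segment_frame(img, segmentation_params(min_area = 20, opening_radius = 0))
  expect_equal(max(lab2), 2)
})

test_that("diagonally touching foreground is one 8-connected component", {
  img <- matrix(0, 20, 20)
  img[3:6, 3:6] <- 100
  img[7:10, 7:10] <- 100  # touches the first square only at a corner
  lab <- segment_frame(
    img,
    segmentation_params(threshold_method = "fixed", fixed_threshold = 50,
                        min_area = 1, opening_radius = 0)
  )
  expect_equal(max(lab), 1)
})

test_that("border-touching regions are dropped when clear_border is set", {
  img <- matrix(0, 40, 40)
  img[1:10, 5:15] <- 100           # touches row 1
  img[20:30, 20:30] <- 100
  p_keep <- segmentation_params(min_area = 10, clear_border = FALSE)
  p_drop <- segmentation_params(min_area = 10, clear_border = TRUE)
  expect_equal(max(segment_frame(img, p_keep)), 2)
  expect_equal(max(segment_frame(img, p_drop)), 1)
})

test_that("labels are contiguous and respect min_area on simulated frames", {
  cfg <- small_config(n_frames = 2L)
  stk <- simulate_timelapse(cfg)$stack
  p <- segmentation_params(min_area = 50)
  for (t in 1:2) {
    lab <- segment_frame(get_frame(stk, "reporter", t), p)
    k <- max(lab)
    if (k > 0) {
      areas <- tabulate(lab[lab > 0], nbins = k)
      expect_true(all(areas >= p$min_area))
      expect_identical(sort(unique(as.vector(lab[lab > 0]))), seq_len(k))
    }
  }
})

static_maps <- function(n_frames, discs) {
  lapply(seq_len(n_frames), function(t) {
    lab <- matrix(0L, 64, 64)
    for (i in seq_along(discs)) {
      d <- discs[[i]]
      lab[disc_mask(64, 64, d[1], d[2], d[3])] <- i
    }
    lab
  })
}

test_that("static cells give one gapless track each, with no identity swaps", {
  maps <- static_maps(6, list(c(20, 20, 7), c(45, 45, 7)))
  tr <- track_cells(maps, min_iou = 0.3)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
  counts <- table(tr$track_id)
  expect_true(all(counts == 6))
  # frames consecutive within each track
  for (id in unique(tr$track_id)) {
    f <- sort(tr$frame[tr$track_id == id])
    expect_identical(f, seq(min(f), max(f)))
  }
  # identity maintained: the same label is carried by the same track
  expect_equal(dplyr::n_distinct(paste(tr$track_id, tr$label)), 2)
})

test_that("a jump below the IoU threshold ends the track and starts a new one", {
  lab1 <- matrix(0L, 64, 64); lab1[disc_mask(64, 64, 15, 15, 6)] <- 1L
  lab2 <- matrix(0L, 64, 64); lab2[disc_mask(64, 64, 50, 50, 6)] <- 1L
  # oracle check: zero overlap between the two frames
  expect_equal(sum(lab1 > 0 & lab2 > 0), 0)
  tr <- track_cells(list(lab1, lab2), min_iou = 0.3)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
})

test_that("tracking is deterministic and rejects degenerate input", {
  maps <- static_maps(4, list(c(20, 20, 7), c(45, 45, 7)))
  expect_identical(track_cells(maps, 0.3), track_cells(maps, 0.3))
  expect_error(track_cells(list()), "empty")
  expect_error(track_cells(maps[1]), "2 frames")
  expect_error(track_cells(maps, min_iou = 1.5), "min_iou")
})

test_that("segmentation recovers >= 95% of eligible ground-truth cells at IoU 0.7", {
  recovered <- 0L; eligible <- 0L
  p <- segmentation_params(min_area = 50)
  for (seed in 1:3) {
    cfg <- simulation_config(
      field_size = c(256L, 256L), n_cells = 10L, n_frames = 3L,
      cell_radius_mean = 10, noise_sd = 5, seed = seed
    )
    sim <- simulate_timelapse(cfg)
    for (t in seq_len(n_frames(sim$stack))) {
      lab <- segment_frame(get_frame(sim$stack, "reporter", t), p)
      for (m in sim$truth$masks[[t]]) {
        touches_border <- any(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
        if (sum(m) < p$min_area || touches_border) next
        eligible <- eligible + 1L
        ious <- vapply(seq_len(max(lab, 1L)), function(k) {
          if (max(lab) == 0L) return(0)
          mask_iou(lab == k, m)
        }, numeric(1))
        if (max(ious, 0) >= 0.7) recovered <- recovered + 1L
      }
    }
  }
  expect_gt(eligible, 50)
  expect_gte(recovered / eligible, 0.95)
})
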