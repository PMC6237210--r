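square_mask <- function(ny, nx, y0, y1, x0, x1) {
  m <- matrix(FALSE, ny, nx); m[y0:y1, x0:x1] <- TRUE; m
}

test_that("overlap areas match hand-constructed geometries", {
  m <- square_mask(5, 5, 1, 5, 1, 5)
  expect_equal(overlap_areas(m, m), c(area_A = 0, area_B = 25, area_C = 0))

  a <- square_mask(20, 20, 1, 5, 1, 6)    # 30 px
  b <- square_mask(20, 20, 10, 14, 10, 17) # 40 px
  expect_equal(overlap_areas(a, b), c(area_A = 30, area_B = 0, area_C = 40))

  sq1 <- square_mask(30, 30, 5, 14, 5, 14)   # 10 x 10
  sq2 <- square_mask(30, 30, 5, 14, 10, 19)  # shifted right by 5
  expect_equal(overlap_areas(sq1, sq2), c(area_A = 50, area_B = 50, area_C = 50))

  expect_error(overlap_areas(m, square_mask(6, 6, 1, 2, 1, 2)), "shape")
})

test_that("the deformation index reproduces its anchor values", {
  expect_equal(deformation_index(0, 100, 0), 0)     # static cell
  expect_equal(deformation_index(50, 50, 50), 1)    # half-shifted square
  expect_equal(deformation_index(100, 0, 100), 2)   # complete relocation
  expect_error(deformation_index(0, 0, 10), "empty initial")
  expect_error(deformation_index(-1, 5, 0), ">= 0")
})

test_that("overlap areas agree exactly with brute-force enumeration", {
  set.seed(101)
  for (case in 1:1000) {
    ny <- sample(1:32, 1); nx <- sample(1:32, 1)
    m1 <- random_mask(ny, nx); m2 <- random_mask(ny, nx)
    got <- overlap_areas(m1, m2)
    expect_identical(unname(got), unname(oracle_overlap(m1, m2)))
    # conservation: A + B = initial area, B + C = final area
    expect_equal(got[["area_A"]] + got[["area_B"]], sum(m1))
    expect_equal(got[["area_B"]] + got[["area_C"]], sum(m2))
  }
})

test_that("index is 0 iff masks are identical (nonempty cases)", {
  set.seed(11)
  for (case in 1:50) {
    m1 <- random_mask(16, 16)
    if (!any(m1)) next
    expect_equal(do.call(deformation_index, as.list(overlap_areas(m1, m1))), 0)
    m2 <- m1; flip <- sample(length(m2), 1); m2[flip] <- !m2[flip]
    ab <- overlap_areas(m1, m2)
    expect_gt(deformation_index(ab[1], ab[2], ab[3]), 0)
  }
})

make_label_seq <- function(masks) {
  lapply(masks, function(m) {
    lab <- matrix(0L, nrow(m), ncol(m)); lab[m] <- 1L; lab
  })
}

test_that("track records: static cell, window count, and disappearance", {
  m <- square_mask(40, 40, 10, 20, 10, 20)
  maps <- make_label_seq(replicate(6, m, simplify = FALSE))
  tr <- track_cells(maps, 0.3)
  rec <- compute_track_deformation(tr, maps, window = 5)
  expect_equal(nrow(rec), 1)               # length 6, window 5: one record
  expect_equal(rec$index, 0)
  expect_false(rec$disappeared)

  # shorter window slides: length 6, window 2 -> 4 records, all zero
  rec2 <- compute_track_deformation(tr, maps, window = 2)
  expect_equal(nrow(rec2), 4)
  expect_true(all(rec2$index == 0))

  # a track shorter than the window at the movie's end yields no record
  rec3 <- compute_track_deformation(tr[tr$frame <= 3, ], maps[1:3], window = 5)
  expect_equal(nrow(rec3), 0)
})

test_that("a vanished cell is flagged, with index 1 by the formula", {
  m <- square_mask(40, 40, 10, 20, 10, 20)
  empty <- matrix(FALSE, 40, 40)
  far <- square_mask(40, 40, 28, 38, 28, 38)
  # cell present frames 1-2 then gone; a different cell appears elsewhere
  maps <- make_label_seq(list(m, m, far, far, far, far, far))
  tr <- track_cells(maps, 0.3)
  rec <- compute_track_deformation(tr, maps, window = 5)
  gone <- rec[rec$disappeared, ]
  expect_gte(nrow(gone), 1)
  expect_true(all(gone$index == 1))
  expect_true(all(gone$area_B == 0 & gone$area_C == 0))
  expect_true(all(gone$area_A > 0))
})

test_that("pipeline records equal an independent per-pixel oracle", {
  cfg <- small_config(motility = 0.35, n_frames = 7L, seed = 21L)
  res <- analyze_movie(cfg)
  expect_gt(nrow(res$deformation), 0)
  lab_of <- function(track, frame) {
    r <- res$tracks[res$tracks$track_id == track & res$tracks$frame == frame, ]
    if (nrow(r) == 0) return(NA_integer_)
    r$label
  }
  for (i in seq_len(nrow(res$deformation))) {
    rec <- res$deformation[i, ]
    m0 <- res$label_maps[[rec$t_start]] == lab_of(rec$track_id, rec$t_start)
    l1 <- lab_of(rec$track_id, rec$t_end)
    m1 <- if (is.na(l1)) matrix(FALSE, nrow(m0), ncol(m0))
          else res$label_maps[[rec$t_end]] == l1
    ora <- oracle_overlap(m0, m1)
    expect_identical(
      c(rec$area_A, rec$area_B, rec$area_C),
      as.numeric(ora)
    )
    expect_equal(rec$index, (ora[1] + ora[3]) / (ora[1] + ora[2]),
                 ignore_attr = TRUE)
  }
})

test_that("per-cell summary averages a track's records", {
  rec <- tibble::tibble(
    track_id = c(1L, 1L, 2L), t_start = c(1L, 2L, 1L), t_end = c(6L, 7L, 6L),
    area_A = c(10, 20, 0), area_B = c(90, 80, 50), area_C = c(10, 0, 0),
    index = c(0.2, 0.2, 0), disappeared = c(FALSE, FALSE, FALSE)
  )
  s <- summarize_deformation(rec)
  expect_equal(s$mean_index, c(0.2, 0))
  expect_equal(s$n_records, c(2L, 1L))
})
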