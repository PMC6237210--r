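em2 <- function() {
  endmember_matrix(
    cbind(c(1, 0), c(0.6, 0.8)),
    c("reporter", "autofluorescence")
  )
}

test_that("endmember validation rejects bad spectra", {
  expect_error(
    endmember_matrix(cbind(c(-1, 0), c(0, 1)), c("a", "autofluorescence")),
    "nonnegative"
  )
  expect_error(
    endmember_matrix(cbind(c(1, 0), c(0, 1)), c("a", "b")),
    "autofluorescence"
  )
  expect_error(
    endmember_matrix(cbind(c(1, 1), c(2, 2)), c("a", "autofluorescence")),
    "rank deficient"
  )
  expect_error(
    endmember_matrix(cbind(c(1, 0), c(0, 0)), c("a", "autofluorescence")),
    "positive norm"
  )
})

test_that("pure, mixed and zero pixels unmix correctly", {
  em <- default_endmembers()
  S <- em$spectra
  n_det <- nrow(S)
  det_names <- paste0("det", seq_len(n_det))
  # pure pixel per endmember
  raw_arr <- array(0, c(1, n_det, 1, ncol(S)))
  for (e in seq_len(ncol(S))) raw_arr[1, , 1, e] <- S[, e]
  ab <- unmix(
    image_stack(raw_arr, det_names), em,
    drop_autofluorescence = FALSE
  )
  for (e in seq_len(ncol(S))) {
    expected <- rep(0, ncol(S)); expected[e] <- 1
    expect_equal(ab$data[1, , 1, e], expected, tolerance = 1e-9)
  }
  # known mixture (0.3, 0.7, 0, 0) recovered within 1e-6
  truth <- c(0.3, 0.7, 0, 0)
  mixed <- as.vector(S %*% truth)
  raw <- image_stack(array(mixed, c(1, n_det, 1, 1)), det_names)
  got <- unmix(raw, em, drop_autofluorescence = FALSE)$data[1, , 1, 1]
  expect_equal(got, truth, tolerance = 1e-6)
  # all-zero pixel stays zero
  raw0 <- image_stack(array(0, c(1, n_det, 1, 1)), det_names)
  expect_true(all(unmix(raw0, em, drop_autofluorescence = FALSE)$data == 0))
})

test_that("unmixing matches an exhaustive grid-search oracle on tiny images", {
  set.seed(42)
  em <- em2()
  S <- em$spectra
  grid <- seq(0, 1, by = 1e-3)
  # oracle: full grid search over both abundances, step 1e-3
  oracle_pixel <- function(p) {
    best <- c(0, 0); best_err <- Inf
    for (a2 in grid) {
      r <- p - S[, 2] * a2
      # residual over a1 handled vectorised for speed
      errs <- (r[1] - S[1, 1] * grid)^2 + (r[2] - S[2, 1] * grid)^2
      i <- which.min(errs)
      if (errs[i] < best_err) {
        best_err <- errs[i]; best <- c(grid[i], a2)
      }
    }
    best
  }
  truth <- matrix(runif(8, 0, 1), 2, 4)  # 4 pixels, 2 abundances
  pixels <- S %*% truth + matrix(rnorm(8, 0, 0.02), 2, 4)
  pixels[pixels < 0] <- 0
  arr <- array(0, c(1, 2, 1, 4))
  for (d in 1:2) arr[1, d, 1, ] <- pixels[d, ]
  raw <- image_stack(arr, c("det1", "det2"))
  got <- unmix(raw, em, drop_autofluorescence = FALSE)
  for (px in 1:4) {
    expect_equal(
      got$data[1, , 1, px], oracle_pixel(pixels[, px]),
      tolerance = 3e-3
    )
  }
})

test_that("abundances are always nonnegative", {
  set.seed(7)
  em <- default_endmembers()
  n_det <- nrow(em$spectra)
  arr <- array(runif(4 * n_det * 6 * 6, 0, 50), c(4, n_det, 6, 6))
  ab <- unmix(image_stack(arr, paste0("det", seq_len(n_det))), em,
    drop_autofluorescence = FALSE
  )
  expect_true(all(ab$data >= 0))
})

test_that("spectral simulation and unmixing round-trip the clean channels", {
  # noiseless: exact identity-style recovery
  cfg0 <- small_config(
    field_size = c(64L, 64L), n_cells = 3L, n_frames = 2L,
    cell_radius_mean = 7, noise_sd = 0, seed = 5L
  )
  sp0 <- simulate_spectral(cfg0)
  ab0 <- unmix(sp0$raw, sp0$endmembers, drop_autofluorescence = FALSE)
  expect_lt(max(abs(ab0$data - sp0$abundance_truth$data)), 1e-6)

  # with autofluorescence_weight = 0 the autofluorescence abundance is 0
  cfg_noaf <- small_config(
    field_size = c(48L, 48L), n_cells = 2L, n_frames = 2L,
    cell_radius_mean = 7, noise_sd = 0, autofluorescence_weight = 0, seed = 6L
  )
  sp_noaf <- simulate_spectral(cfg_noaf)
  expect_true(all(sp_noaf$abundance_truth$data[, 4, , ] == 0))

  # noisy: per-channel RMSE within 2 x noise_sd
  cfg <- small_config(
    field_size = c(64L, 64L), n_cells = 3L, n_frames = 2L,
    cell_radius_mean = 7, noise_sd = 4, seed = 5L
  )
  sp <- simulate_spectral(cfg)
  ab <- unmix(sp$raw, sp$endmembers, drop_autofluorescence = TRUE)
  for (c in seq_along(ab$channels)) {
    rmse <- sqrt(mean((ab$data[, c, , ] - sp$clean$data[, c, , ])^2))
    expect_lt(rmse, 2 * cfg$noise_sd)
  }
})

test_that("channel-count mismatches are rejected", {
  em <- em2()
  raw <- image_stack(array(1, c(1, 3, 2, 2)), c("d1", "d2", "d3"))
  expect_error(unmix(raw, em), "detector channels")
})

test_that("endmember CSV round-trips", {
  em <- default_endmembers()
  path <- withr::local_tempfile(fileext = ".csv")
  write_endmembers_csv(em, path)
  back <- read_endmembers_csv(path)
  expect_equal(back$spectra, em$spectra)
})
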