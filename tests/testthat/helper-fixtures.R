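# Small, fast simulator configs used across the suite. Fields are kept well
# below the 512 px production default so the whole suite runs in seconds.

small_config <- function(...) {
  defaults <- list(
    field_size = c(128L, 128L), n_cells = 4L, n_frames = 7L,
    cell_radius_mean = 9, cell_radius_sd = 1, seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Brute-force per-pixel oracle for the overlap areas: explicit loops, no set
# algebra shared with the implementation.
oracle_overlap <- function(m1, m2) {
  a <- 0L; b <- 0L; c <- 0L
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(ncol(m1))) {
      if (m1[i, j] && m2[i, j]) {
        b <- b + 1L
      } else if (m1[i, j]) {
        a <- a + 1L
      } else if (m2[i, j]) {
        c <- c + 1L
      }
    }
  }
  c(area_A = a, area_B = b, area_C = c)
}

# Independent mean-ratio oracle for the bone-resorbing index (ring = 0).
oracle_resorbing <- function(ph, mask) {
  s <- 0; ns <- 0; si <- 0L; ni <- 0L
  for (i in seq_len(nrow(ph))) {
    for (j in seq_len(ncol(ph))) {
      if (mask[i, j]) { s <- s + ph[i, j]; si <- si + 1L }
      else { ns <- ns + ph[i, j]; ni <- ni + 1L }
    }
  }
  (s / si) / (ns / ni)
}

random_mask <- function(ny, nx, p = 0.4) {
  matrix(runif(ny * nx) < p, ny, nx)
}

# IoU between two logical masks
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}
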