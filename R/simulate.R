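#' Simulation configuration
#'
#' Parameters of the synthetic two-photon time-lapse generator. Defaults
#' describe an untreated-like field; [make_condition_config()] derives the
#' named experimental scenarios from the condition table.
#'
#' @param field_size Integer vector (Y, X) field size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Minutes between frames; the default 1 min makes the
#'   standard 5-min deformation window span 5 frames.
#' @param n_cells Number of osteoclast-like cells placed in the field.
#' @param cell_radius_mean,cell_radius_sd Mean and SD of cell base radius
#'   in pixels.
#' @param motility Dimensionless boundary-change rate per frame (>= 0). Zero
#'   means perfectly static cells.
#' @param secretion Dimensionless pH-probe amplitude (>= 0) deposited under
#'   resorbing cells, as a fraction of `cell_intensity`.
#' @param resorbing_fraction Fraction in \[0, 1\] of cells that secrete.
#' @param cell_intensity Reporter-channel amplitude of a cell (a.u.).
#' @param background_level Additive background intensity in all channels.
#' @param noise_sd SD of the additive Gaussian noise (clipped at zero).
#' @param autofluorescence_weight Fraction in \[0, 1\] scaling the
#'   autofluorescence component in spectral simulation.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(field_size = c(512L, 512L),
                              n_frames = 10L,
                              frame_interval = 1,
                              n_cells = 10L,
                              cell_radius_mean = 15,
                              cell_radius_sd = 2,
                              motility = 0.05,
                              secretion = 1,
                              resorbing_fraction = 0.8,
                              cell_intensity = 100,
                              background_level = 10,
                              noise_sd = 5,
                              autofluorescence_weight = 0.2,
                              pixel_size = 1,
                              seed = 1L) {
  cfg <- list(
    field_size = as.integer(field_size),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    n_cells = as.integer(n_cells),
    cell_radius_mean = cell_radius_mean,
    cell_radius_sd = cell_radius_sd,
    motility = motility,
    secretion = secretion,
    resorbing_fraction = resorbing_fraction,
    cell_intensity = cell_intensity,
    background_level = background_level,
    noise_sd = noise_sd,
    autofluorescence_weight = autofluorescence_weight,
    pixel_size = pixel_size,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (length(cfg$field_size) != 2L || any(cfg$field_size < 16L)) {
    abort("`field_size` must be two integers >= 16.")
  }
  if (cfg$n_frames < 2L) abort("`n_frames` must be >= 2.")
  if (cfg$motility < 0) abort("`motility` must be >= 0.")
  if (cfg$secretion < 0) abort("`secretion` must be >= 0.")
  if (cfg$resorbing_fraction < 0 || cfg$resorbing_fraction > 1) {
    abort("`resorbing_fraction` must lie in [0, 1].")
  }
  if (cfg$autofluorescence_weight < 0 || cfg$autofluorescence_weight > 1) {
    abort("`autofluorescence_weight` must lie in [0, 1].")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (cfg$n_cells < 1L) abort("`n_cells` must be >= 1.")
  invisible(cfg)
}

#' Named experimental scenarios
#'
#' One row per imaging condition: untreated osteoporotic mice and mice 12 or
#' 24 hours after a single injection of risedronate (ris), alendronate (aln)
#' or minodronate (mino). Motility and secretion encode the qualitative
#' findings: every bisphosphonate strongly reduces proton secretion by 12 h
#' and the suppression persists at 24 h; risedronate raises osteoclast
#' motility the most at 12 h, alendronate less so, while minodronate's
#' motility effect peaks at 24 h rather than 12 h. The numeric values are
#' free choices constrained only by those orderings and are kept in this one
#' table rather than in logic.
#'
#' @return A tibble with columns `condition`, `motility`, `secretion`.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  tibble::tribble(
    ~condition,  ~motility, ~secretion,
    "untreated", 0.05,      1.00,
    "ris_12h",   0.50,      0.10,
    "aln_12h",   0.30,      0.10,
    "mino_12h",  0.10,      0.10,
    "ris_24h",   0.30,      0.15,
    "aln_24h",   0.20,      0.15,
    "mino_24h",  0.40,      0.15
  )
}

#' Build the simulation config for a named condition
#'
#' @param condition One of the names in [condition_table()].
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()] (e.g. a smaller
#'   `field_size` for quick runs). `motility` and `secretion` come from the
#'   condition table and cannot be overridden here.
#' @return A `simulation_config`.
#' @export
#' @examples
#' cfg <- make_condition_config("ris_12h", seed = 1)
#' cfg$motility > make_condition_config("aln_12h", seed = 1)$motility
make_condition_config <- function(condition, seed, ...) {
  tab <- condition_table()
  row <- tab[tab$condition == condition, ]
  if (nrow(row) != 1L) {
    abort(sprintf(
      "Unknown condition '%s'. Valid conditions: %s.",
      condition, paste(tab$condition, collapse = ", ")
    ))
  }
  extra <- list(...)
  if (any(c("motility", "secretion") %in% names(extra))) {
    abort("`motility` and `secretion` are fixed by the condition table.")
  }
  args <- c(
    list(motility = row$motility, secretion = row$secretion, seed = seed),
    extra
  )
  do.call(simulation_config, args)
}

# Rasterize one star-convex cell: radius over angle is
# r(theta) = r0 * pmax(0.25, 1 + sum_k a_k cos(k theta) + b_k sin(k theta)).
# Returns a logical Y x X mask. Low-order Fourier boundaries guarantee a
# simply-connected region and make the zero-motility case exact.
rasterize_cell <- function(cy, cx, r0, coef_a, coef_b, field_size) {
  rmax <- r0 * (1 + sum(abs(coef_a)) + sum(abs(coef_b)))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(field_size[1], ceiling(cy + rmax))
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(field_size[2], ceiling(cx + rmax))
  mask <- matrix(FALSE, field_size[1], field_size[2])
  if (y1 < y0 || x1 < x0) return(mask)
  ys <- y0:y1; xs <- x0:x1
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  theta <- atan2(dy, dx)
  rad <- 1
  for (k in seq_along(coef_a)) {
    rad <- rad + coef_a[k] * cos((k + 1) * theta) + coef_b[k] * sin((k + 1) * theta)
  }
  rad <- r0 * pmax(0.25, rad)
  mask[ys, xs] <- (dy^2 + dx^2) <= rad^2
  mask
}

# Place cell centres with a minimum separation so cells never fuse. The
# sequential rejection sampler restarts the whole layout when it paints
# itself into a corner; a configuration that still fails after all restarts
# errors with a placement diagnostic.
place_cells <- function(n_cells, radii, field_size,
                        max_retries = 200L, max_restarts = 25L) {
  margin <- 1.6 * radii + 2
  if (any(2 * margin >= min(field_size))) {
    i <- which(2 * margin >= min(field_size))[1]
    abort(sprintf(
      "Cell %d (radius %.1f px) cannot fit in a %d x %d field.",
      i, radii[i], field_size[1], field_size[2]
    ))
  }
  for (restart in seq_len(max_restarts)) {
    centres <- matrix(NA_real_, n_cells, 2)
    placed_all <- TRUE
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- c(
          runif(1, margin[i], field_size[1] - margin[i]),
          runif(1, margin[i], field_size[2] - margin[i])
        )
        if (i == 1L) { ok <- TRUE } else {
          prev <- centres[seq_len(i - 1L), , drop = FALSE]
          dist <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
          ok <- all(dist >= 1.4 * (radii[seq_len(i - 1L)] + radii[i]))
        }
        if (ok) { centres[i, ] <- cand; break }
      }
      if (!ok) { placed_all <- FALSE; break }
    }
    if (placed_all) return(centres)
  }
  abort(sprintf(
    "Failed to place %d cells after %d layout restarts in a %d x %d field; reduce `n_cells` or `cell_radius_mean`.",
    n_cells, max_restarts, field_size[1], field_size[2]
  ))
}

# Smooth random field in [0, 1]: coarse Gaussian grid, bilinearly upsampled,
# then Gaussian-blurred. Used for the bone channel and autofluorescence.
smooth_field <- function(field_size, grain = 16L, sigma = 6) {
  # the blur kernel (2 * ceiling(3 sigma) + 1 px) must fit inside the field
  sigma <- min(sigma, max(1, (min(field_size) - 3) / 6))
  gy <- max(2L, ceiling(field_size[1] / grain))
  gx <- max(2L, ceiling(field_size[2] / grain))
  coarse <- matrix(rnorm(gy * gx), gy, gx)
  yi <- seq(1, gy, length.out = field_size[1])
  xi <- seq(1, gx, length.out = field_size[2])
  y0 <- pmin(floor(yi), gy - 1L); x0 <- pmin(floor(xi), gx - 1L)
  fy <- yi - y0; fx <- xi - x0
  # bilinear interpolation, vectorized over the full grid
  up <- outer(seq_along(yi), seq_along(xi), function(i, j) {
    a <- coarse[cbind(y0[i], x0[j])] * (1 - fy[i]) * (1 - fx[j])
    b <- coarse[cbind(y0[i] + 1L, x0[j])] * fy[i] * (1 - fx[j])
    c <- coarse[cbind(y0[i], x0[j] + 1L)] * (1 - fy[i]) * fx[j]
    d <- coarse[cbind(y0[i] + 1L, x0[j] + 1L)] * fy[i] * fx[j]
    a + b + c + d
  })
  sm <- as.matrix(EBImage::gblur(up, sigma = sigma))
  rng <- range(sm)
  if (diff(rng) < 1e-12) return(matrix(0.5, field_size[1], field_size[2]))
  (sm - rng[1]) / diff(rng)
}

# Noise-free render shared by simulate_timelapse() and simulate_spectral().
simulate_clean <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  fs <- config$field_size
  n <- config$n_cells
  nf <- config$n_frames

  radii <- pmax(4, rnorm(n, config$cell_radius_mean, config$cell_radius_sd))
  centres <- place_cells(n, radii, fs)
  n_harm <- 3L  # Fourier orders 2..4 on the boundary
  coef_a <- matrix(rnorm(n * n_harm, 0, 0.08), n, n_harm)
  coef_b <- matrix(rnorm(n * n_harm, 0, 0.08), n, n_harm)
  resorbing <- runif(n) < config$resorbing_fraction

  bone <- smooth_field(fs)

  masks <- vector("list", nf)
  data <- array(0, c(nf, 3L, fs[1], fs[2]))
  ring <- EBImage::makeBrush(3L, shape = "diamond")  # 1-px erosion element
  for (t in seq_len(nf)) {
    if (t > 1L) {
      # boundary + centroid random walk; step magnitude proportional to
      # motility so motility = 0 leaves every mask bit-identical. The
      # centroid step is weighted below the boundary step: osteoclasts are
      # adherent, so shape change dominates translocation.
      step_c <- 0.3 * config$motility * radii
      centres <- centres + cbind(rnorm(n, 0, step_c), rnorm(n, 0, step_c))
      centres[, 1] <- pmin(pmax(centres[, 1], 1.6 * radii), fs[1] - 1.6 * radii)
      centres[, 2] <- pmin(pmax(centres[, 2], 1.6 * radii), fs[2] - 1.6 * radii)
      coef_a <- coef_a + matrix(rnorm(n * n_harm, 0, 0.3 * config$motility), n, n_harm)
      coef_b <- coef_b + matrix(rnorm(n * n_harm, 0, 0.3 * config$motility), n, n_harm)
      coef_a <- pmin(pmax(coef_a, -0.25), 0.25)
      coef_b <- pmin(pmax(coef_b, -0.25), 0.25)
    }
    frame_masks <- vector("list", n)
    reporter <- matrix(0, fs[1], fs[2])
    probe <- matrix(0, fs[1], fs[2])
    for (i in seq_len(n)) {
      m <- rasterize_cell(
        centres[i, 1], centres[i, 2], radii[i],
        coef_a[i, ], coef_b[i, ], fs
      )
      frame_masks[[i]] <- m
      reporter[m] <- reporter[m] + config$cell_intensity
      if (resorbing[i] && config$secretion > 0) {
        footprint <- as.matrix(EBImage::erode(m * 1, ring)) > 0
        probe[footprint] <- probe[footprint] +
          config$secretion * config$cell_intensity
      }
    }
    masks[[t]] <- frame_masks
    data[t, 1, , ] <- reporter + config$background_level
    data[t, 2, , ] <- probe + config$background_level
    data[t, 3, , ] <- 30 * bone + config$background_level
  }
  list(
    data = data,
    channels = c("reporter", "ph_probe", "bone"),
    masks = masks,
    resorbing_flags = resorbing
  )
}

#' Simulate a multi-channel time-lapse stack with ground truth
#'
#' Renders `n_cells` star-convex osteoclast-like cells whose boundaries and
#' centroids evolve by a random walk with step magnitude proportional to
#' `motility`. The reporter channel shows all cells; resorbing cells deposit
#' pH-probe intensity (amplitude proportional to `secretion`) within their
#' footprint eroded by 1 px; a static smooth field stands in for the bone
#' (SHG) channel. Gaussian noise of sd `noise_sd` is added to every channel
#' and clipped at zero.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#' \describe{
#'   \item{stack}{an [image_stack()] with channels reporter, ph_probe, bone}
#'   \item{truth}{ground truth: `masks` (per frame, a list of per-cell
#'     logical masks), `resorbing_flags`, and the `config`}
#' }
#' @export
#' @examples
#' sim <- simulate_timelapse(simulation_config(
#'   field_size = c(96, 96), n_cells = 3, n_frames = 3, cell_radius_mean = 8
#' ))
#' sim$stack
simulate_timelapse <- function(config) {
  clean <- simulate_clean(config)
  data <- clean$data
  if (config$noise_sd > 0) {
    data <- data + array(rnorm(length(data), 0, config$noise_sd), dim(data))
  }
  data[data < 0] <- 0
  stack <- image_stack(
    data, clean$channels,
    pixel_size = config$pixel_size, frame_interval = config$frame_interval
  )
  truth <- structure(
    list(
      masks = clean$masks,
      resorbing_flags = clean$resorbing_flags,
      config = config
    ),
    class = "ground_truth"
  )
  list(stack = stack, truth = truth)
}

#' Union of ground-truth cell masks in one frame
#'
#' @param truth A `ground_truth` object from [simulate_timelapse()].
#' @param frame Frame index.
#' @param cells Optional integer subset of cells; defaults to all.
#' @return A logical Y x X matrix.
#' @export
truth_mask <- function(truth, frame, cells = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  fm <- truth$masks[[frame]]
  if (is.null(cells)) cells <- seq_along(fm)
  out <- Reduce(`|`, fm[cells])
  out
}
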