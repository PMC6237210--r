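#' Endmember reference spectra
#'
#' A detector-channels x endmembers matrix of nonnegative reference spectra,
#' as commercial spectral-unmixing software is configured. One endmember must
#' be named `"autofluorescence"`; the remaining columns are the fluorophore
#' channels recovered downstream.
#'
#' @param spectra Numeric matrix, detector channels in rows, endmembers in
#'   columns; all entries >= 0, every column with positive norm, full column
#'   rank.
#' @param endmember_names Character vector of column names; must contain
#'   `"autofluorescence"`.
#' @return An `endmember_matrix` object.
#' @export
#' @examples
#' em <- endmember_matrix(
#'   rbind(c(1, 0, 0.4), c(0, 1, 0.6)),
#'   c("reporter", "ph_probe", "autofluorescence")
#' )
endmember_matrix <- function(spectra, endmember_names) {
  spectra <- as.matrix(spectra)
  if (any(!is.finite(spectra)) || any(spectra < 0)) {
    abort("Endmember spectra must be finite and nonnegative.")
  }
  if (length(endmember_names) != ncol(spectra)) {
    abort("One name per endmember column is required.")
  }
  if (!"autofluorescence" %in% endmember_names) {
    abort("One endmember must be named 'autofluorescence'.")
  }
  norms <- sqrt(colSums(spectra^2))
  if (any(norms <= 0)) abort("Every endmember column needs positive norm.")
  rk <- qr(spectra)$rank
  if (rk < ncol(spectra)) {
    abort(sprintf(
      "Endmember matrix is rank deficient (rank %d < %d endmembers; condition number %.3g).",
      rk, ncol(spectra), kappa(spectra)
    ))
  }
  colnames(spectra) <- endmember_names
  structure(
    list(spectra = spectra, endmember_names = endmember_names),
    class = "endmember_matrix"
  )
}

#' Default endmember matrix for the simulated instrument
#'
#' Six detector bands, as on a multi-anode spectral detector: reporter, pH
#' probe and bone each dominate their own band with modest spillover into a
#' neighbour, while autofluorescence is spectrally broad and overlaps all of
#' them — the situation linear unmixing is meant to resolve. The
#' overdetermined design (more bands than endmembers) keeps the unmixing
#' noise gain of every fluorophore channel below 1.3.
#'
#' @return An `endmember_matrix` with endmembers reporter, ph_probe, bone,
#'   autofluorescence.
#' @export
default_endmembers <- function() {
  endmember_matrix(
    cbind(
      reporter         = c(0.90, 0.10, 0.00, 0.00, 0.00, 0.00),
      ph_probe         = c(0.00, 0.10, 0.85, 0.05, 0.00, 0.00),
      bone             = c(0.00, 0.00, 0.00, 0.05, 0.85, 0.10),
      autofluorescence = c(0.20, 0.30, 0.10, 0.30, 0.05, 0.05)
    ),
    c("reporter", "ph_probe", "bone", "autofluorescence")
  )
}

#' Simulate a raw multi-detector spectral stack
#'
#' Renders the noise-free clean channels of `config`, adds a smooth
#' autofluorescence abundance map (amplitude `autofluorescence_weight *
#' cell_intensity`), and mixes them into detector channels as a per-pixel
#' linear combination with the endmember spectra, plus clipped Gaussian
#' noise.
#'
#' @param config A [simulation_config()].
#' @param endmembers An [endmember_matrix()] whose non-autofluorescence
#'   endmembers match the simulator's clean channels (reporter, ph_probe,
#'   bone) in order.
#' @return A list: `raw` (detector-channel [image_stack()]), `clean`
#'   (noise-free true-channel stack), `abundance_truth` (stack of true
#'   abundances including autofluorescence), `endmembers`.
#' @export
simulate_spectral <- function(config, endmembers = default_endmembers()) {
  stopifnot(inherits(endmembers, "endmember_matrix"))
  clean <- simulate_clean(config)
  others <- setdiff(endmembers$endmember_names, "autofluorescence")
  if (!identical(others, clean$channels)) {
    abort(sprintf(
      "Endmembers must be the clean channels (%s) plus 'autofluorescence'; got %s.",
      paste(clean$channels, collapse = ", "),
      paste(endmembers$endmember_names, collapse = ", ")
    ))
  }
  fs <- config$field_size
  nf <- config$n_frames
  af <- config$autofluorescence_weight * config$cell_intensity * smooth_field(fs, grain = 24L, sigma = 8)
  n_det <- nrow(endmembers$spectra)
  n_end <- ncol(endmembers$spectra)

  truth <- array(0, c(nf, n_end, fs[1], fs[2]))
  raw <- array(0, c(nf, n_det, fs[1], fs[2]))
  S <- endmembers$spectra
  for (t in seq_len(nf)) {
    ab <- matrix(0, n_end, fs[1] * fs[2])
    for (c in seq_along(clean$channels)) ab[c, ] <- as.vector(clean$data[t, c, , ])
    ab[n_end, ] <- as.vector(af)
    mixed <- S %*% ab
    for (d in seq_len(n_det)) raw[t, d, , ] <- matrix(mixed[d, ], fs[1], fs[2])
    for (e in seq_len(n_end)) truth[t, e, , ] <- matrix(ab[e, ], fs[1], fs[2])
  }
  if (config$noise_sd > 0) {
    raw <- raw + array(rnorm(length(raw), 0, config$noise_sd), dim(raw))
  }
  raw[raw < 0] <- 0
  list(
    raw = image_stack(raw, paste0("det", seq_len(n_det)),
      pixel_size = config$pixel_size, frame_interval = config$frame_interval
    ),
    clean = image_stack(clean$data, clean$channels,
      pixel_size = config$pixel_size, frame_interval = config$frame_interval
    ),
    abundance_truth = image_stack(truth, endmembers$endmember_names,
      pixel_size = config$pixel_size, frame_interval = config$frame_interval
    ),
    endmembers = endmembers
  )
}

# Per-pixel nonnegative least squares against the endmember spectra.
# Fast path: the unconstrained least-squares solution, computed for all
# pixels in one matrix solve; pixels where it goes negative are re-solved
# with the active-set NNLS of pracma::lsqnonneg.
nnls_pixels <- function(S, P) {
  X <- qr.solve(S, P)
  bad <- which(matrixStats_colAnys_neg(X))
  for (j in bad) {
    X[, j] <- pracma::lsqnonneg(S, P[, j])$x
  }
  X[X < 0] <- 0  # clamp numerical dust from the fast path
  X
}

matrixStats_colAnys_neg <- function(X, tol = 1e-9) {
  colSums(X < -tol) > 0
}

#' Linear spectral unmixing by per-pixel nonnegative least squares
#'
#' Solves, for every pixel, `min || S a - p ||` subject to `a >= 0`, where
#' `S` holds the endmember spectra and `p` the detector intensities, and
#' returns the abundance maps. Dropping the `"autofluorescence"` abundance
#' yields unmixed images with autofluorescence excluded.
#'
#' @param raw A detector-channel [image_stack()].
#' @param endmembers An [endmember_matrix()] with one spectrum row per
#'   detector channel of `raw`.
#' @param drop_autofluorescence If `TRUE` (default), the returned stack
#'   contains only the non-autofluorescence abundances.
#' @return An abundance [image_stack()] with endmember names as channels.
#' @export
#' @examples
#' em <- endmember_matrix(
#'   rbind(c(1, 0.3), c(0, 0.7)), c("reporter", "autofluorescence")
#' )
#' raw <- image_stack(array(c(1, 0), c(1, 2, 1, 1)), c("det1", "det2"))
#' unmix(raw, em)
unmix <- function(raw, endmembers, drop_autofluorescence = TRUE) {
  stopifnot(inherits(raw, "image_stack"), inherits(endmembers, "endmember_matrix"))
  S <- endmembers$spectra
  d <- dim(raw$data)
  if (d[2] != nrow(S)) {
    abort(sprintf(
      "Raw stack has %d detector channels but endmember spectra have %d rows.",
      d[2], nrow(S)
    ))
  }
  n_end <- ncol(S)
  out <- array(0, c(d[1], n_end, d[3], d[4]))
  for (t in seq_len(d[1])) {
    P <- matrix(0, d[2], d[3] * d[4])
    for (c in seq_len(d[2])) P[c, ] <- as.vector(raw$data[t, c, , ])
    A <- nnls_pixels(S, P)
    for (e in seq_len(n_end)) out[t, e, , ] <- matrix(A[e, ], d[3], d[4])
  }
  ab <- image_stack(out, endmembers$endmember_names,
    pixel_size = raw$pixel_size, frame_interval = raw$frame_interval
  )
  if (drop_autofluorescence) {
    keep <- which(ab$channels != "autofluorescence")
    ab <- image_stack(ab$data[, keep, , , drop = FALSE], ab$channels[keep],
      pixel_size = ab$pixel_size, frame_interval = ab$frame_interval
    )
  }
  ab
}

#' Read an endmember matrix from CSV
#'
#' Rows are detector channels, columns endmembers, header row holds the
#' endmember names.
#' @param path CSV path.
#' @return An [endmember_matrix()].
#' @export
read_endmembers_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  endmember_matrix(as.matrix(df), colnames(df))
}

#' Write an endmember matrix to CSV
#' @param endmembers An [endmember_matrix()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_endmembers_csv <- function(endmembers, path) {
  utils::write.csv(as.data.frame(endmembers$spectra), path, row.names = FALSE)
  invisible(path)
}
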