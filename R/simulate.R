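#' Rotate a cubic volume by a uniformly random 3D rotation
#'
#' Draws a rotation uniformly from SO(3) (via a normalized Gaussian
#' quaternion) and resamples the volume on the same grid with trilinear
#' interpolation, zero outside the grid. Because shapes are generated well
#' inside the grid, total mass is conserved up to interpolation loss.
#'
#' @param volume cubic 3D array.
#' @param seed integer seed controlling the rotation draw.
#' @param identity if `TRUE`, skip the random draw and return the input
#'   unchanged (useful for degenerate-task construction).
#' @return rotated volume, same dimensions.
#' @export
rotate_random <- function(volume, seed = NULL, identity = FALSE) {
  d <- dim(volume)
  if (length(d) != 3 || length(unique(d)) != 1)
    .fscc_stop("volume must be a cubic 3D array")
  if (identity) return(volume)
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- quaternion_to_matrix(q)
  rotate_volume(volume, R)
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a cubic volume by a given rotation matrix
#'
#' @param volume cubic 3D array.
#' @param R 3x3 rotation matrix.
#' @return resampled volume (trilinear interpolation, zero padding).
#' @export
rotate_volume <- function(volume, R) {
  d <- dim(volume)
  if (length(d) != 3 || length(unique(d)) != 1)
    .fscc_stop("volume must be a cubic 3D array")
  g <- d[1]
  ctr <- (g + 1) / 2
  ax <- seq_len(g) - ctr
  # coordinates of every output voxel (columns of a 3 x V matrix)
  P <- rbind(rep(ax, times = g * g),
             rep(rep(ax, each = g), times = g),
             rep(ax, each = g * g))
  S <- crossprod(R, P)  # source = R^{-1} p, R orthonormal
  trilinear_sample(volume, S + ctr)
}

# Sample `volume` at real-valued 1-based coordinates (3 x V matrix); zero
# outside the grid.
trilinear_sample <- function(volume, S) {
  g <- dim(volume)[1]
  x0 <- floor(S[1, ]); y0 <- floor(S[2, ]); z0 <- floor(S[3, ])
  fx <- S[1, ] - x0;   fy <- S[2, ] - y0;   fz <- S[3, ] - z0
  acc <- numeric(ncol(S))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx == 1) fx else 1 - fx) *
         (if (dy == 1) fy else 1 - fy) *
         (if (dz == 1) fz else 1 - fz)
    ok <- xi >= 1 & xi <= g & yi >= 1 & yi <= g & zi >= 1 & zi <= g & w > 0
    if (any(ok)) {
      idx <- xi[ok] + g * (yi[ok] - 1) + g * g * (zi[ok] - 1)
      acc[ok] <- acc[ok] + w[ok] * volume[idx]
    }
  }
  array(acc, dim = dim(volume))
}

#' Add Gaussian noise to reach a target signal-to-noise ratio
#'
#' SNR follows the variance-ratio convention used for simulated tomography
#' benchmarks: `snr = var(signal) / var(noise)`. The injected noise is
#' zero-mean Gaussian, rescaled so its empirical variance equals
#' `var(volume) / target_snr` exactly, making the realized SNR match the
#' target for any grid size and seed.
#'
#' @param volume 3D array with nonzero variance.
#' @param target_snr positive variance ratio; `Inf` returns the volume
#'   unchanged.
#' @param seed integer seed for the noise draw.
#' @return `volume + noise`.
#' @export
add_noise_to_snr <- function(volume, target_snr, seed = NULL) {
  if (!is.finite(target_snr)) return(volume)
  if (target_snr <= 0) .fscc_stop("target_snr must be positive")
  vs <- var(as.vector(volume))
  if (vs == 0) .fscc_stop("volume is constant: SNR undefined")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- rnorm(length(volume))
  n <- n - mean(n)
  n <- n * sqrt(vs / target_snr) / sd(n)  # exact realized noise variance
  volume + array(n, dim = dim(volume))
}

#' Suppress the missing-wedge region of Fourier space
#'
#' Emulates the anisotropic distortion of limited-tilt tomography: Fourier
#' coefficients whose (kx, kz)-plane direction lies more than
#' `wedge_half_angle` degrees from the kx axis (the double wedge around the
#' beam axis kz) are zeroed; the tilt axis is y. `wedge_half_angle = 90`
#' leaves the volume untouched.
#'
#' @param volume cubic 3D array.
#' @param wedge_half_angle degrees in (0, 90].
#' @return real volume after inverse transform.
#' @export
apply_missing_wedge <- function(volume, wedge_half_angle) {
  d <- dim(volume)
  if (length(d) != 3 || length(unique(d)) != 1)
    .fscc_stop("volume must be a cubic 3D array")
  if (wedge_half_angle <= 0 || wedge_half_angle > 90)
    .fscc_stop("wedge_half_angle must be in (0, 90]")
  if (wedge_half_angle == 90) return(volume)
  g <- d[1]
  mask <- missing_wedge_mask(g, wedge_half_angle)
  F <- fft(volume)
  F[mask] <- 0
  Re(fft(F, inverse = TRUE)) / length(volume)
}

# Logical array: TRUE where the Fourier coefficient falls in the missing
# double wedge. Frequencies follow the DFT layout of stats::fft.
missing_wedge_mask <- function(g, wedge_half_angle) {
  k <- c(0:floor(g / 2), -(ceiling(g / 2) - 1):-1)[seq_len(g)]
  KX <- array(rep(k, times = g * g), dim = c(g, g, g))
  KZ <- aperm(KX, c(3, 2, 1))
  psi <- atan2(abs(KZ), abs(KX)) * 180 / pi
  psi > wedge_half_angle
}

#' Simulator configuration
#'
#' Bundles and validates the parameters of the synthetic subtomogram
#' generator. One subtomogram is produced by randomly rotating its class's
#' density map, adding Gaussian noise at `target_snr`, and (optionally)
#' applying a missing wedge.
#'
#' @param n_classes number of shape classes; must equal `length(shapes)`.
#' @param grid_size voxels per edge (default 32, the standard extracted
#'   subtomogram size).
#' @param shapes list of shape specifications (see
#'   [generate_shape_density()]); defaults to [default_shape_set()].
#' @param samples_per_class subtomograms generated per class (>= 1).
#' @param target_snr variance-ratio SNR of the generated volumes. The
#'   default 0.5 keeps small CPU experiments informative; the hostile
#'   benchmark value 0.02 is available by setting it here.
#' @param wedge_half_angle degrees in (0, 90]; 90 (default) disables the
#'   missing wedge.
#' @param seed integer master seed; fixed seed gives bit-identical datasets.
#' @return an object of class `fscc_sim_config`.
#' @export
simulator_config <- function(n_classes, grid_size = 32,
                             shapes = default_shape_set(n_classes, grid_size),
                             samples_per_class = 10, target_snr = 0.5,
                             wedge_half_angle = 90, seed = 1) {
  if (n_classes != length(shapes))
    .fscc_stop("n_classes must equal the number of shape specifications")
  if (samples_per_class < 1) .fscc_stop("samples_per_class must be >= 1")
  if (!is.finite(target_snr) && !is.infinite(target_snr))
    .fscc_stop("target_snr must be positive (possibly Inf)")
  if (is.finite(target_snr) && target_snr <= 0)
    .fscc_stop("target_snr must be positive")
  if (wedge_half_angle <= 0 || wedge_half_angle > 90)
    .fscc_stop("wedge_half_angle must be in (0, 90]")
  structure(list(n_classes = as.integer(n_classes),
                 grid_size = as.integer(grid_size), shapes = shapes,
                 samples_per_class = as.integer(samples_per_class),
                 target_snr = target_snr,
                 wedge_half_angle = wedge_half_angle,
                 seed = as.integer(seed)),
            class = "fscc_sim_config")
}

#' Generate a labeled synthetic subtomogram dataset
#'
#' @param config an [simulator_config()] object.
#' @return an object of class `fscc_dataset`: list with `volumes` (list of
#'   cubic arrays), `labels` (integer class ids `0..n_classes-1`), and the
#'   generating `config`.
#' @examples
#' ds <- build_synthetic_dataset(simulator_config(3, grid_size = 16,
#'                                                samples_per_class = 2))
#' table(ds$labels)
#' @export
build_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "fscc_sim_config"))
  set.seed(config$seed)
  densities <- lapply(config$shapes, generate_shape_density,
                      grid_size = config$grid_size)
  n <- config$n_classes * config$samples_per_class
  volumes <- vector("list", n)
  labels <- integer(n)
  i <- 0
  for (cl in seq_len(config$n_classes)) {
    for (s in seq_len(config$samples_per_class)) {
      i <- i + 1
      v <- rotate_random(densities[[cl]])
      v <- add_noise_to_snr(v, config$target_snr)
      if (config$wedge_half_angle < 90)
        v <- apply_missing_wedge(v, config$wedge_half_angle)
      volumes[[i]] <- v
      labels[i] <- cl - 1L
    }
  }
  structure(list(volumes = volumes, labels = labels, config = config),
            class = "fscc_dataset")
}

#' @export
print.fscc_dataset <- function(x, ...) {
  cat(sprintf("Synthetic subtomogram dataset: %d volumes (%d^3), %d classes\n",
              length(x$volumes), x$config$grid_size, x$config$n_classes))
  cat(sprintf("  SNR %.3g, wedge half-angle %g deg, seed %d\n",
              x$config$target_snr, x$config$wedge_half_angle, x$config$seed))
  invisible(x)
}
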