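#' Image-formation parameters
#'
#' Parameters of the synthetic confocal acquisition: voxel size, an
#' anisotropic Gaussian point-spread function, a linear photon budget, and
#' a standard camera noise model (Poisson shot noise on signal plus
#' background, additive Gaussian read noise, clipping and integer
#' quantization to the detector bit depth).
#'
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @param psf_sigma `(lateral, axial)` Gaussian PSF sigma in µm; axial must
#'   be at least lateral.
#' @param photons_per_unit Expected photons collected from one unit of
#'   expression in the reporter channel (signal scale).
#' @param background_level Mean background (counts per voxel).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param bit_depth Detector bit depth, 8 or 16.
#' @param seed Integer seed fixing all noise; the same seed reproduces a
#'   rendered stack bit-identically.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(voxel_size = c(0.3, 0.1, 0.1),
                           psf_sigma = c(0.12, 0.35),
                           photons_per_unit = 3e7,
                           background_level = 10,
                           read_noise_sd = 1.5,
                           bit_depth = 16L,
                           seed = 1L) {
  if (any(voxel_size <= 0)) stop("voxel_size must be positive", call. = FALSE)
  if (psf_sigma[2] < psf_sigma[1]) {
    stop("axial PSF sigma must be >= lateral sigma", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (photons_per_unit < 0 || background_level < 0 || read_noise_sd < 0) {
    stop("photon and noise parameters must be non-negative", call. = FALSE)
  }
  structure(list(voxel_size = voxel_size, psf_sigma = psf_sigma,
                 photons_per_unit = photons_per_unit,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "imaging_params")
}

#' @export
print.imaging_params <- function(x, ...) {
  cat(sprintf("Imaging: voxels (%.3g, %.3g, %.3g) um, PSF sigma lat %.3g / ax %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$psf_sigma[1], x$psf_sigma[2]))
  cat(sprintf("  %.3g photons/unit, background %.3g, read noise %.3g, %d bit, seed %d\n",
              x$photons_per_unit, x$background_level, x$read_noise_sd,
              x$bit_depth, x$seed))
  invisible(x)
}

# Truncated, renormalized (unit-sum) 1-D Gaussian kernel; sigma in voxels.
gauss_kernel <- function(sigma_vox) {
  r <- ceiling(3 * sigma_vox) + 1
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# Convolve a [z, y, x] array along one axis with a unit-sum kernel via a
# banded matrix product (zero boundary: callers keep signal one kernel
# radius away from the stack faces so total intensity is conserved).
conv_axis <- function(a, axis, kern) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kern) - 1L) / 2L
  B <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- kern[off + r + 1L]
  }
  if (axis == 1L) {
    out <- B %*% matrix(a, n, d[2] * d[3])
    dim(out) <- d
    out
  } else if (axis == 3L) {
    out <- matrix(a, d[1] * d[2], n) %*% t(B)
    dim(out) <- d
    out
  } else {
    a2 <- aperm(a, c(2L, 1L, 3L))
    out <- B %*% matrix(a2, n, d[1] * d[3])
    dim(out) <- c(n, d[1], d[3])
    aperm(out, c(2L, 1L, 3L))
  }
}

#' Apply an anisotropic Gaussian PSF to a voxel array
#'
#' Separable Gaussian blur with a truncated, renormalized (unit-sum)
#' kernel per axis.  Signal whose support stays one kernel radius away
#' from the stack boundary is conserved exactly.
#'
#' @param a Numeric array `[z, y, x]`.
#' @param psf_sigma `(lateral, axial)` sigma in µm.
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @param lateral_only If `TRUE`, blur only in y and x (single-plane
#'   acquisition mode).
#' @return Blurred array of the same dimensions.
#' @export
apply_psf <- function(a, psf_sigma, voxel_size, lateral_only = FALSE) {
  sig_vox <- c(psf_sigma[2] / voxel_size[1],   # axial along z
               psf_sigma[1] / voxel_size[2],
               psf_sigma[1] / voxel_size[3])
  if (lateral_only) sig_vox[1] <- 0
  for (ax in 1:3) {
    if (sig_vox[ax] > 1e-8 && dim(a)[ax] > 1L) {
      a <- conv_axis(a, ax, gauss_kernel(sig_vox[ax]))
    }
  }
  a
}

# Camera model: Poisson(signal + background) + N(0, read_noise), clipped to
# the detector range and quantized to integers.  Assumes the RNG state has
# been set by the caller.
apply_noise <- function(signal, imaging) {
  lam <- signal + imaging$background_level
  counts <- rpois(length(lam), lambda = lam)
  if (imaging$read_noise_sd > 0) {
    counts <- counts + rnorm(length(lam), sd = imaging$read_noise_sd)
  }
  top <- 2^imaging$bit_depth - 1
  counts <- round(pmin(pmax(counts, 0), top))
  dim(counts) <- dim(signal)
  counts
}
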