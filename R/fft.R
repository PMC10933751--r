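# Centered, unitary Fourier transforms.
#
# Every k-space <-> image-space mapping in this package uses the same
# convention: the DC sample sits at the center of the grid
# (0-based index floor(n/2)) and both directions are scaled by
# 1/sqrt(Ny*Nz) so that F is unitary.  A unitary F keeps the SENSE
# operator norm-bounded and makes singular-value thresholds scale-stable.
#
# For even grid sizes the fftshift/ifftshift sandwich is algebraically a
# checkerboard sign modulation, fftshift(fft(ifftshift(x))) =
# s * C .* fft(C .* x) with C[i,j] = (-1)^(i+j) and s = (-1)^(Ny/2+Nz/2),
# which is much cheaper than four index permutations; odd sizes fall back
# to explicit circular shifts.

.fft_cache <- new.env(parent = emptyenv())

.circshift_idx <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

.fftshift2 <- function(x) {
  d <- dim(x)
  iy <- .circshift_idx(d[1], d[1] %/% 2L)
  iz <- .circshift_idx(d[2], d[2] %/% 2L)
  if (length(d) == 2L) x[iy, iz, drop = FALSE] else x[iy, iz, , drop = FALSE]
}

.ifftshift2 <- function(x) {
  d <- dim(x)
  iy <- .circshift_idx(d[1], -(d[1] %/% 2L))
  iz <- .circshift_idx(d[2], -(d[2] %/% 2L))
  if (length(d) == 2L) x[iy, iz, drop = FALSE] else x[iy, iz, , drop = FALSE]
}

# checkerboard plane scaled by 1/sqrt(N); the center-shift sign s is
# applied once by the caller
.checkerboard <- function(ny, nz) {
  key <- paste0("cb", ny, "x", nz)
  cb <- .fft_cache[[key]]
  if (is.null(cb)) {
    cb <- outer((-1)^(seq_len(ny) - 1L), (-1)^(seq_len(nz) - 1L)) /
      sqrt(ny * nz)
    .fft_cache[[key]] <- cb
  }
  cb
}

# Batched un-centered 2-D FFT over the first two dimensions of a 3-D array
# (or a plain matrix).  Uses two mvfft() passes so a whole coil/group stack
# is transformed in two C-level calls.
.fft2_raw <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (length(d) == 2L) {
    return(stats::fft(x, inverse = inverse))
  }
  a <- stats::mvfft(matrix(x, d[1], d[2] * d[3]), inverse = inverse)
  b <- aperm(array(a, d), c(2L, 1L, 3L))
  cc <- stats::mvfft(matrix(b, d[2], d[1] * d[3]), inverse = inverse)
  aperm(array(cc, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

.fft2c_impl <- function(x, inverse) {
  d <- dim(x)
  if (d[1] %% 2L == 0L && d[2] %% 2L == 0L) {
    cb <- .checkerboard(d[1], d[2])
    s <- (-1)^((d[1] %/% 2L) + (d[2] %/% 2L)) * sqrt(d[1] * d[2])
    if (length(d) == 3L) cb <- as.vector(cb)   # recycles across slices
    return(cb * .fft2_raw(cb * x, inverse = inverse) * s)
  }
  .fftshift2(.fft2_raw(.ifftshift2(x), inverse = inverse)) / sqrt(d[1] * d[2])
}

#' Centered unitary 2-D Fourier transform
#'
#' Transforms image space to k-space (`fft2c`) or k-space to image space
#' (`ifft2c`) with the DC component at the grid center and unitary
#' (`1/sqrt(N)`) normalization in both directions.  A matrix is transformed
#' as one plane; a 3-D array is treated as a stack of planes (third
#' dimension = coil or shot group) and transformed slice-wise.
#'
#' @param x Complex (or numeric) matrix `Ny x Nz`, or array `Ny x Nz x K`.
#' @return Complex array of the same shape.
#' @examples
#' x <- matrix(rnorm(16 * 12), 16, 12)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) .fft2c_impl(x, inverse = FALSE)

#' @rdname fft2c
#' @export
ifft2c <- function(x) .fft2c_impl(x, inverse = TRUE)
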