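# Temporal-SNR and frequency-domain metrics for magnitude time series.

#' Voxelwise temporal SNR map
#'
#' tSNR = temporal mean / temporal standard deviation (N-1 denominator) of
#' a magnitude time series.  Voxels with zero temporal variance are
#' flagged invalid (tSNR = NA) and excluded from summaries.
#'
#' @param series Numeric `Ny x Nz x T` magnitude array (time last); at
#'   least 3 frames.
#' @param mask Optional logical `Ny x Nz` matrix restricting the map.
#' @return Object of class `tsnr_map`: list with `mean`, `sd`, `tsnr`
#'   (NA where invalid), `valid` (logical matrix).
#' @export
tsnr_map <- function(series, mask = NULL) {
  d <- dim(series)
  if (length(d) != 3L) .stopf("'series' must be an Ny x Nz x T array")
  if (d[3] < 3L) .stopf("tSNR needs at least 3 frames (got %d)", d[3])
  m <- matrix(series, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (d[3] - 1))
  valid <- sdv > 0
  tsnr <- ifelse(valid, mu / sdv, NA_real_)
  if (!is.null(mask)) {
    valid <- valid & as.vector(mask)
    tsnr[!as.vector(mask)] <- NA_real_
  }
  structure(list(mean = matrix(mu, d[1], d[2]),
                 sd = matrix(sdv, d[1], d[2]),
                 tsnr = matrix(tsnr, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2])),
            class = "tsnr_map")
}

#' @export
print.tsnr_map <- function(x, ...) {
  cat(sprintf("<tsnr_map> %dx%d, %d valid voxel(s), mean tSNR %.2f over valid voxels\n",
              nrow(x$tsnr), ncol(x$tsnr), sum(x$valid),
              mean(x$tsnr[x$valid])))
  invisible(x)
}

#' Mean tSNR over a mask
#'
#' Arithmetic mean of the tSNR map over valid voxels inside the mask.
#'
#' @param map A [tsnr_map()].
#' @param mask Optional logical `Ny x Nz` matrix (default: all valid
#'   voxels).
#' @return Scalar mean tSNR.
#' @export
mean_tsnr <- function(map, mask = NULL) {
  if (!inherits(map, "tsnr_map")) .stopf("'map' must be a tsnr_map")
  sel <- map$valid
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) .stopf("no valid voxels inside the mask")
  mean(map$tsnr[sel])
}

#' Mean power spectrum over a mask
#'
#' Per-voxel mean-removed FFT magnitude squared (`|X_k|^2 / T`), averaged
#' over the masked voxels.  No windowing by default (set `window =
#' "hann"` to taper).  With `one_sided = TRUE` (default) only bins up to
#' the Nyquist frequency `1 / (2 TR)` are returned.
#'
#' @param series Numeric `Ny x Nz x T` magnitude array; at least 8 frames.
#' @param mask Logical `Ny x Nz` matrix of voxels to average.
#' @param TR Volume repetition time in seconds.
#' @param one_sided Return only frequencies up to Nyquist (default TRUE).
#' @param window `"none"` (default) or `"hann"`.
#' @return List with `freq` (Hz) and `power`.
#' @export
mean_power_spectrum <- function(series, mask, TR, one_sided = TRUE,
                                window = c("none", "hann")) {
  window <- match.arg(window)
  d <- dim(series)
  if (length(d) != 3L) .stopf("'series' must be an Ny x Nz x T array")
  if (d[3] < 8L) .stopf("power spectrum needs at least 8 frames")
  if (!any(mask)) .stopf("empty mask")
  m <- matrix(series, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
  m <- m - rowMeans(m)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(d[3]) / (d[3] + 1)))
    m <- m * rep(w, each = nrow(m))
  }
  Fm <- stats::mvfft(t(m))                       # T x voxels
  power <- rowMeans(Mod(Fm)^2) / d[3]
  freq <- (seq_len(d[3]) - 1) / (d[3] * TR)
  if (one_sided) {
    keep <- seq_len(d[3] %/% 2 + 1L)
    power <- power[keep]; freq <- freq[keep]
  }
  list(freq = freq, power = power)
}

#' Support mask from a mean magnitude image
#'
#' Voxels whose mean magnitude is at least `fraction` times the image
#' maximum.  An all-zero image yields an empty mask.
#'
#' @param mean_image Numeric (or complex; magnitude is taken) matrix.
#' @param fraction Threshold fraction (default 0.1); 0 keeps the full
#'   grid.
#' @return Logical matrix.
#' @export
support_mask <- function(mean_image, fraction = 0.1) {
  a <- Mod(mean_image)
  mx <- max(a)
  if (mx == 0) return(matrix(FALSE, nrow(a), ncol(a)))
  a >= fraction * mx
}
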