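# SENSE encoding operator E = M.F.S.F^-1 and friends.
#
# X lives on the k-space grid, one single-("virtual")-coil plane per shot
# group; Y is the measured multi-coil k-space per shot group.  All Fourier
# transforms are centered and unitary (see fft.R), which makes the adjoint
# below exact under the plain Euclidean complex inner products.

.check_maps <- function(maps, Ny, Nz) {
  d <- dim(maps)
  if (is.null(d) || length(d) == 2L) {
    maps <- array(maps, c(dim(maps) %||% length(maps), 1L))
    d <- dim(maps)
  }
  if (d[1] != Ny || d[2] != Nz)
    .stopf("coil maps are %dx%d but the grid is %dx%d", d[1], d[2], Ny, Nz)
  maps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_group_stack <- function(X) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  if (length(dim(X)) != 3L) .stopf("expected an Ny x Nz x G array")
  X
}

#' SENSE forward operator for multi-shot-group k-space
#'
#' Applies `E = M . F . S . F^-1` per shot group: inverse-transform the
#' group's virtual-coil k-space to image space, weight by each coil
#' sensitivity, forward-transform, and zero the samples the group did not
#' acquire.
#'
#' @param X Complex `Ny x Nz x G` array (or matrix for `G = 1`): one
#'   k-space plane per shot group.
#' @param maps Complex `Ny x Nz x C` coil sensitivity array.
#' @param masks 0/1 `Ny x Nz x G` array of per-group sampling masks (or
#'   matrix for `G = 1`).
#' @return Complex `Ny x Nz x C x G` array of masked multi-coil k-space.
#' @seealso [sense_adjoint()], [coil_combine_kspace()]
#' @export
sense_forward <- function(X, maps, masks) {
  X <- .as_group_stack(X); masks <- .as_group_stack(masks)
  d <- dim(X); Ny <- d[1]; Nz <- d[2]; G <- d[3]
  maps <- .check_maps(maps, Ny, Nz); C <- dim(maps)[3]
  if (!all(dim(masks) == c(Ny, Nz, G)))
    .stopf("masks must be %dx%dx%d", Ny, Nz, G)
  imgs <- ifft2c(X)                                   # Ny x Nz x G
  # big stack ordered (coil fastest, then group)
  big <- imgs[, , rep(seq_len(G), each = C), drop = FALSE] *
    as.vector(maps[, , rep(seq_len(C), times = G), drop = FALSE])
  k <- fft2c(big)
  k <- k * as.vector(masks[, , rep(seq_len(G), each = C), drop = FALSE])
  array(k, c(Ny, Nz, C, G))
}

#' SENSE adjoint operator
#'
#' Exact adjoint of [sense_forward()] under the Euclidean complex inner
#' product: mask, inverse-transform each coil, weight by conjugate
#' sensitivities, sum over coils, forward-transform.
#'
#' @param Y Complex `Ny x Nz x C x G` array of multi-coil k-space.
#' @inheritParams sense_forward
#' @return Complex `Ny x Nz x G` array.
#' @export
sense_adjoint <- function(Y, maps, masks) {
  masks <- .as_group_stack(masks)
  d <- dim(Y)
  if (length(d) == 3L) { Y <- array(Y, c(d, 1L)); d <- dim(Y) }
  if (length(d) != 4L) .stopf("'Y' must be an Ny x Nz x C x G array")
  Ny <- d[1]; Nz <- d[2]; C <- d[3]; G <- d[4]
  maps <- .check_maps(maps, Ny, Nz)
  if (dim(maps)[3] != C) .stopf("coil count mismatch between Y and maps")
  if (!all(dim(masks) == c(Ny, Nz, G)))
    .stopf("masks must be %dx%dx%d", Ny, Nz, G)
  Ym <- array(Y, c(Ny, Nz, C * G)) *
    as.vector(masks[, , rep(seq_len(G), each = C), drop = FALSE])
  imgs <- ifft2c(Ym)
  w <- imgs * as.vector(Conj(maps[, , rep(seq_len(C), times = G),
                                  drop = FALSE]))
  # sum over coils within each group
  per_group <- array(0i, c(Ny, Nz, G))
  w <- array(w, c(Ny * Nz, C, G))
  for (g in seq_len(G))
    per_group[, , g] <- matrix(rowSums(matrix(w[, , g], Ny * Nz, C)), Ny, Nz)
  fft2c(per_group)
}

#' Coil-combine multi-coil k-space to a single virtual coil
#'
#' Image-space matched-filter combination: weight each coil image by the
#' conjugate sensitivity, sum, and normalize by the sum of squared
#' sensitivity magnitudes (floored at `1e-12 * max|S|^2` so voxels outside
#' the coil support map to 0 rather than dividing by ~0).  The combined
#' image is returned as k-space.
#'
#' @param kspace Complex `Ny x Nz x C` multi-coil k-space.
#' @param maps Complex `Ny x Nz x C` coil sensitivities.
#' @return Complex `Ny x Nz` single-coil k-space.
#' @export
coil_combine_kspace <- function(kspace, maps) {
  if (length(dim(kspace)) == 2L) kspace <- array(kspace, c(dim(kspace), 1L))
  d <- dim(kspace)
  maps <- .check_maps(maps, d[1], d[2])
  if (dim(maps)[3] != d[3]) .stopf("coil count mismatch")
  imgs <- ifft2c(kspace)
  num <- rowSums(imgs * Conj(maps), dims = 2)
  den <- rowSums(Mod(maps)^2, dims = 2)
  eps <- 1e-12 * max(den)
  comb <- num / pmax(den, eps)
  comb[den <= eps] <- 0
  fft2c(comb)
}
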