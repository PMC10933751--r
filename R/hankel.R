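# Block-Hankel lifting of multi-shot-group k-space and singular-value
# thresholding.
#
# A k1 x k2 sliding window (valid positions only, no wrap-around) walks
# over each group's Ny x Nz k-space plane; each window is vectorized into
# a row, and the per-group blocks are concatenated side by side.  When the
# group images share a magnitude and differ only by smooth phase
# modulations, the columns of different blocks are nearly linearly
# dependent, so the lifted matrix is (approximately) low rank.

#' Hankel lifting configuration
#'
#' @param kernel_ky,kernel_kz Sliding-window (kernel) size along ky and kz;
#'   default 6 x 6.
#' @return Object of class `hankel_config`.
#' @export
hankel_config <- function(kernel_ky = 6, kernel_kz = 6) {
  if (!.is_count(kernel_ky) || !.is_count(kernel_kz))
    .stopf("kernel sizes must be positive integers")
  structure(list(kernel_ky = as.integer(kernel_ky),
                 kernel_kz = as.integer(kernel_kz)),
            class = "hankel_config")
}

# Precomputed index plan for a (Ny, Nz, k1, k2, G) lifting geometry.
# idx[r, c] is the 1-based linear index into as.vector(X) feeding lifted
# entry (r, c).  ord / ends / targets implement a fast grouped-sum adjoint;
# coverage is the diagonal of H^H H.
.hankel_plan <- function(Ny, Nz, k1, k2, G) {
  if (k1 > Ny || k2 > Nz)
    .stopf("Hankel kernel %dx%d exceeds the %dx%d grid", k1, k2, Ny, Nz)
  wy <- Ny - k1 + 1L; wz <- Nz - k2 + 1L
  win0 <- as.vector(outer(seq_len(wy) - 1L, (seq_len(wz) - 1L) * Ny, `+`))
  pat0 <- as.vector(outer(seq_len(k1) - 1L, (seq_len(k2) - 1L) * Ny, `+`))
  idx1 <- outer(win0, pat0, `+`) + 1L                  # plane-local indices
  idx <- matrix(0L, wy * wz, k1 * k2 * G)
  for (g in seq_len(G))
    idx[, (g - 1L) * k1 * k2 + seq_len(k1 * k2)] <- idx1 + (g - 1L) * Ny * Nz
  iv <- as.vector(idx)
  ord <- order(iv)
  sorted <- iv[ord]
  ends <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  targets <- sorted[ends]
  coverage <- numeric(Ny * Nz * G)
  coverage[targets] <- diff(c(0L, ends))
  list(Ny = Ny, Nz = Nz, G = G, k1 = k1, k2 = k2,
       nrow = wy * wz, ncol = k1 * k2 * G,
       idx = idx, ord = ord, ends = ends, targets = targets,
       coverage = coverage)
}

#' Block-Hankel lifting of multi-shot-group k-space
#'
#' Row `r` of the result is the vectorized `k1 x k2` patch at sliding-window
#' position `r`, with the `G` shot-group blocks concatenated horizontally.
#' The matrix has `(Ny - k1 + 1) * (Nz - k2 + 1)` rows and `k1 * k2 * G`
#' columns.
#'
#' @param X Complex `Ny x Nz x G` array (or `Ny x Nz` matrix, `G = 1`).
#' @param cfg A [hankel_config()].
#' @return Complex lifted matrix.
#' @seealso [hankel_unlift()], [hankel_coverage()]
#' @export
hankel_lift <- function(X, cfg = hankel_config()) {
  X <- .as_group_stack(X)
  d <- dim(X)
  p <- .hankel_plan(d[1], d[2], cfg$kernel_ky, cfg$kernel_kz, d[3])
  matrix(X[p$idx], p$nrow, p$ncol)
}

#' Adjoint of the block-Hankel lifting
#'
#' Each k-space location accumulates the sum of every lifted-matrix entry
#' that references it, so `hankel_unlift(hankel_lift(X)) ==
#' hankel_coverage(...) * X` elementwise.  Divide by the coverage counts
#' for a normalized (averaging) un-lifting.
#'
#' @param M Complex lifted matrix as produced by [hankel_lift()].
#' @param cfg A [hankel_config()].
#' @param grid Integer `c(Ny, Nz)` k-space grid size.
#' @param G Number of shot groups.
#' @return Complex `Ny x Nz x G` array.
#' @export
hankel_unlift <- function(M, cfg, grid, G) {
  p <- .hankel_plan(grid[1], grid[2], cfg$kernel_ky, cfg$kernel_kz, G)
  if (!all(dim(M) == c(p$nrow, p$ncol)))
    .stopf("lifted matrix is %dx%d but the plan expects %dx%d",
           nrow(M), ncol(M), p$nrow, p$ncol)
  array(.unlift_with_plan(M, p), c(grid[1], grid[2], G))
}

.unlift_with_plan <- function(M, p) {
  cs <- cumsum(as.vector(M)[p$ord])
  sums <- cs[p$ends] - c(0 + 0i, cs[p$ends[-length(p$ends)]])
  x <- complex(length(p$coverage))
  x[p$targets] <- sums
  x
}

#' Coverage counts of the Hankel lifting (diagonal of H^H H)
#'
#' @inheritParams hankel_unlift
#' @return Numeric `Ny x Nz x G` array of patch-coverage counts; interior
#'   entries of a large grid have count `k1 * k2`.
#' @export
hankel_coverage <- function(cfg, grid, G) {
  p <- .hankel_plan(grid[1], grid[2], cfg$kernel_ky, cfg$kernel_kz, G)
  array(p$coverage, c(grid[1], grid[2], G))
}

# Economy SVD with failure context.
.safe_svd <- function(M, values_only = FALSE) {
  out <- tryCatch(
    if (values_only) svd(M, nu = 0, nv = 0) else svd(M),
    error = function(e) .stopf("SVD failed on a %dx%d lifted matrix: %s",
                               nrow(M), ncol(M), conditionMessage(e)))
  out
}

#' Singular-value hard thresholding
#'
#' Computes the SVD `M = U S V^H` and zeroes singular values below a cut,
#' keeping the survivors unchanged (a projection, hence idempotent).
#'
#' @param M Complex matrix.
#' @param tau Threshold.  Interpretation depends on `mode`:
#'   `"relative"` (default) keeps singular values `>= tau * sigma_1`;
#'   `"absolute"` keeps singular values `>= tau`; `"rank"` keeps the
#'   largest `tau` singular values.
#' @param mode One of `"relative"`, `"absolute"`, `"rank"`.
#' @return Thresholded matrix of the same shape.
#' @seealso [sv_soft_threshold()]
#' @export
sv_hard_threshold <- function(M, tau,
                              mode = c("relative", "absolute", "rank")) {
  mode <- match.arg(mode)
  if (tau < 0) .stopf("'tau' must be nonnegative")
  s <- .safe_svd(M)
  keep <- switch(mode,
    relative = s$d >= tau * s$d[1],
    absolute = s$d >= tau,
    rank     = seq_along(s$d) <= tau)
  .sv_rebuild(s, ifelse(keep, s$d, 0))
}

#' Singular-value soft thresholding
#'
#' Maps each singular value to `max(sigma - tau, 0)`, the proximal operator
#' of the nuclear norm; never increases the nuclear norm.
#'
#' @param M Complex matrix.
#' @param tau Nonnegative shrinkage amount (absolute units).
#' @return Thresholded matrix of the same shape.
#' @export
sv_soft_threshold <- function(M, tau) {
  if (tau < 0) .stopf("'tau' must be nonnegative")
  s <- .safe_svd(M)
  .sv_rebuild(s, pmax(s$d - tau, 0))
}

.sv_rebuild <- function(s, d_new) {
  keep <- d_new > 0
  if (!any(keep)) return(matrix(0i, nrow(s$u), nrow(s$v)))
  U <- s$u[, keep, drop = FALSE]
  V <- s$v[, keep, drop = FALSE]
  (U * rep(d_new[keep], each = nrow(U))) %*% Conj(t(V))
}

#' Nuclear norm (sum of singular values)
#'
#' @param M Complex matrix.
#' @return Nonnegative scalar.
#' @export
nuclear_norm <- function(M) sum(.safe_svd(M, values_only = TRUE)$d)
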