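# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators never perturb user code.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Complex inner product <a, b> = sum(conj(a) * b); both flattened.
.cdot <- function(a, b) sum(Conj(a) * b)

# Normalized pixel-center coordinates on [-1, 1) for an n-point axis.
.norm_coords <- function(n) (seq_len(n) - 1 - n / 2) / (n / 2)

# u/v coordinate matrices for an Ny x Nz grid (u varies along rows = ky
# image axis, v along columns).
.grid_uv <- function(ny, nz) {
  list(u = matrix(.norm_coords(ny), ny, nz),
       v = matrix(.norm_coords(nz), ny, nz, byrow = TRUE))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
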