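# Simulation framework: ground-truth phantom, smooth coil maps,
# second-order-harmonic respiratory phase fluctuations, per-shot k-space
# synthesis for any shot schedule, and calibrated thermal noise.
#
# The generator's stated world: a 2D ky-kz plane of a 3D EPI acquisition,
# respiration at ~0.25 Hz modulating the image phase through a smooth
# second-order spatial harmonic map, thermal noise as i.i.d. complex
# Gaussian samples on acquired k-space lines only, and time advancing
# continuously across volumes (shot timestamp x shot TR, never re-zeroed).

# ellipse table for the structured phantom: centers/axes in [-1,1] units,
# angle in degrees, additive amplitude.  Values chosen so every interior
# compartment stays well above the default 0.1 support threshold.
.phantom_ellipses <- data.frame(
  cx  = c( 0.00,  0.00, -0.18,  0.18,  0.00,  0.00, -0.30,  0.28),
  cy  = c( 0.00,  0.00,  0.05,  0.05, -0.45,  0.38, -0.32, -0.38),
  a   = c( 0.72,  0.65,  0.11,  0.11,  0.13,  0.10,  0.08,  0.07),
  b   = c( 0.90,  0.83,  0.26,  0.26,  0.13,  0.10,  0.08,  0.07),
  ang = c( 0,     0,     18,   -18,    0,     0,     0,     0),
  amp = c( 1.00, -0.30, -0.25, -0.25,  0.25,  0.20,  0.15,  0.15))

#' Synthetic ground-truth phantom
#'
#' Deterministic complex test image on an `Ny x Nz` grid with magnitude in
#' `[0, 1]`, internal structure (so ghosting is visible), support strictly
#' inside the grid, and an optional smooth low-order baseline phase
#' `c0 + c1*u + c2*v + c3*u*v` on normalized coordinates `[-1, 1)`.
#' A mild k-space Gaussian apodization removes the hard ellipse edges.
#'
#' @param Ny,Nz Grid size (default 48 x 48).
#' @param structure `"shepp_logan_variant"` (ellipse phantom, default) or
#'   `"smooth_blobs"` (sum of random Gaussian blobs, controlled by `seed`).
#' @param baseline_phase Numeric coefficients `c(c0, c1, c2, c3)` in
#'   radians for the `1, u, v, u*v` terms; default all zero (real image).
#' @param smooth Gaussian apodization width as a fraction of the k-space
#'   half-width; larger = sharper image.  Default `Inf` (no apodization),
#'   matching the canonical hard-edged head phantom so that the thresholded
#'   support mask coincides with the analytic ellipse support.
#' @param seed RNG seed used only by `"smooth_blobs"`.
#' @return Complex `Ny x Nz` matrix with attributes `support` (logical
#'   matrix, the analytic pre-apodization object support) and `uv`
#'   (the normalized coordinate grids).
#' @export
make_phantom <- function(Ny = 48, Nz = 48,
                         structure = c("shepp_logan_variant", "smooth_blobs"),
                         baseline_phase = c(0, 0, 0, 0),
                         smooth = Inf, seed = 1) {
  structure <- match.arg(structure)
  uv <- .grid_uv(Ny, Nz); u <- uv$u; v <- uv$v
  img <- matrix(0, Ny, Nz)
  if (structure == "shepp_logan_variant") {
    for (i in seq_len(nrow(.phantom_ellipses))) {
      e <- .phantom_ellipses[i, ]
      th <- e$ang * pi / 180
      ur <- (u - e$cx) * cos(th) + (v - e$cy) * sin(th)
      vr <- -(u - e$cx) * sin(th) + (v - e$cy) * cos(th)
      img <- img + e$amp * ((ur / e$a)^2 + (vr / e$b)^2 <= 1)
    }
    support <- (u / .phantom_ellipses$a[1])^2 +
      (v / .phantom_ellipses$b[1])^2 <= 1
  } else {
    blobs <- .with_seed(seed, {
      nb <- 6
      data.frame(cx = stats::runif(nb, -0.45, 0.45),
                 cy = stats::runif(nb, -0.45, 0.45),
                 s  = stats::runif(nb, 0.10, 0.25),
                 a  = stats::runif(nb, 0.4, 1.0))
    })
    for (i in seq_len(nrow(blobs)))
      img <- img + blobs$a[i] *
        exp(-((u - blobs$cx[i])^2 + (v - blobs$cy[i])^2) / (2 * blobs$s[i]^2))
    support <- img >= 0.1 * max(img)
  }
  if (is.finite(smooth)) {
    # optional k-space Gaussian apodization for band-limited smooth edges
    fy <- matrix(.norm_coords(Ny), Ny, Nz)
    fz <- matrix(.norm_coords(Nz), Ny, Nz, byrow = TRUE)
    w <- exp(-(fy^2 + fz^2) / (2 * smooth^2))
    img <- Re(ifft2c(fft2c(img) * w))
    img <- pmax(img, 0)
  }
  img <- img / max(img)
  ph <- baseline_phase[1] + baseline_phase[2] * u + baseline_phase[3] * v +
    baseline_phase[4] * u * v
  out <- img * exp(1i * ph)
  attr(out, "support") <- support
  attr(out, "uv") <- uv
  out
}

#' Smooth synthetic coil sensitivity maps
#'
#' `n_coils` Gaussian-lobe magnitude profiles centered on a ring just
#' outside the object, each with a mild linear phase ramp, then normalized
#' pointwise so the root-sum-of-squares across coils equals 1 wherever the
#' unnormalized RSS is nonnegligible (and 0 elsewhere).  Deterministic for
#' a fixed seed.
#'
#' @param n_coils Number of coils (>= 1).
#' @param grid Integer `c(Ny, Nz)`.
#' @param seed RNG seed for the small random jitter of lobe centers,
#'   widths and phase ramps.
#' @return Complex `Ny x Nz x n_coils` array.
#' @export
make_coil_maps <- function(n_coils, grid = c(48, 48), seed = 1) {
  if (!.is_count(n_coils)) .stopf("'n_coils' must be a positive integer")
  Ny <- grid[1]; Nz <- grid[2]
  uv <- .grid_uv(Ny, Nz); u <- uv$u; v <- uv$v
  par <- .with_seed(seed, {
    th <- 2 * pi * (seq_len(n_coils) - 1) / n_coils +
      stats::runif(n_coils, -0.15, 0.15)
    data.frame(cx = 1.25 * cos(th), cy = 1.25 * sin(th),
               sg = stats::runif(n_coils, 0.9, 1.2),
               pa = stats::runif(n_coils, -1.5, 1.5),
               pb = stats::runif(n_coils, -1.5, 1.5),
               p0 = stats::runif(n_coils, -pi, pi))
  })
  S <- array(0i, c(Ny, Nz, n_coils))
  for (c in seq_len(n_coils)) {
    mag <- exp(-((u - par$cx[c])^2 + (v - par$cy[c])^2) / (2 * par$sg[c]^2))
    S[, , c] <- mag * exp(1i * (par$pa[c] * u + par$pb[c] * v + par$p0[c]))
  }
  rss <- sqrt(rowSums(Mod(S)^2, dims = 2))
  thr <- 1e-8 * max(rss)
  scale <- ifelse(rss > thr, 1 / pmax(rss, thr), 0)
  S * as.vector(scale)
}

#' Second-order-harmonic physiological phase model
#'
#' Phase maps are `phi(u, v, t) = trace(t) * sum_k a_k B_k(u, v)` on the 6
#' real second-order 2D harmonic/polynomial basis maps
#' `{1, u, v, u*v, u^2 - v^2, u^2 + v^2}` over normalized coordinates
#' `[-1, 1)^2`.  The temporal trace is a respiratory sinusoid plus a slow
#' linear drift and optional smooth stochastic jitter (a fixed 3-sinusoid
#' series drawn once from `seed`, so the trace stays deterministic and
#' continuous in `t`):
#' `trace(t) = sin(2 pi f t + phase) + drift * t + jitter(t)`.
#'
#' @param amplitudes Numeric length-6 vector of per-basis amplitudes in
#'   radians.  The default gives a peak-to-peak phase excursion of roughly
#'   1.4 rad at the object edge, a plausible magnitude for respiration-
#'   induced B0 modulation at 7T (the magnitude is a free knob of the
#'   simulation, not a literature value).
#' @param resp_freq Respiratory frequency in Hz (default 0.25, i.e. a 4 s
#'   period).
#' @param resp_phase Phase of the sinusoid at `t = 0`, radians.
#' @param drift Linear drift rate in units of the trace per second
#'   (default 0.005).
#' @param jitter_sd Standard-deviation scale of the stochastic jitter
#'   component (default 0, disabled).
#' @param shot_TR Time between consecutive shots in seconds (default
#'   0.055, matching 3D EPI protocols with 55-68 ms shot TR).
#' @param seed Seed for the jitter component.
#' @return Object of class `phase_model`.
#' @export
phase_model <- function(amplitudes = c(0.10, 0.20, 0.25, 0.10, 0.08, 0.15),
                        resp_freq = 0.25, resp_phase = 0,
                        drift = 0.005, jitter_sd = 0,
                        shot_TR = 0.055, seed = 1) {
  if (length(amplitudes) != 6)
    .stopf("'amplitudes' must have length 6 (basis 1,u,v,uv,u^2-v^2,u^2+v^2)")
  jit <- if (jitter_sd > 0) {
    .with_seed(seed, data.frame(f = stats::runif(3, 0.02, 0.8),
                                p = stats::runif(3, 0, 2 * pi),
                                a = stats::rnorm(3, 0, jitter_sd / sqrt(3))))
  } else NULL
  structure(list(amplitudes = amplitudes, resp_freq = resp_freq,
                 resp_phase = resp_phase, drift = drift,
                 jitter_sd = jitter_sd, jitter = jit,
                 shot_TR = shot_TR, seed = seed),
            class = "phase_model")
}

#' Evaluate the 6-map second-order harmonic basis on a grid
#'
#' @param grid Integer `c(Ny, Nz)`.
#' @return `Ny x Nz x 6` array with maps `1, u, v, u*v, u^2 - v^2,
#'   u^2 + v^2`.
#' @export
harmonic_basis <- function(grid) {
  uv <- .grid_uv(grid[1], grid[2]); u <- uv$u; v <- uv$v
  B <- array(0, c(grid[1], grid[2], 6))
  B[, , 1] <- 1; B[, , 2] <- u; B[, , 3] <- v
  B[, , 4] <- u * v; B[, , 5] <- u^2 - v^2; B[, , 6] <- u^2 + v^2
  B
}

.trace_at <- function(t, model) {
  tr <- sin(2 * pi * model$resp_freq * t + model$resp_phase) +
    model$drift * t
  if (!is.null(model$jitter))
    for (i in 1:3)
      tr <- tr + model$jitter$a[i] *
        sin(2 * pi * model$jitter$f[i] * t + model$jitter$p[i])
  tr
}

#' Physiological phase map at a time point
#'
#' @param t Time in seconds (scalar).
#' @param model A [phase_model()].
#' @param grid Integer `c(Ny, Nz)`.
#' @return `Ny x Nz` phase map in radians.
#' @export
phase_map_at <- function(t, model, grid) {
  if (!inherits(model, "phase_model")) .stopf("'model' must be a phase_model")
  B <- harmonic_basis(grid)
  static <- matrix(0, grid[1], grid[2])
  for (k in 1:6) static <- static + model$amplitudes[k] * B[, , k]
  .trace_at(t, model) * static
}

#' Thermal noise specification
#'
#' `sd` is the standard deviation of one complex k-space sample,
#' `sqrt(E|n|^2)`; real and imaginary parts each have standard deviation
#' `sd / sqrt(2)`.
#'
#' @param sd Nonnegative complex-sample standard deviation (0 = noiseless).
#' @param seed RNG seed for the noise stream.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1) {
  if (!(length(sd) == 1 && is.finite(sd) && sd >= 0))
    .stopf("'sd' must be a nonnegative scalar")
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

#' Calibrate noise level to a target image-domain SNR
#'
#' The package's SNR definition: mean phantom magnitude over the support
#' divided by the complex-sample noise standard deviation in the
#' fully-sampled coil-combined image.  With unitary Fourier transforms and
#' RSS-normalized coil maps, image-domain noise sd equals k-space noise sd,
#' so the calibration is closed-form: `sd = mean|phantom|_support / target`.
#'
#' @param target_snr Target mean SNR (> 0; `Inf` gives a noiseless spec).
#' @param phantom Complex ground-truth image (from [make_phantom()]).
#' @param maps Coil maps; unused by the closed form (kept for signature
#'   stability) because RSS-normalized maps propagate unit noise gain.
#' @param support_fraction Threshold fraction defining the support mask
#'   (default 0.1, see [support_mask()]).
#' @param seed Seed stored in the returned [noise_spec()].
#' @return A [noise_spec()].
#' @export
snr_calibrate <- function(target_snr, phantom, maps = NULL,
                          support_fraction = 0.1, seed = 1) {
  if (!(length(target_snr) == 1 && target_snr > 0))
    .stopf("'target_snr' must be positive")
  if (is.infinite(target_snr)) return(noise_spec(0, seed))
  supp <- support_mask(Mod(phantom), support_fraction)
  noise_spec(mean(Mod(phantom)[supp]) / target_snr, seed)
}

#' Simulate a multi-volume multi-shot acquisition
#'
#' For every volume and every shot (at its acquisition timestamp times the
#' shot TR, advancing continuously across volumes) the ground-truth image
#' is modulated by `exp(i * phase_map_at(t))`, weighted by each coil map,
#' Fourier transformed, and the shot's `(ky, kz)` lines are extracted into
#' its shot group's k-space array.  I.i.d. complex Gaussian noise is added
#' to acquired samples only.  Calling again with `reference = TRUE` (or a
#' zero-amplitude model) and the same noise seed yields the paired
#' physiological-noise-free series with identical noise draws.
#'
#' @param phantom Complex `Ny x Nz` ground-truth image.
#' @param maps Complex `Ny x Nz x C` coil maps.
#' @param schedule A [build_schedule()] result on the same grid.
#' @param model A [phase_model()].
#' @param noise A [noise_spec()].
#' @param n_volumes Number of volumes to simulate.
#' @param phase_sampling `"per_shot"` (default): each shot sees the phase
#'   map at its own timestamp; `"per_group"`: all shots of a group within
#'   one volume see the phase map at the group's mean shot time, i.e.
#'   exactly one smooth phase state per shot group.
#' @param reference If `TRUE`, force zero phase amplitudes (the matched
#'   reference series) while keeping the same noise stream.
#' @return Object of class `sim_series`: a list with `volumes` (one
#'   element per volume, each holding `kspace` `[Ny, Nz, C, G]` and
#'   `masks` `[Ny, Nz, G]`), `masks`, `schedule`, `phantom`, `maps`,
#'   `model`, `noise`, `phase_truth` (list over volumes of `[Ny, Nz, G]`
#'   per-group phase maps at group mean times), `group_times`, and
#'   `volume_TR`.
#' @export
simulate_timeseries <- function(phantom, maps, schedule, model, noise,
                                n_volumes,
                                phase_sampling = c("per_shot", "per_group"),
                                reference = FALSE) {
  phase_sampling <- match.arg(phase_sampling)
  if (!inherits(schedule, "shot_schedule"))
    .stopf("'schedule' must be a shot_schedule")
  if (!inherits(noise, "noise_spec")) .stopf("'noise' must be a noise_spec")
  cfg <- schedule$config
  Ny <- cfg$Ny; Nz <- cfg$Nz
  if (!all(dim(phantom) == c(Ny, Nz)))
    .stopf("phantom grid %dx%d does not match schedule grid %dx%d",
           nrow(phantom), ncol(phantom), Ny, Nz)
  maps <- .check_maps(maps, Ny, Nz); C <- dim(maps)[3]
  G <- schedule$n_groups; S <- schedule$n_shots
  if (reference) { model <- unclass(model); model$amplitudes <- rep(0, 6)
                   class(model) <- "phase_model" }
  masks <- group_masks(schedule)
  zero_amp <- all(model$amplitudes == 0)
  B <- harmonic_basis(c(Ny, Nz))
  static <- matrix(0, Ny, Nz)
  for (k in 1:6) static <- static + model$amplitudes[k] * B[, , k]

  # per-shot line assignment index templates (built once)
  ln <- schedule$lines
  shot_of_line <- ln$shot
  # flat indices into [Ny, Nz, C, G] and into a [Ny, Nz, C] coil stack
  nyz <- Ny * Nz
  line_plane <- ln$ky + ln$kz * Ny                    # 0-based plane index
  coil_off <- (seq_len(C) - 1L) * nyz
  dest0 <- rep(line_plane, times = C) + rep(coil_off, each = nrow(ln)) +
    rep(ln$group, times = C) * (nyz * C)
  src0 <- rep(line_plane, times = C) + rep(coil_off, each = nrow(ln))
  shot_rep <- rep(shot_of_line, times = C)

  # noise for the whole series, drawn in one deterministic stream
  n_acq <- nrow(ln) * C
  noise_all <- if (noise$sd > 0)
    .with_seed(noise$seed, matrix(stats::rnorm(2 * n_acq * n_volumes,
                                               sd = noise$sd / sqrt(2)),
                                  ncol = 2)) else NULL

  group_mean_order <- vapply(split(schedule$shots$shot, schedule$shots$group),
                             mean, numeric(1))
  volume_TR <- S * model$shot_TR
  volumes <- vector("list", n_volumes)
  phase_truth <- vector("list", n_volumes)
  group_times <- matrix(0, n_volumes, G)
  zero_state <- NULL
  for (v in seq_len(n_volumes)) {
    t0 <- (v - 1) * S * model$shot_TR
    shot_times <- t0 + schedule$shots$shot * model$shot_TR
    gt <- t0 + group_mean_order * model$shot_TR
    group_times[v, ] <- gt
    # coil k-space per phase state
    if (zero_amp) {
      if (is.null(zero_state))
        zero_state <- fft2c(array(as.vector(phantom), c(Ny, Nz, C)) *
                              as.vector(maps))
      kst <- list(zero_state); state_of_shot <- rep(1L, S)
    } else if (phase_sampling == "per_group") {
      kst <- lapply(seq_len(G), function(g) {
        img <- phantom * exp(1i * .trace_at(gt[g], model) * static)
        fft2c(array(as.vector(img), c(Ny, Nz, C)) * as.vector(maps))
      })
      state_of_shot <- schedule$shots$group + 1L
    } else {
      big <- array(0i, c(Ny, Nz, C * S))
      for (s in seq_len(S)) {
        img <- phantom * exp(1i * .trace_at(shot_times[s], model) * static)
        big[, , (s - 1L) * C + seq_len(C)] <-
          array(as.vector(img), c(Ny, Nz, C)) * as.vector(maps)
      }
      big <- fft2c(big)
      kst <- lapply(seq_len(S), function(s)
        big[, , (s - 1L) * C + seq_len(C), drop = FALSE])
      state_of_shot <- seq_len(S)
    }
    Y <- array(0i, c(Ny, Nz, C, G))
    for (st in unique(state_of_shot)) {
      sel <- state_of_shot[shot_rep + 1L] == st
      Y[dest0[sel] + 1L] <- kst[[st]][src0[sel] + 1L]
    }
    if (!is.null(noise_all)) {
      rows <- (v - 1L) * n_acq + seq_len(n_acq)
      Y[dest0 + 1L] <- Y[dest0 + 1L] +
        complex(real = noise_all[rows, 1], imaginary = noise_all[rows, 2])
    }
    volumes[[v]] <- list(kspace = Y, masks = masks)
    ph <- array(0, c(Ny, Nz, G))
    if (!zero_amp)
      for (g in seq_len(G)) ph[, , g] <- .trace_at(gt[g], model) * static
    phase_truth[[v]] <- ph
  }
  structure(list(volumes = volumes, masks = masks, schedule = schedule,
                 phantom = phantom, maps = maps, model = model,
                 noise = noise, phase_truth = phase_truth,
                 group_times = group_times, volume_TR = volume_TR),
            class = "sim_series")
}

#' @export
print.sim_series <- function(x, ...) {
  d <- dim(x$volumes[[1]]$kspace)
  cat(sprintf("<sim_series> %d volume(s), grid %dx%d, %d coil(s), %d shot group(s), volume TR %.3f s\n",
              length(x$volumes), d[1], d[2], d[3], d[4], x$volume_TR))
  invisible(x)
}
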