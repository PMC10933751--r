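#' Trajectory configuration for 3D multi-shot EPI ky-kz sampling
#'
#' Describes a blipped-CAIPI sampling pattern on the ky-kz plane of a 3D
#' multi-shot EPI acquisition.  Each shot (one excitation's EPI readout
#' train) acquires one line per sampled ky position; along kz the line
#' index is incremented by CAIPI blips of size `dkz` inside a band of
#' height `width`, wrapping within the band.
#'
#' Two orderings are supported:
#' \describe{
#'   \item{`standard`}{sequential ordering along kz; consecutive shots are
#'     offset by `Rz`, so `width = Rz` and `dkz < Rz`.}
#'   \item{`seg_caipi`}{interleaved ordering along kz with
#'     `N = width / Rz >= 2` interleaves.  Consecutive shots of one
#'     interleave are offset by `width`; interleave `j + 1` is offset by
#'     `Rz` relative to interleave `j`.  The wider per-shot band permits a
#'     blip size `dkz >= Rz`, which is what makes each interleave's own
#'     sampling pattern a near-uniform CAIPI lattice.}
#' }
#'
#' Shots of one interleave are binned as one shot group, so the number of
#' shot groups equals the number of interleaves, `width / Rz`.
#'
#' @param Ny,Nz Integer ky / kz matrix sizes.
#' @param Ry,Rz Integer under-sampling factors along ky and along the shot
#'   (kz) dimension; both `>= 1`.  `Nz` must be divisible by `Rz` and by
#'   `width`.  `Ny` need not be divisible by `Ry`; the sampled ky lines are
#'   `0, Ry, 2 Ry, ...` below `Ny` (`ceiling(Ny / Ry)` lines per shot).
#' @param scheme `"standard"` or `"seg_caipi"`.
#' @param width kz offset between two consecutive shots with identical
#'   trajectories, which also equals the kz span of each shot.  Must equal
#'   `Rz` for `standard` and an integer multiple `N * Rz` for `seg_caipi`
#'   (`N = 1` degenerates to the standard ordering, line for line).
#'   Defaults to `Rz` for the standard scheme.
#' @param dkz CAIPI kz blip size, `0 <= dkz < width`.
#' @param ky_offset Global offset of the first sampled ky line (default 0).
#' @return An object of class `trajectory_config`.
#' @seealso [build_schedule()], [suggest_dkz()]
#' @examples
#' trajectory_config(116, 96, Ry = 2, Rz = 2, scheme = "seg_caipi",
#'                   width = 8, dkz = 3)
#' @export
trajectory_config <- function(Ny, Nz, Ry = 1, Rz = 1,
                              scheme = c("standard", "seg_caipi"),
                              width = NULL, dkz = 0, ky_offset = 0) {
  scheme <- match.arg(scheme)
  for (nm in c("Ny", "Nz", "Ry", "Rz"))
    if (!.is_count(get(nm))) .stopf("'%s' must be a positive integer", nm)
  if (is.null(width)) {
    if (scheme == "standard") width <- Rz
    else .stopf("'width' is required for the seg_caipi scheme")
  }
  if (!.is_count(width)) .stopf("'width' must be a positive integer")
  if (!(length(dkz) == 1 && dkz == round(dkz) && dkz >= 0))
    .stopf("'dkz' must be a nonnegative integer")
  if (scheme == "standard" && width != Rz)
    .stopf("standard scheme requires width == Rz (got width=%d, Rz=%d)",
           width, Rz)
  if (scheme == "seg_caipi" && width %% Rz != 0)
    .stopf("seg_caipi requires width = N*Rz for integer N >= 1 (width=%d, Rz=%d)",
           width, Rz)
  if (Nz %% Rz != 0)
    .stopf("divisibility violation: Nz %% Rz must be 0 (Nz=%d, Rz=%d)", Nz, Rz)
  if (Nz %% width != 0)
    .stopf("divisibility violation: Nz %% width must be 0 (Nz=%d, width=%d)",
           Nz, width)
  if (dkz >= width)
    .stopf("'dkz' must be smaller than 'width' (dkz=%d, width=%d)", dkz, width)
  structure(list(Ny = as.integer(Ny), Nz = as.integer(Nz),
                 Ry = as.integer(Ry), Rz = as.integer(Rz),
                 width = as.integer(width), dkz = as.integer(dkz),
                 scheme = scheme, ky_offset = as.integer(ky_offset)),
            class = "trajectory_config")
}

#' @export
print.trajectory_config <- function(x, ...) {
  cat(sprintf("<trajectory_config> %s(%d,%d)  grid %dx%d  R=%dx%d  %d interleave(s)\n",
              if (x$scheme == "seg_caipi") "seg-CAIPI" else "blipped-CAIPI",
              x$width, x$dkz, x$Ny, x$Nz, x$Ry, x$Rz, x$width %/% x$Rz))
  invisible(x)
}

#' Build the shot schedule for a sampling configuration
#'
#' Enumerates every shot of the trajectory: which `(ky, kz)` line each shot
#' acquires, its interleave, its shot group (= interleave), and its global
#' acquisition timestamp.  Shots are ordered interleave-major: all shots of
#' interleave 0 in ascending kz origin, then interleave 1, and so on, so
#' that each shot group consists of consecutively acquired shots.
#'
#' The intra-shot blip rule is `kz = origin + ((n * dkz) mod width)` for
#' line index `n`, i.e. blips of size `dkz` that wrap inside the shot's
#' kz band of height `width`.  kz indices are taken modulo `Nz`, so bands
#' that start near the top of the grid wrap around circularly; this is what
#' makes the combined seg-CAIPI mask identical to the corresponding
#' standard blipped-CAIPI mask.
#'
#' @param config A [trajectory_config()].
#' @return An object of class `shot_schedule` with elements
#'   \describe{
#'     \item{config}{the input configuration}
#'     \item{shots}{data frame, one row per shot: `shot` (acquisition
#'       timestamp, 0-based), `interleave`, `group`, `kz_origin`}
#'     \item{lines}{data frame, one row per acquired line: `shot`,
#'       `interleave`, `group`, `line` (0-based index along the readout
#'       train), `ky`, `kz` (0-based grid indices)}
#'     \item{n_shots, n_groups, lines_per_shot}{counts}
#'   }
#' @examples
#' sched <- build_schedule(trajectory_config(12, 12, Ry = 3, Rz = 2,
#'                                           scheme = "seg_caipi",
#'                                           width = 4, dkz = 1))
#' sched$n_groups  # 2 shot groups
#' @export
build_schedule <- function(config) {
  if (!inherits(config, "trajectory_config"))
    .stopf("'config' must be a trajectory_config")
  Ny <- config$Ny; Nz <- config$Nz; Ry <- config$Ry; Rz <- config$Rz
  width <- config$width; dkz <- config$dkz
  n_int <- width %/% Rz                       # interleaves = shot groups
  shots_per_int <- Nz %/% width
  n_shots <- Nz %/% Rz
  stopifnot(n_int * shots_per_int == n_shots)
  ky <- seq.int(0L, Ny - 1L, by = Ry) + config$ky_offset
  if (any(ky >= Ny)) .stopf("ky_offset pushes sampled lines off the grid")
  n_lines <- length(ky)
  nseq <- seq_len(n_lines) - 1L
  blip <- (nseq * dkz) %% width

  shot_id <- 0L
  shots <- vector("list", n_shots); lines <- vector("list", n_shots)
  for (j in seq_len(n_int) - 1L) {
    for (s in seq_len(shots_per_int) - 1L) {
      origin <- j * Rz + s * width
      kz <- (origin + blip) %% Nz
      shots[[shot_id + 1L]] <- data.frame(
        shot = shot_id, interleave = j, group = j, kz_origin = origin)
      lines[[shot_id + 1L]] <- data.frame(
        shot = shot_id, interleave = j, group = j,
        line = nseq, ky = ky, kz = kz)
      shot_id <- shot_id + 1L
    }
  }
  structure(list(config = config,
                 shots = do.call(rbind, shots),
                 lines = do.call(rbind, lines),
                 n_shots = n_shots,
                 n_groups = n_int,
                 lines_per_shot = n_lines),
            class = "shot_schedule")
}

#' @export
print.shot_schedule <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d shots, %d shot group(s), %d shots/group, %d lines/shot\n",
              x$n_shots, x$n_groups, x$n_shots %/% x$n_groups,
              x$lines_per_shot))
  invisible(x)
}

#' Per-shot-group sampling masks
#'
#' One binary `Ny x Nz` mask per shot group; entry 1 marks a `(ky, kz)`
#' line acquired by some shot of that group.  Group masks are mutually
#' disjoint and sum to the combined mask.
#'
#' @param schedule A [build_schedule()] result.
#' @return Numeric 0/1 array `Ny x Nz x n_groups`.
#' @export
group_masks <- function(schedule) {
  if (!inherits(schedule, "shot_schedule"))
    .stopf("'schedule' must be a shot_schedule")
  cfg <- schedule$config
  m <- array(0, c(cfg$Ny, cfg$Nz, schedule$n_groups))
  ln <- schedule$lines
  idx <- cbind(ln$ky + 1L, ln$kz + 1L, ln$group + 1L)
  if (anyDuplicated(idx))
    .stopf("schedule integrity error: duplicate (ky,kz) line within a shot group")
  m[idx] <- 1
  tot <- rowSums(m, dims = 2)
  if (any(tot > 1))
    .stopf("schedule integrity error: overlapping lines across shot groups")
  m
}

#' Combined sampling mask across all shots
#'
#' Union of all shots' acquired lines on the `Ny x Nz` grid.  The number of
#' ones equals `lines_per_shot * n_shots` = `ceiling(Ny/Ry) * (Nz/Rz)`.
#'
#' @inheritParams group_masks
#' @return Numeric 0/1 matrix `Ny x Nz`.
#' @export
combined_mask <- function(schedule) {
  rowSums(group_masks(schedule), dims = 2)
}

#' Advisory CAIPI blip-size selection
#'
#' Brute-force search over `dkz` in `1, ..., width - 1` choosing the blip
#' size that minimizes the largest distance from any sampled point of a
#' single shot group's mask to its nearest neighboring sample (distances on
#' the ky-kz torus, with the ky axis scaled by `Ry/width` so both axes are
#' in units of the local lattice).  Advisory only: schedules always take an
#' explicit `dkz`.
#'
#' @param config A [trajectory_config()]; its `dkz` field is ignored.
#' @return Integer blip size.
#' @export
suggest_dkz <- function(config) {
  best <- NULL; best_val <- Inf
  for (d in seq_len(config$width - 1L)) {
    cfg <- config; cfg$dkz <- as.integer(d)
    sched <- build_schedule(cfg)
    ln <- sched$lines[sched$lines$group == 0L, ]
    # torus coordinates, kz in samples, ky scaled so one ky step of the
    # group's Ry x width lattice matches one kz step
    pts <- cbind(ln$ky * (config$width / config$Ry), ln$kz)
    n <- nrow(pts)
    wrap <- function(dx, p) pmin(abs(dx) %% p, p - abs(dx) %% p)
    maxmin <- 0
    for (i in seq_len(n)) {
      dy <- wrap(pts[, 1] - pts[i, 1], config$Ny * config$width / config$Ry)
      dz <- wrap(pts[, 2] - pts[i, 2], config$Nz)
      dd <- sqrt(dy^2 + dz^2); dd[i] <- Inf
      maxmin <- max(maxmin, min(dd))
    }
    if (maxmin < best_val) { best_val <- maxmin; best <- d }
  }
  as.integer(best)
}

#' Serialize a shot schedule to JSON
#'
#' Writes the configuration echo plus per-shot line lists to a JSON file
#' (or returns the JSON string when `path` is `NULL`).
#'
#' @param schedule A [build_schedule()] result.
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  cfg <- schedule$config
  per_shot <- lapply(split(schedule$lines, schedule$lines$shot), function(d)
    list(shot = d$shot[1], interleave = d$interleave[1], group = d$group[1],
         ky = d$ky, kz = d$kz))
  names(per_shot) <- NULL
  obj <- list(config = unclass(cfg),
              n_shots = schedule$n_shots, n_groups = schedule$n_groups,
              lines_per_shot = schedule$lines_per_shot, shots = per_shot)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
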