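# Trajectory generation: shot/group combinatorics, mask structure, and the
# seg-CAIPI <-> standard combined-mask identity.

seg <- function(Ny, Nz, Ry, Rz, width, dkz)
  build_schedule(trajectory_config(Ny, Nz, Ry, Rz, "seg_caipi",
                                   width = width, dkz = dkz))
std <- function(Ny, Nz, Ry, Rz, dkz)
  build_schedule(trajectory_config(Ny, Nz, Ry, Rz, "standard", dkz = dkz))

test_that("shot and shot-group counts reproduce the in-vivo protocol table", {
  # columns: Ny, Nz, Ry, Rz, width, dkz, shots, per_group
  cases <- rbind(
    c(116, 96, 2, 2, 8, 3, 48, 12),   # 1.8 mm
    c(116, 96, 2, 4, 8, 2, 24, 12),   # 1.8 mm R=2x4
    c(140, 96, 3, 2, 8, 3, 48, 12),   # 1.5 mm R=3x2
    c(140, 96, 3, 3, 6, 2, 32, 16),   # 1.5 mm R=3x3
    c(174, 120, 3, 2, 4, 1, 60, 30),  # 1.2 mm width comparison
    c(174, 120, 3, 2, 6, 3, 60, 20),
    c(174, 120, 3, 2, 8, 3, 60, 15),
    c(208, 120, 4, 2, 6, 3, 60, 20))  # 1.0 mm
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    sch <- seg(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_equal(sch$n_shots, cs[7], info = paste("row", i))
    expect_equal(sch$n_shots / sch$n_groups, cs[8], info = paste("row", i))
    expect_equal(sch$n_groups, cs[5] / cs[4], info = paste("row", i))
  }
})

test_that("schematic trajectory group counts match the figure caption", {
  expect_equal(seg(12, 24, 3, 2, 4, 1)$n_groups, 2)
  expect_equal(seg(12, 24, 3, 2, 6, 1)$n_groups, 3)
})

test_that("shot structure invariants hold", {
  sch <- seg(116, 96, 2, 2, 8, 3)
  ln <- sch$lines
  # one line per sampled ky, per shot
  expect_true(all(tapply(ln$ky, ln$shot, function(k)
    all(sort(k) == seq(0, 114, by = 2)))))
  # kz of each shot lies in a circular band of height = width at its origin
  for (s in unique(ln$shot)) {
    o <- sch$shots$kz_origin[sch$shots$shot == s]
    rel <- (ln$kz[ln$shot == s] - o) %% 96
    expect_true(all(rel < 8))
  }
  # acquisition order is interleave-major
  expect_true(all(diff(sch$shots$interleave) >= 0))
})

test_that("degenerate seg-CAIPI with width = Rz equals the standard scheme", {
  a <- seg(24, 24, 2, 2, 2, 1)
  b <- std(24, 24, 2, 2, 1)
  expect_equal(a$lines[c("shot", "ky", "kz")], b$lines[c("shot", "ky", "kz")])
})

test_that("configuration errors name the failing constraint", {
  expect_error(trajectory_config(48, 96, 2, 2, "seg_caipi", width = 7, dkz = 1),
               "width = N\\*Rz")
  expect_error(trajectory_config(48, 90, 2, 2, "seg_caipi", width = 8, dkz = 1),
               "Nz % width", fixed = TRUE)
  expect_error(trajectory_config(48, 95, 2, 2, "standard", dkz = 1),
               "Nz % Rz", fixed = TRUE)
  expect_error(trajectory_config(48, 96, 2, 2, "seg_caipi", width = 8, dkz = 8),
               "smaller than 'width'")
  expect_error(trajectory_config(48, 96, 2, 2, "standard", dkz = 2),
               "smaller than 'width'")
})

test_that("non-divisible Ny is accepted with ceiling(Ny/Ry) lines per shot", {
  sch <- seg(140, 96, 3, 3, 6, 2)
  expect_equal(sch$lines_per_shot, ceiling(140 / 3))
  expect_true(all(sch$lines$ky < 140))
})

test_that("combined mask has (lines per shot) * (Nz/Rz) ones", {
  expect_equal(sum(combined_mask(seg(116, 96, 2, 2, 8, 3))), 58 * 48)
  # R = 1x1, width 1 --> all ones
  expect_true(all(combined_mask(std(8, 6, 1, 1, 0)) == 1))
})

test_that("group masks partition the combined mask and form Ry x width lattices", {
  grid <- expand.grid(Ry = c(1, 2, 3), Rz = c(1, 2), N = c(2, 3), dkz = c(1, 3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    width <- g$N * g$Rz
    if (g$dkz >= width) next
    sch <- seg(24, 24, g$Ry, g$Rz, width, g$dkz)
    gm <- group_masks(sch)
    expect_equal(rowSums(gm, dims = 2), combined_mask(sch))
    expect_true(all(gm %in% c(0, 1)))
    # each group's sampled kz per ky line is a lattice of spacing = width
    for (gg in seq_len(dim(gm)[3])) for (ky in which(rowSums(gm[, , gg]) > 0)) {
      kz <- which(gm[ky, , gg] > 0) - 1
      expect_equal(length(kz), 24 / width)
      expect_true(length(unique(diff(sort(kz)))) <= 1)
    }
  }
})

test_that("CAIPI congruence: sampled kz satisfy kz = n*dkz (mod Rz) at ky line n", {
  for (cfgpars in list(c(2, 2, 8, 3), c(3, 2, 6, 3), c(2, 4, 8, 2))) {
    sch <- seg(24, 48, cfgpars[1], cfgpars[2], cfgpars[3], cfgpars[4])
    ln <- sch$lines
    expect_true(all((ln$kz - ln$line * cfgpars[4]) %% cfgpars[2] == 0))
  }
})

test_that("seg-CAIPI combined masks equal their standard blipped-CAIPI pairings", {
  # (width, dkz) <-> standard(Rz, dkz mod Rz), every protocol-table pairing
  pairings <- list(
    list(seg = c(116, 96, 2, 2, 8, 3),  std_dkz = 1),
    list(seg = c(116, 96, 2, 4, 8, 2),  std_dkz = 2),
    list(seg = c(140, 96, 3, 2, 8, 3),  std_dkz = 1),
    list(seg = c(140, 96, 3, 3, 6, 2),  std_dkz = 2),
    list(seg = c(174, 120, 3, 2, 4, 1), std_dkz = 1),
    list(seg = c(174, 120, 3, 2, 6, 3), std_dkz = 1),
    list(seg = c(174, 120, 3, 2, 8, 3), std_dkz = 1),
    list(seg = c(208, 120, 4, 2, 6, 3), std_dkz = 1))
  for (p in pairings) {
    s <- p$seg
    expect_equal(combined_mask(seg(s[1], s[2], s[3], s[4], s[5], s[6])),
                 combined_mask(std(s[1], s[2], s[3], s[4], p$std_dkz)),
                 info = paste(s, collapse = ","))
    expect_equal(p$std_dkz, s[6] %% s[4])
  }
  # the small documented case
  expect_equal(combined_mask(seg(12, 24, 2, 2, 8, 3)),
               combined_mask(std(12, 24, 2, 2, 1)))
})

test_that("blip-size advisor returns a valid blip and is sane for small cases", {
  cfg <- trajectory_config(24, 24, 2, 2, "seg_caipi", width = 8, dkz = 1)
  d <- suggest_dkz(cfg)
  expect_true(d >= 1 && d < 8)
})

test_that("schedule JSON serialization round-trips the line lists", {
  sch <- seg(12, 12, 3, 2, 4, 1)
  js <- jsonlite::fromJSON(schedule_to_json(sch), simplifyVector = TRUE)
  expect_equal(js$n_shots, 6)
  expect_equal(js$n_groups, 2)
  expect_equal(js$config$width, 4)
  expect_equal(unlist(js$shots$ky[1]), sch$lines$ky[sch$lines$shot == 0])
  expect_equal(unlist(js$shots$kz[6]), sch$lines$kz[sch$lines$shot == 5])
})
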