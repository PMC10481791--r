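# Filament coils: geometry builders, Biot-Savart fields, inductances.

test_that("circular loop fields match the textbook closed forms", {
  R <- 10e-3; I0 <- 2
  loop <- circular_loop_coil(R, n_segments = 512L, I0 = I0)
  seg <- as_tibble(loop)
  len <- sqrt((seg$xe - seg$xs)^2 + (seg$ye - seg$ys)^2 + (seg$ze - seg$zs)^2)
  expect_equal(nrow(seg), 512L)
  expect_equal(len, rep(2 * R * sin(pi / 512), 512L), tolerance = 1e-12)
  # center and on-axis flux density
  f0 <- coil_fields(loop, c(0, 0, 0))
  expect_equal(f0$Bz, MU0_TEST * I0 / (2 * R), tolerance = 1e-3)
  expect_equal(f0$Bx, 0, tolerance = 1e-15)
  z <- 5e-3
  fz <- coil_fields(loop, c(0, 0, z))
  expect_equal(fz$Bz, MU0_TEST * I0 * R^2 / (2 * (R^2 + z^2)^1.5), tolerance = 1e-3)
  # reversing all segments negates every field exactly
  seg_rev <- seg
  seg_rev[, c("xs", "ys", "zs", "xe", "ye", "ze")] <-
    seg[, c("xe", "ye", "ze", "xs", "ys", "zs")]
  rev <- filament_coil(seg_rev, I0 = I0)
  pts <- rbind(c(3e-3, 1e-3, 4e-3), c(-8e-3, 2e-3, -1e-3))
  expect_equal(as.matrix(coil_fields(rev, pts)[, -(1:3)]),
               -as.matrix(coil_fields(loop, pts)[, -(1:3)]))
  # linearity in the terminal current
  loop5 <- circular_loop_coil(R, n_segments = 512L, I0 = 5 * I0)
  expect_equal(as.matrix(coil_fields(loop5, pts)[, -(1:3)]),
               5 * as.matrix(coil_fields(loop, pts)[, -(1:3)]))
  # an observation point exactly on a filament names the offending point
  on_wire <- (loop$start[5, ] + loop$end[5, ]) / 2
  expect_error(coil_fields(loop, on_wire), "guard distance")
})

test_that("induced electric field is -dI/dt times the unit-current vector potential", {
  R <- 10e-3
  loop <- circular_loop_coil(R, n_segments = 512L, I0 = 7)
  pts <- rbind(c(4e-3, 0, 2e-3), c(0, 6e-3, -3e-3))
  expect_true(all(as.matrix(coil_E(loop, pts, dIdt = 0)[, 4:6]) == 0))
  E1 <- as.matrix(coil_E(loop, pts, dIdt = 1e6)[, 4:6])
  E2 <- as.matrix(coil_E(loop, pts, dIdt = 2e6)[, 4:6])
  expect_equal(E2, 2 * E1)
  # on-axis magnitude against a dense line-integral quadrature of the ring
  z <- 4e-3; dIdt <- 1e6
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  dl <- 2 * pi * R / 20000
  rr <- sqrt(R^2 + z^2)
  # A is azimuthal by symmetry; on the axis |A| = 0, so probe slightly off-axis
  p <- c(2e-3, 0, z)
  Aq <- c(0, 0, 0)
  for (k in seq_along(th)) {
    src <- c(R * cos(th[k]), R * sin(th[k]), 0)
    tang <- c(-sin(th[k]), cos(th[k]), 0)
    Aq <- Aq + tang * dl / sqrt(sum((p - src)^2))
  }
  Aq <- MU0_TEST / (4 * pi) * Aq
  Eo <- as.matrix(coil_E(loop, p, dIdt = dIdt)[, 4:6])
  expect_equal(as.numeric(Eo), -dIdt * Aq, tolerance = 1e-4)
})

test_that("helical spiral builder honors pitch profile, skew and twist", {
  pitch <- rep(110e-3 / 20, 20)
  sp <- helical_spiral_coil(9e-3, n_turns = 20, pitch = pitch,
                            skew_angle = 15 * pi / 180,
                            n_segments_per_turn = 32L)
  seg <- as_tibble(sp)
  expect_lte(max(seg$ze) - min(seg$zs), 110e-3 + 1e-9)
  # twisted bundle is strictly longer than the untwisted one
  args <- list(radius = 9e-3, n_turns = 5, pitch = 5e-3, bundle_radius = 2e-3,
               n_bundle_filaments = 7L, n_segments_per_turn = 32L)
  plain <- do.call(helical_spiral_coil, c(args, twist_pitch = Inf))
  twist <- do.call(helical_spiral_coil, c(args, twist_pitch = 20e-3))
  wire_len <- function(coil) {
    s <- as_tibble(coil)
    sum(sqrt((s$xe - s$xs)^2 + (s$ye - s$ys)^2 + (s$ze - s$zs)^2))
  }
  expect_gt(wire_len(twist), wire_len(plain))
  expect_error(helical_spiral_coil(9e-3, n_turns = 20, pitch = rep(5e-3, 10)),
               "pitch profile")
  expect_error(helical_spiral_coil(-1, n_turns = 2, pitch = 1e-3), "positive")
})

test_that("net weighted current through a cross-section equals one", {
  for (coil in list(circular_loop_coil(10e-3, wire_radius = 1e-3, n_segments = 64L,
                                       n_filaments = 19L),
                    helical_spiral_coil(9e-3, n_turns = 3, pitch = 5e-3,
                                        bundle_radius = 2e-3,
                                        n_bundle_filaments = 7L,
                                        n_segments_per_turn = 32L))) {
    seg <- as_tibble(coil)
    # weighted segment crossings of an (irrationally oriented) azimuthal
    # half-plane: one crossing per turn per filament
    phi <- 0.7
    ds <- sin(phi) * seg$xs - cos(phi) * seg$ys
    de <- sin(phi) * seg$xe - cos(phi) * seg$ye
    on_side <- cos(phi) * (seg$xs + seg$xe) + sin(phi) * (seg$ys + seg$ye) > 0
    up <- ds < 0 & de >= 0 & on_side
    dn <- ds > 0 & de <= 0 & on_side
    n_turns <- abs(sum(seg$weight[dn]) - sum(seg$weight[up])) # turns x unit current
    expect_equal(n_turns %% 1, 0, tolerance = 1e-9)
    expect_gte(n_turns, 1)
  }
})

test_that("Litz bundle sizing follows the packing table", {
  expect_equal(litz_bundle_radius(0.15e-3, 100), 0.15e-3 / 0.0902)
  expect_equal(round(litz_bundle_radius(0.15e-3, 100) * 1e3, 3), 1.663)
  expect_equal(litz_bundle_radius(2e-3, 1), 2e-3)
  expect_equal(litz_bundle_radius(0.30e-3, 100), 2 * litz_bundle_radius(0.15e-3, 100))
  expect_error(litz_bundle_radius(0.15e-3, 37), class = "coremag_unsupported_count")
})

test_that("Neumann self-inductance matches the uniform-current loop formula", {
  R <- 10e-3; a <- 1e-3
  loop <- circular_loop_coil(R, wire_radius = a, n_segments = 128L, n_filaments = 37L)
  L <- self_inductance(loop, check = FALSE)
  Lref <- MU0_TEST * R * (log(8 * R / a) - 1.75)
  expect_lt(abs(L / Lref - 1), 0.03)
  # independent of the terminal current
  loop2 <- circular_loop_coil(R, wire_radius = a, n_segments = 128L,
                              n_filaments = 37L, I0 = 123)
  expect_equal(self_inductance(loop2, check = FALSE), L)
  # single-filament thin loops warn about the log divergence
  expect_warning(self_inductance(circular_loop_coil(R, n_segments = 64L)),
                 class = "coremag_thin_loop")
})

test_that("mutual inductance is symmetric and matches the coaxial dipole limit", {
  R <- 10e-3; d <- 100e-3
  a <- circular_loop_coil(R, n_segments = 128L)
  bseg <- as_tibble(a)
  bseg$zs <- bseg$zs + d; bseg$ze <- bseg$ze + d
  b <- filament_coil(bseg)
  Mab <- mutual_inductance(a, b)
  expect_identical(Mab, mutual_inductance(b, a))
  # exact coaxial-loop mutual inductance via complete elliptic integrals
  skip_if_not_installed("pracma")
  k2 <- 4 * R * R / ((R + R)^2 + d^2)
  ek <- pracma::ellipke(k2)
  k <- sqrt(k2)
  Mexact <- MU0_TEST * sqrt(R * R) * ((2 / k - k) * ek$k - (2 / k) * ek$e)
  expect_lt(abs(Mab / Mexact - 1), 0.005)
  # the point-dipole form is the far limit; at d = 10 R the next-order term
  # still contributes a few percent, so compare the limit at d = 30 R
  dfar <- 300e-3
  bfar <- as_tibble(a)
  bfar$zs <- bfar$zs + dfar; bfar$ze <- bfar$ze + dfar
  Mfar <- mutual_inductance(a, filament_coil(bfar))
  expect_lt(abs(Mfar / (MU0_TEST * pi * R^4 / (2 * dfar^3)) - 1), 0.02)
  # perpendicular loops centered on a common axis couple to (nearly) zero
  cseg <- as_tibble(circular_loop_coil(R, n_segments = 128L))
  rot <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)) # x stays, loop now in x-z plane
  pts_s <- as.matrix(cseg[, c("xs", "ys", "zs")]) %*% t(rot)
  pts_e <- as.matrix(cseg[, c("xe", "ye", "ze")]) %*% t(rot)
  cseg[, c("xs", "ys", "zs")] <- pts_s + matrix(c(0, 0, d), nrow(cseg), 3, byrow = TRUE)
  cseg[, c("xe", "ye", "ze")] <- pts_e + matrix(c(0, 0, d), nrow(cseg), 3, byrow = TRUE)
  cc <- filament_coil(cseg)
  expect_lt(abs(mutual_inductance(a, cc)) / Mexact, 1e-10)
})

test_that("flux density is numerically divergence-free", {
  loop <- circular_loop_coil(10e-3, n_segments = 256L)
  h <- 1e-4
  base <- expand.grid(x = c(-4e-3, 0, 4e-3), y = c(-3e-3, 2e-3), z = c(2e-3, 6e-3))
  Bmax <- 0; divmax <- 0
  for (i in seq_len(nrow(base))) {
    p <- as.numeric(base[i, ])
    div <- 0
    for (k in 1:3) {
      dp <- c(0, 0, 0); dp[k] <- h
      Bp <- as.matrix(coil_fields(loop, rbind(p + dp, p - dp))[, 4:6])
      div <- div + (Bp[1, k] - Bp[2, k]) / (2 * h)
      Bmax <- max(Bmax, max(abs(Bp)))
    }
    divmax <- max(divmax, abs(div))
  }
  expect_lt(divmax, 1e-6 * Bmax / h)
})

test_that("coil CSV round trip and rigid transforms preserve geometry", {
  coil <- circular_loop_coil(10e-3, wire_radius = 1e-3, n_segments = 32L,
                             n_filaments = 7L, I0 = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coil_csv(coil, path)
  back <- read_coil_csv(path, I0 = 3)
  expect_equal(back$start, coil$start, tolerance = 1e-12)
  expect_equal(back$weight, coil$weight)
  Rm <- rotation_xyz(0.3, -0.2, 1.1)
  tr <- transform_coil(coil, Rm, c(1e-3, -2e-3, 5e-3))
  p <- c(4e-3, 1e-3, 2e-3)
  f0 <- as.matrix(coil_fields(coil, p)[, 7:9])
  f1 <- as.matrix(coil_fields(tr, matrix(Rm %*% p + c(1e-3, -2e-3, 5e-3), 1))[, 7:9])
  expect_equal(as.numeric(f1), as.numeric(Rm %*% as.numeric(f0)), tolerance = 1e-10)
})
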