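# psi dihedrals, flip classification, circular densities, theta angles.

test_that("psi of a constructed geometry is exact; symmetry properties hold", {
  tr <- make_psi_traj(120)
  s <- psi_series(tr, "A", 1L)
  expect_equal(s$psi, 120, tolerance = 1e-6)

  # mirror image inverts the sign (chirality)
  mir <- tr
  mir$coords[, 1, ] <- -mir$coords[, 1, ]
  expect_equal(psi_series(mir, "A", 1L)$psi, -120, tolerance = 1e-6)

  # rigid-body rotation leaves psi unchanged
  R <- poreflux:::rotation_matrix(c(1, 2, 3), 37)
  rot <- tr
  rot$coords[, , 1] <- tr$coords[, , 1] %*% t(R)
  expect_equal(psi_series(rot, "A", 1L)$psi, 120, tolerance = 1e-6)

  # chain-terminal residue: psi undefined
  expect_error(psi_series(tr, "A", 2L), "psi undefined")

  # independent oracle: bio3d torsion on random 4-point geometries
  set.seed(11)
  for (k in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    mine <- poreflux:::dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("flip classification recovers planted fractions and edge cases", {
  mk <- function(psi) data.frame(time = seq_along(psi) - 1, psi = psi)
  # constant inside the band
  f0 <- classify_flips(mk(rep(-38, 50)), band_center = -40)
  expect_equal(f0$flip_fraction, 0)
  expect_true(is.na(f0$first_flip_time))
  # constant outside
  f1 <- classify_flips(mk(rep(140, 50)), band_center = -40)
  expect_equal(f1$flip_fraction, 1)
  expect_equal(f1$first_flip_time, 0)

  # telegraph fixture: recovered fraction within 1% of planted
  s <- gen_dihedral_series(synth_spec(seed = 31, duration = 4000, dt = 1,
                                      flip_rate = 5),
                           state_means = c(-40, 140), noise_sd = 5)
  fs <- classify_flips(data.frame(time = s$times, psi = s$psi),
                       band_center = -40)
  expect_lt(abs(fs$flip_fraction - mean(s$labels == 2L)), 0.01)

  # zero hysteresis reduces to plain circular band membership
  set.seed(4)
  psi <- poreflux:::wrap_angle(runif(500, -180, 180))
  fz <- classify_flips(mk(psi), band_center = -40, band_halfwidth = 40,
                       hysteresis = 0)
  plain <- poreflux:::circ_dist(psi, -40) > 40
  expect_equal(as.character(fz$state), ifelse(plain, "flipped",
                                              "crystallographic"))
  expect_error(classify_flips(mk(psi), 0, band_halfwidth = 95), "180")
})

test_that("hysteresis suppresses chatter at the band edge", {
  # oscillation just past the edge: plain membership flickers, Schmitt holds
  psi <- rep(c(1, 12), 20)  # band centre 0, halfwidth 8 -> edge at 8
  f <- classify_flips(data.frame(time = seq_along(psi), psi = psi),
                      band_center = 0, band_halfwidth = 8, hysteresis = 10)
  expect_equal(f$flip_fraction, 0)  # 12 < 8 + 10: never leaves
  f2 <- classify_flips(data.frame(time = seq_along(psi), psi = psi),
                       band_center = 0, band_halfwidth = 8, hysteresis = 0)
  expect_equal(f2$flip_fraction, 0.5)
})

test_that("circular density integrates to one and finds planted modes", {
  set.seed(5)
  # unimodal: all mass near one angle
  d1 <- angle_distribution(rep(30, 100) + rnorm(100, 0, 0.01), bandwidth = 2)
  expect_equal(d1$angle[which.max(d1$density)], 30, tolerance = 1)
  # integral over the circle (trapezoid over the closed grid)
  step <- diff(d1$angle[1:2])
  integral <- sum(d1$density[-1] + d1$density[-nrow(d1)]) / 2 * step
  expect_equal(integral, 1, tolerance = 1e-6)

  # bimodal with means straddling the wrap seam
  ang <- c(rnorm(2000, -40, 8), poreflux:::wrap_angle(rnorm(2000, 170, 8)))
  d2 <- angle_distribution(ang, bandwidth = 6)
  find_mode_near <- function(d, centre, halfw = 30) {
    sel <- poreflux:::circ_dist(d$angle, centre) < halfw
    d$angle[sel][which.max(d$density[sel])]
  }
  expect_lt(poreflux:::circ_dist(find_mode_near(d2, -40), -40), 2)
  expect_lt(poreflux:::circ_dist(find_mode_near(d2, 170), 170), 2)
  expect_error(angle_distribution(1), "2 samples")
})

test_that("theta angle measures helix rotation against the reference", {
  hx <- make_helix_system()
  tr0 <- traj_from_coords(hx$system, list(hx$coords))
  th0 <- m4_theta(tr0, "A", hx$system, hx$coords)
  expect_equal(th0$theta, 0, tolerance = 1e-8)

  # rotate 15 deg about an axis through CA(315) perpendicular to the helix
  R <- poreflux:::rotation_matrix(c(0, 0, 1), 15)
  pivot <- hx$coords[1, ]
  rot <- sweep(sweep(hx$coords, 2, pivot) %*% t(R), 2, pivot, "+")
  th15 <- m4_theta(traj_from_coords(hx$system, list(rot)), "A",
                   hx$system, hx$coords)
  expect_equal(th15$theta, 15, tolerance = 1e-6)

  # pure translation: theta unchanged
  th_t <- m4_theta(traj_from_coords(hx$system, list(hx$coords + 12)), "A",
                   hx$system, hx$coords)
  expect_equal(th_t$theta, 0, tolerance = 1e-8)

  # global rotation applied to both frame and reference: invariant
  both <- hx$coords %*% t(R)
  th_b <- m4_theta(traj_from_coords(hx$system, list(both %*% t(R))), "A",
                   hx$system, both)
  expect_equal(th_b$theta, 15, tolerance = 1e-6)

  # mismatched residue range errors
  short <- make_helix_system(resids = 315:330)
  expect_error(m4_theta(traj_from_coords(short$system, list(short$coords)),
                        "A", hx$system, hx$coords), "mismatch")
})
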