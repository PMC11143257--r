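# The planted-truth generators: determinism, edge cases, and marginal
# statistics.

test_that("generators are pure functions of spec and seed", {
  sp <- synth_spec(seed = 12, duration = 200, dt = 1)
  a <- gen_ion_channel_traj(sp)
  b <- gen_ion_channel_traj(sp)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$events, b$events)
  expect_identical(gen_dihedral_series(sp)$psi, gen_dihedral_series(sp)$psi)
  expect_identical(gen_hills(sp, 50)$hills, gen_hills(sp, 50)$hills)
  expect_identical(gen_dose_response(seed = 5, noise_sd = 3),
                   gen_dose_response(seed = 5, noise_sd = 3))
})

test_that("zero permeation rate plants no events and ions stay on one side", {
  g <- gen_ion_channel_traj(synth_spec(seed = 3, duration = 300, dt = 1,
                                       permeation_rate = 0))
  expect_equal(nrow(g$events), 0)
  ax <- compute_pore_axis(g$trajectory, g$sf_selection)
  ac <- poreflux:::axial_coordinates(g$trajectory, g$ion_selection, ax)
  for (i in seq_along(g$ion_selection)) {
    dz <- ac$dz[i, ]
    expect_true(all(dz < g$lower) || all(dz > g$upper))
  }
})

test_that("excessive permeation rates are rejected rather than aliased", {
  expect_error(
    gen_ion_channel_traj(synth_spec(seed = 1, duration = 50, dt = 1,
                                    permeation_rate = 2000)),
    "rate too high")
})

test_that("seeds differ in event times but share marginal statistics", {
  gapset <- function(seeds) {
    unlist(lapply(seeds, function(s) {
      tt <- gen_ion_channel_traj(synth_spec(seed = s, duration = 2000, dt = 1,
                                            permeation_rate = 5))$events$time
      if (length(tt) > 1) diff(tt) else numeric(0)
    }))
  }
  g1 <- gapset(1:25)
  g2 <- gapset(26:50)
  expect_false(identical(g1, g2))
  # same inter-event law across seed groups
  expect_gt(suppressWarnings(stats::ks.test(g1, g2))$p.value, 0.01)
  # counts are Poisson-dispersed around rate * duration
  counts <- vapply(301:340, function(s) {
    nrow(gen_ion_channel_traj(synth_spec(seed = s, duration = 1000, dt = 1,
                                         permeation_rate = 5))$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 40))
  expect_lt(stats::var(counts) / mean(counts), 2)
})

test_that("telegraph dihedral series carries accurate labels and wraps", {
  # flip_rate 0: constant label series
  s0 <- gen_dihedral_series(synth_spec(seed = 1, duration = 100, dt = 1,
                                       flip_rate = 0),
                            state_means = c(-40, 140))
  expect_true(all(s0$labels == 1L))

  # labels agree with a midpoint threshold at small noise
  s <- gen_dihedral_series(synth_spec(seed = 8, duration = 3000, dt = 1,
                                      flip_rate = 5),
                           state_means = c(-40, 140), noise_sd = 5)
  thresh <- circ_dist_label <- abs(poreflux:::wrap_angle(s$psi - (-40))) > 90
  agreement <- mean((s$labels == 2L) == thresh)
  expect_gte(agreement, 0.99)

  # wrap convention at the boundary
  sw <- gen_dihedral_series(synth_spec(seed = 2, duration = 500, dt = 1,
                                       flip_rate = 0),
                            state_means = c(175, -40), noise_sd = 5)
  expect_true(all(sw$psi > -180 & sw$psi <= 180))
  expect_true(any(sw$psi < -170))  # noise actually crossed the seam
})

test_that("distance series realizes the planted contact probability", {
  g1 <- gen_distance_series(synth_spec(seed = 1, duration = 100, dt = 1,
                                       contact_p = 1))
  expect_true(all(g1$distance < 5))
  g0 <- gen_distance_series(synth_spec(seed = 1, duration = 100, dt = 1,
                                       contact_p = 0))
  expect_true(all(g0$distance > 5))
  g <- gen_distance_series(synth_spec(seed = 6, duration = 10000, dt = 1,
                                      contact_p = 0.8))
  sd3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(mean(g$distance < 5) - 0.8), sd3)
  expect_equal(mean(g$contact), g$realized_p)
})

test_that("hills obey the well-tempered height decay and sample symmetrically", {
  sp <- synth_spec(seed = 3)
  one <- gen_hills(sp, n_hills = 1)
  expect_equal(nrow(one$hills), 1)
  expect_equal(one$hills$height, sp$hill_height)

  g <- gen_hills(sp, n_hills = 2000)
  expect_lt(mean(utils::tail(g$hills$height, 200)),
            mean(utils::head(g$hills$height, 200)))

  # symmetric double well: hill centres split evenly about the midline
  sym <- synth_spec(seed = 9, fes_definition = list(
    list(center = c(-90, 0), depth = 25, width = 30),
    list(center = c(90, 0), depth = 25, width = 30)))
  gs <- gen_hills(sym, n_hills = 4000)
  frac_left <- mean(gs$hills$cv1 < 0)
  expect_lt(abs(frac_left - 0.5), 0.1)

  expect_error(synth_spec(bias_factor = 1), "bias_factor")
})

test_that("dose-response generator hits the Hill-curve anchors", {
  d <- gen_dose_response(ic50 = 7, concentrations = c(7, 7000), noise_sd = 0)
  expect_equal(d$pct_inhibition[1], 50)
  expect_gt(d$pct_inhibition[2], 99.8)
  expect_error(gen_dose_response(concentrations = c(-1, 2, 3, 4)), "positive")
})
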