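# Pore axis, crossing detection, conductance arithmetic and Dz traces.

test_that("pore axis is the mass-weighted SF centre with the +7 convention", {
  sys <- particle_system(c("X1", "X2"), c("UNK", "UNK"), c(1L, 2L), c("A", "A"),
                         element = c("C", "C"), mass = c(1, 3))
  coords <- array(c(0, 0, 0, 0, 0, 4), c(2, 3, 1))
  # rows are atoms: atom1 (0,0,0), atom2 (0,0,4)
  coords <- array(0, c(2, 3, 1))
  coords[1, , 1] <- c(0, 0, 0)
  coords[2, , 1] <- c(0, 0, 4)
  tr <- trajectory(sys, coords, 0, c(100, 100, 100))
  ax <- compute_pore_axis(tr, c(0L, 1L))
  expect_equal(ax$oz, 3)  # weighted mean of 0 and 4 with masses 1, 3
  expect_equal(attr(ax, "offset"), 7)
  # the SF centre itself reports at +7 on the axis
  ac <- poreflux:::axial_coordinates(tr, 1L, ax)
  expect_equal(ac$dz[1, 1], 4 - 3 + 7)
  expect_error(compute_pore_axis(tr, integer(0)), "empty")
})

test_that("translation moves the origin but not axial ion coordinates", {
  g <- gen_ion_channel_traj(synth_spec(seed = 21, duration = 300, dt = 1))
  tr <- g$trajectory
  ax <- compute_pore_axis(tr, g$sf_selection)
  shifted <- tr
  shifted$coords <- tr$coords + 5
  ax2 <- compute_pore_axis(shifted, g$sf_selection)
  expect_equal(ax2$oz, ax$oz + 5)
  a1 <- poreflux:::axial_coordinates(tr, g$ion_selection, ax)
  a2 <- poreflux:::axial_coordinates(shifted, g$ion_selection, ax2)
  expect_equal(a1$dz, a2$dz, tolerance = 1e-10)
})

test_that("the state machine counts full traversals once and ignores feints", {
  lower <- 1; upper <- 13  # reported-axis planes; raw z = dz + 33
  # single monotone traversal
  tr <- make_ion_traj(seq(28, 52, by = 2))
  ax <- compute_pore_axis(tr, 0L)
  ev <- detect_permeation_events(tr, 1L, ax, lower, upper)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "outward")
  expect_false(ev$undersampled)

  # inward traversal
  ev2 <- detect_permeation_events(make_ion_traj(seq(52, 28, by = -2)), 1L,
                                  ax, lower, upper)
  expect_equal(ev2$direction, "inward")

  # oscillation across the lower boundary only: no events
  osc <- make_ion_traj(33 + c(-3, 2, -3, 3, -2, 4, -3))
  expect_equal(nrow(detect_permeation_events(osc, 1L,
                                             compute_pore_axis(osc, 0L),
                                             lower, upper)), 0)

  # a mid-pore retreat voids the attempt; the later full pass still counts once
  z <- 33 + c(-2, 3, 8, 3, -2, 3, 8, 12, 15)
  tr3 <- make_ion_traj(z)
  ev3 <- detect_permeation_events(tr3, 1L, compute_pore_axis(tr3, 0L),
                                  lower, upper)
  expect_equal(nrow(ev3), 1)

  # leaving the cylinder radially mid-slab voids the traversal
  nf <- 13
  xy <- matrix(20, nf, 2)
  xy[7, ] <- c(35, 20)  # radial excursion beyond 8 A
  tr4 <- make_ion_traj(seq(28, 52, by = 2), ion_xy = xy)
  ev4 <- detect_permeation_events(tr4, 1L, compute_pore_axis(tr4, 0L),
                                  lower, upper)
  expect_equal(nrow(ev4), 0)

  # a single-step jump across both planes is counted but flagged
  jump <- make_ion_traj(c(30, 31, 50, 51))
  evj <- detect_permeation_events(jump, 1L, compute_pore_axis(jump, 0L),
                                  lower, upper)
  expect_equal(nrow(evj), 1)
  expect_true(evj$undersampled)
})

test_that("detected counts equal planted counts; stride-2 refinement agrees", {
  for (s in 1:8) {
    g <- gen_ion_channel_traj(synth_spec(seed = 400 + s, duration = 600, dt = 1,
                                         permeation_rate = (s %% 5) * 2))
    ax <- compute_pore_axis(g$trajectory, g$sf_selection)
    ev <- detect_permeation_events(g$trajectory, g$ion_selection, ax,
                                   g$lower, g$upper)
    expect_equal(nrow(ev), nrow(g$events))
    tr2 <- stride_frames(g$trajectory, 2)
    ax2 <- compute_pore_axis(tr2, g$sf_selection)
    ev_s2 <- detect_permeation_events(tr2, g$ion_selection, ax2,
                                      g$lower, g$upper)
    expect_equal(nrow(ev_s2), nrow(g$events))
  }
})

test_that("conductance follows N e / (t V) exactly", {
  e <- 1.602176634e-19
  hand <- 5 * e / (1000e-9) / (200e-3) * 1e12
  expect_equal(conductance(5, 1000, 200), hand, tolerance = 1e-12)
  expect_equal(round(conductance(5, 1000, 200)), 4)
  expect_equal(conductance(0, 1000, 200), 0)
  expect_equal(conductance(5, 2000, 200), conductance(5, 1000, 200) / 2)
  expect_error(conductance(5, 1000, 0), "V = 0")
  expect_error(conductance(5, 0, 200), "positive")

  sm <- permeation_summary(list(data.frame(x = 1:3), data.frame(x = 1:2)),
                           t_ns = 1000, V_mV = 200)
  expect_equal(sm$N, 5)
  expect_equal(sm$per_run, c(3L, 2L))
  expect_equal(sm$gamma, conductance(5, 2000, 200))
})

test_that("dz_trace measures signed height above the plane centre", {
  sys <- particle_system(c("P", "P", "C12"), c("POPC", "POPC", "LIG"),
                         c(1L, 2L, 3L), c("L", "L", "X"))
  mk <- function(zlig) {
    coords <- array(0, c(3, 3, length(zlig)))
    for (f in seq_along(zlig)) {
      coords[1, , f] <- c(0, 0, 10)
      coords[2, , f] <- c(5, 0, 14)
      coords[3, , f] <- c(2, 2, zlig[f])
    }
    trajectory(sys, coords, seq_along(zlig) - 1, c(100, 100, 100))
  }
  expect_equal(dz_trace(mk(12), 2L, c(0L, 1L))$dz, 0)   # at the plane centre
  expect_equal(dz_trace(mk(22), 2L, c(0L, 1L))$dz, 10)

  # planted linear drift of -8 A recovered within 5%
  set.seed(7)
  z0 <- 20
  drift <- seq(0, -8, length.out = 200)
  tr <- mk(z0 + drift + rnorm(200, 0, 0.3))
  d <- dz_trace(tr, 2L, c(0L, 1L))
  fit <- stats::lm(dz ~ time, data = d)
  total <- unname(stats::coef(fit)[2]) * 199
  expect_lt(abs(total - (-8)) / 8, 0.05)
  expect_error(dz_trace(mk(12), 2L, integer(0)), "plane")
})
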