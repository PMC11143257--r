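# Synthetic trajectory/hills/dose-response generators with planted ground
# truth. Every generator is a pure function of (spec, seed): identical inputs
# give bit-identical output. Planted truth is returned alongside the data and
# is never read by the analysis modules.

#' Specification for the synthetic generators
#'
#' Defaults encode the study conditions the analysis stages are verified
#' against: 1 us trajectories, a permeation rate of 5 events/us (the average
#' outward K+ rate of a conductive run at +200 mV), well-tempered hills with
#' h0 = 1.2 kJ/mol, sigma = 0.25 rad and bias factor 8, and an 8 A pore
#' cylinder around a selectivity filter whose backbone centre sits at +7 A on
#' the reported pore axis.
#'
#' @param seed integer RNG seed.
#' @param duration trajectory length in ns.
#' @param dt frame spacing in ns.
#' @param pore_radius cylindrical gate radius in angstrom.
#' @param pore_half_length half-extent of the SF along z in angstrom.
#' @param permeation_rate planted full-traversal rate in events per us.
#' @param n_bulk_ions number of non-permeating bulk ions.
#' @param flip_rate telegraph switching rate for dihedral series, events/us.
#' @param contact_p planted per-frame contact probability.
#' @param fes_definition list of Gaussian wells, each
#'   `list(center = c(cv1, cv2) deg, depth = kJ/mol, width = deg)`.
#' @param hill_height initial Gaussian hill height h0, kJ/mol.
#' @param hill_sigma hill width in degrees (0.25 rad by default).
#' @param bias_factor well-tempered bias factor (> 1).
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       duration = 1000,
                       dt = 1,
                       pore_radius = 8,
                       pore_half_length = 3,
                       permeation_rate = 5,
                       n_bulk_ions = 8,
                       flip_rate = 5,
                       contact_p = 0.5,
                       fes_definition = default_double_well(),
                       hill_height = 1.2,
                       hill_sigma = 0.25 * 180 / pi,
                       bias_factor = 8) {
  spec <- list(seed = as.integer(seed), duration = duration, dt = dt,
               pore_radius = pore_radius, pore_half_length = pore_half_length,
               permeation_rate = permeation_rate, n_bulk_ions = n_bulk_ions,
               flip_rate = flip_rate, contact_p = contact_p,
               fes_definition = fes_definition, hill_height = hill_height,
               hill_sigma = hill_sigma, bias_factor = bias_factor)
  validate_synth_spec(spec)
  class(spec) <- "synth_spec"
  spec
}

validate_synth_spec <- function(spec) {
  with(spec, {
    if (dt <= 0) stop("dt must be positive")
    if (duration <= 0) stop("duration must be positive")
    if (permeation_rate < 0 || flip_rate < 0) stop("rates must be >= 0")
    if (contact_p < 0 || contact_p > 1) stop("contact_p must be in [0, 1]")
    if (pore_radius <= 0) stop("pore_radius must be positive")
    if (hill_height < 0) stop("hill_height must be >= 0")
    if (bias_factor <= 1) stop("bias_factor must exceed 1")
  })
  invisible(spec)
}

#' Symmetric-in-shape double-well free-energy surface definition
#'
#' Two Gaussian wells 4 kJ/mol apart in depth (one contour step), used as the
#' desk-scale ground truth for free-energy reconstruction tests.
#' @export
default_double_well <- function() {
  list(
    list(center = c(-60, -60), depth = 30, width = 30),
    list(center = c(120, 60), depth = 26, width = 30)
  )
}

# Geometry constants for the synthetic channel (angstrom, raw box frame).
SYNTH_BOX <- c(40, 40, 80)
SYNTH_SF_Z <- 40          # raw z of the SF backbone centre
SYNTH_AXIS_OFFSET <- 7    # reported axial position of the SF centre
SYNTH_TRAVERSAL_FRAMES <- 12L

#' Generate a synthetic ion-channel trajectory with planted permeation events
#'
#' Builds a static pseudo selectivity filter (two chains of glycine backbone
#' atoms ringing the pore axis) plus K+ ions. Bulk ions perform reflected 1D
#' Brownian motion confined to one side of the pore and never traverse. At
#' Poisson-planted times a dedicated carrier ion is driven monotonically from
#' below the lower crossing plane to above the upper one, staying close to
#' the axis, over `r SYNTH_TRAVERSAL_FRAMES` frames.
#'
#' @param spec a [synth_spec()].
#' @return list with `trajectory` (a [trajectory()]), `events` (data.frame of
#'   planted event times, ns, and carrier atom indices), `sf_selection`
#'   (0-based indices of SF backbone atoms), `ion_selection`, `lower`/`upper`
#'   (crossing-plane defaults, reported-axis angstrom) and `spec`.
#' @export
gen_ion_channel_traj <- function(spec) {
  validate_synth_spec(spec)
  set.seed(spec$seed)
  n_fr <- as.integer(round(spec$duration / spec$dt))
  times <- (seq_len(n_fr) - 1) * spec$dt
  trav_ns <- SYNTH_TRAVERSAL_FRAMES * spec$dt

  # planted event schedule: Poisson count, minimum separation one traversal
  lambda <- spec$permeation_rate * spec$duration / 1000
  n_ev <- stats::rpois(1, lambda)
  margin <- trav_ns + 2 * spec$dt
  if (n_ev > 0 && n_ev * margin > spec$duration - 2 * margin) {
    stop("permeation rate too high: ", n_ev,
         " events cannot be resolved at dt = ", spec$dt, " ns")
  }
  ev_times <- numeric(0)
  if (n_ev > 0) {
    for (try in seq_len(1000)) {
      cand <- sort(stats::runif(n_ev, margin, spec$duration - margin))
      if (n_ev == 1 || min(diff(cand)) >= margin) {
        ev_times <- cand
        break
      }
    }
    if (!length(ev_times)) {
      stop("permeation rate too high: could not place ", n_ev,
           " events with ", margin, " ns separation")
    }
  }

  sf <- synth_sf_atoms()
  n_sf <- nrow(sf$table)
  n_car <- n_ev
  n_blk <- spec$n_bulk_ions
  n_ion <- n_car + n_blk
  ion_tab <- data.frame(
    atom_name = rep("K", n_ion),
    residue_name = rep("K", n_ion),
    residue_id = seq_len(n_ion),
    chain_id = rep("I", n_ion)
  )
  sys <- particle_system(
    atom_name = c(sf$table$atom_name, ion_tab$atom_name),
    residue_name = c(sf$table$residue_name, ion_tab$residue_name),
    residue_id = c(sf$table$residue_id, ion_tab$residue_id),
    chain_id = c(sf$table$chain_id, ion_tab$chain_id)
  )

  coords <- array(0, c(n_sf + n_ion, 3, n_fr))
  for (f in seq_len(n_fr)) coords[seq_len(n_sf), , f] <- sf$coords

  z_lower_raw <- SYNTH_SF_Z - SYNTH_AXIS_OFFSET - 6 + 3  # raw z at Dz = -3 -> 30
  z_upper_raw <- SYNTH_SF_Z + 10                          # raw z at Dz = 17 -> 50
  step_sd <- sqrt(2 * 0.2 * spec$dt)  # nominal D = 0.2 A^2/ns

  # carrier ions: lower bulk before their event, driven traversal, upper after
  for (j in seq_len(n_car)) {
    idx <- n_sf + j
    t0 <- ev_times[j]
    f0 <- findInterval(t0, times)
    fend <- min(f0 + SYNTH_TRAVERSAL_FRAMES - 1L, n_fr)
    pre <- seq_len(max(f0 - 1L, 0L))
    post <- if (fend < n_fr) (fend + 1L):n_fr else integer(0)
    trav <- f0:fend
    coords[idx, 3, pre] <- reflected_walk(length(pre), 5, 28, z_lower_raw - 1,
                                          step_sd)
    coords[idx, 1, pre] <- reflected_walk(length(pre), 4, 36, 20, 3 * step_sd)
    coords[idx, 2, pre] <- reflected_walk(length(pre), 4, 36, 20, 3 * step_sd)
    zt <- seq(z_lower_raw, z_upper_raw, length.out = length(trav))
    coords[idx, 3, trav] <- zt
    coords[idx, 1, trav] <- 20 + stats::runif(length(trav), -1.5, 1.5)
    coords[idx, 2, trav] <- 20 + stats::runif(length(trav), -1.5, 1.5)
    coords[idx, 3, post] <- reflected_walk(length(post), 52, 75, z_upper_raw + 1,
                                           step_sd)
    coords[idx, 1, post] <- reflected_walk(length(post), 4, 36, 20, 3 * step_sd)
    coords[idx, 2, post] <- reflected_walk(length(post), 4, 36, 20, 3 * step_sd)
  }

  # bulk ions: confined to one compartment, never traversing
  for (j in seq_len(n_blk)) {
    idx <- n_sf + n_car + j
    below <- j %% 2 == 0
    zlim <- if (below) c(5, 28) else c(52, 75)
    coords[idx, 3, ] <- reflected_walk(n_fr, zlim[1], zlim[2],
                                       stats::runif(1, zlim[1], zlim[2]),
                                       step_sd)
    coords[idx, 1, ] <- reflected_walk(n_fr, 4, 36, stats::runif(1, 10, 30),
                                       3 * step_sd)
    coords[idx, 2, ] <- reflected_walk(n_fr, 4, 36, stats::runif(1, 10, 30),
                                       3 * step_sd)
  }

  traj <- trajectory(sys, coords, times, SYNTH_BOX)
  events <- data.frame(
    time = ev_times,
    ion_id = if (n_car) n_sf + seq_len(n_car) - 1L else integer(0)
  )
  list(
    trajectory = traj,
    events = events,
    sf_selection = seq_len(n_sf) - 1L,
    ion_selection = n_sf + seq_len(n_ion) - 1L,
    lower = SYNTH_AXIS_OFFSET - spec$pore_half_length - 3,
    upper = SYNTH_AXIS_OFFSET + spec$pore_half_length + 3,
    spec = spec
  )
}

# Static pseudo-SF: 2 chains x 4 glycine residues, backbone atoms on a ring
# of radius 3 A about the pore axis, symmetric so the centre of mass sits
# exactly on (20, 20, SYNTH_SF_Z).
synth_sf_atoms <- function() {
  z_levels <- SYNTH_SF_Z + c(-3, -1, 1, 3)
  ring <- rbind(c(3, 0), c(0, 3), c(-3, 0), c(0, -3))
  names <- c("N", "CA", "C", "O")
  tab <- NULL
  xyz <- NULL
  for (ch in c("A", "B")) {
    for (r in seq_along(z_levels)) {
      for (a in seq_along(names)) {
        # opposite ring positions for the two chains keep the COM on-axis
        pos <- ring[a, ] * if (ch == "A") 1 else -1
        tab <- rbind(tab, data.frame(
          atom_name = names[a], residue_name = "GLY",
          residue_id = r, chain_id = ch
        ))
        xyz <- rbind(xyz, c(20 + pos[1], 20 + pos[2], z_levels[r]))
      }
    }
  }
  colnames(xyz) <- c("x", "y", "z")
  list(table = tab, coords = xyz)
}

# Reflected Brownian walk of length n within [lo, hi], started at z0.
reflected_walk <- function(n, lo, hi, z0, step_sd) {
  if (n == 0) return(numeric(0))
  z <- cumsum(c(z0, stats::rnorm(n - 1, 0, step_sd)))
  w <- hi - lo
  # reflect into [lo, hi] by folding
  z <- abs((z - lo) %% (2 * w) - w)
  lo + pmin(z, w)
}

#' Generate a two-state telegraph dihedral series with planted labels
#'
#' Dwell times are exponential with mean `1000 / flip_rate` ns; wrapped
#' Gaussian noise is added around the state mean.
#'
#' @param spec a [synth_spec()].
#' @param state_means two angles in degrees (state 1 = "crystallographic",
#'   state 2 = "flipped").
#' @param noise_sd Gaussian noise standard deviation in degrees; the state
#'   means must differ by more than 4 * `noise_sd`.
#' @return list with `times` (ns), `psi` (degrees, wrapped to (-180, 180]),
#'   `labels` (1/2 planted state per frame) and `spec`.
#' @export
gen_dihedral_series <- function(spec, state_means = c(-40, 140), noise_sd = 5) {
  validate_synth_spec(spec)
  if (circ_dist(state_means[1], state_means[2]) <= 4 * noise_sd) {
    stop("state means must differ by more than 4 * noise_sd")
  }
  set.seed(spec$seed)
  n_fr <- as.integer(round(spec$duration / spec$dt))
  times <- (seq_len(n_fr) - 1) * spec$dt
  labels <- integer(n_fr)
  if (spec$flip_rate == 0) {
    labels[] <- 1L
  } else {
    mean_dwell <- 1000 / spec$flip_rate  # ns
    t <- 0
    state <- 1L
    f <- 1L
    while (f <= n_fr) {
      dwell <- stats::rexp(1, rate = 1 / mean_dwell)
      f_end <- min(n_fr, findInterval(t + dwell, times))
      if (f_end >= f) labels[f:f_end] <- state
      t <- t + dwell
      f <- f_end + 1L
      state <- 3L - state
    }
  }
  psi <- wrap_angle(state_means[labels] + stats::rnorm(n_fr, 0, noise_sd))
  list(times = times, psi = psi, labels = labels, spec = spec)
}

#' Generate a residue-pair distance series with planted contact probability
#'
#' Frame contact states are i.i.d. Bernoulli(`contact_p`); contact frames get
#' distances jittered below `contact_distance`, non-contact frames above
#' `far_distance`.
#'
#' @param spec a [synth_spec()].
#' @param contact_distance distance assigned to contact frames (angstrom,
#'   must be below 5).
#' @param far_distance distance assigned to non-contact frames (above 5).
#' @return list with `times`, `distance`, `contact` (logical planted states),
#'   `realized_p` and `spec`.
#' @export
gen_distance_series <- function(spec, contact_distance = 4, far_distance = 8) {
  validate_synth_spec(spec)
  if (!(contact_distance < 5 && far_distance > 5)) {
    stop("need contact_distance < 5 A < far_distance")
  }
  set.seed(spec$seed + 1L)
  n_fr <- as.integer(round(spec$duration / spec$dt))
  contact <- stats::runif(n_fr) < spec$contact_p
  jitter_c <- stats::runif(n_fr, 0, min(0.8, contact_distance / 2))
  jitter_f <- stats::runif(n_fr, 0, far_distance - 5 - 1e-6)
  distance <- ifelse(contact, contact_distance - jitter_c,
                     far_distance + jitter_f)
  list(times = (seq_len(n_fr) - 1) * spec$dt, distance = distance,
       contact = contact, realized_p = mean(contact), spec = spec)
}

# Evaluate the ground-truth FES (kJ/mol) defined by Gaussian wells at points
# (s1, s2) in degrees, periodic in both dimensions. Not min-shifted.
fes_true_value <- function(s1, s2, wells) {
  v <- 0
  for (w in wells) {
    d1 <- wrap_angle(s1 - w$center[1])
    d2 <- wrap_angle(s2 - w$center[2])
    v <- v - w$depth * exp(-(d1^2 + d2^2) / (2 * w$width^2))
  }
  v
}

#' Generate a well-tempered metadynamics hills log from a known surface
#'
#' A Metropolis walker samples the ground-truth surface plus the accumulated
#' bias (maintained on a grid); every deposited hill's height follows the
#' well-tempered rule `h_i = h0 * exp(-V(s_i) / ((gamma - 1) kB T))` with
#' kB T at 300 K. Hill times advance 1 ps per hill (a deposition stride of
#' 250 MD steps at a 4 fs timestep).
#'
#' @param spec a [synth_spec()]; `fes_definition`, `hill_height`,
#'   `hill_sigma` and `bias_factor` are used.
#' @param n_hills number of hills to deposit.
#' @param grid_step grid spacing in degrees for the bias bookkeeping and the
#'   returned ground truth.
#' @param n_sweeps Metropolis proposals between depositions.
#' @return list with `hills` (a `hills_log`), `fes_true` (list `cv1`, `cv2`,
#'   `F` matrix, min-shifted) and `spec`.
#' @export
gen_hills <- function(spec, n_hills, grid_step = 5, n_sweeps = 10) {
  validate_synth_spec(spec)
  if (!length(spec$fes_definition)) stop("fes_definition must be non-empty")
  set.seed(spec$seed + 2L)
  gamma <- spec$bias_factor
  sigma <- spec$hill_sigma
  h0 <- spec$hill_height
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  ng <- length(grid)
  Ftrue <- outer(grid, grid,
                 function(a, b) fes_true_value(a, b, spec$fes_definition))
  bias <- matrix(0, ng, ng)

  bilinear <- function(s1, s2) {
    # periodic nearest-node lookup is enough for the walk
    i <- ((round((s1 + 180) / grid_step)) %% ng) + 1
    j <- ((round((s2 + 180) / grid_step)) %% ng) + 1
    bias[i, j]
  }

  # start in the deepest well
  depths <- vapply(spec$fes_definition, function(w) w$depth, numeric(1))
  s <- spec$fes_definition[[which.max(depths)]]$center
  u_cur <- fes_true_value(s[1], s[2], spec$fes_definition) + bilinear(s[1], s[2])

  rec <- matrix(0, n_hills, 4)  # cv1, cv2, height, bias_at_centre
  for (i in seq_len(n_hills)) {
    for (k in seq_len(n_sweeps)) {
      prop <- wrap_angle(s + stats::rnorm(2, 0, 25))
      u_prop <- fes_true_value(prop[1], prop[2], spec$fes_definition) +
        bilinear(prop[1], prop[2])
      if (u_prop <= u_cur ||
          stats::runif(1) < exp(-(u_prop - u_cur) / KBT_300K)) {
        s <- prop
        u_cur <- u_prop
      }
    }
    vb <- bilinear(s[1], s[2])
    h <- h0 * exp(-vb / ((gamma - 1) * KBT_300K))
    gx <- exp(-wrap_angle(grid - s[1])^2 / (2 * sigma^2))
    gy <- exp(-wrap_angle(grid - s[2])^2 / (2 * sigma^2))
    bias <- bias + h * outer(gx, gy)
    u_cur <- fes_true_value(s[1], s[2], spec$fes_definition) +
      bilinear(s[1], s[2])
    rec[i, ] <- c(s[1], s[2], h, vb)
  }

  hills <- data.frame(
    time = seq_len(n_hills) / 1000,  # 1 ps per hill, stored in ns
    cv1 = rec[, 1], cv2 = rec[, 2],
    sigma1 = sigma, sigma2 = sigma,
    height = rec[, 3], biasf = gamma
  )
  class(hills) <- c("hills_log", "data.frame")
  list(
    hills = hills,
    fes_true = list(cv1 = grid, cv2 = grid, F = Ftrue - min(Ftrue)),
    spec = spec
  )
}

#' Generate a Hill-curve dose-response table with known IC50
#'
#' Exact Hill inhibition curve plus Gaussian noise, truncated to [0, 100] %.
#' The default IC50 of 7 uM mirrors the apparent norfluoxetine affinity of a
#' wild-type TREK-1 channel.
#'
#' @param ic50 half-maximal concentration in uM.
#' @param hill_coefficient Hill slope.
#' @param concentrations dose vector in uM (all > 0).
#' @param noise_sd Gaussian noise in percentage points.
#' @param seed RNG seed.
#' @return data.frame with columns `dose_uM` and `pct_inhibition`.
#' @export
gen_dose_response <- function(ic50 = 7, hill_coefficient = 1,
                              concentrations = 10^seq(-1, 3, length.out = 9),
                              noise_sd = 0, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (ic50 <= 0) stop("ic50 must be positive")
  set.seed(seed)
  y <- 100 / (1 + (ic50 / concentrations)^hill_coefficient)
  y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(dose_uM = concentrations,
             pct_inhibition = pmin(100, pmax(0, y)))
}
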