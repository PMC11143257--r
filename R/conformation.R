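# Backbone psi dihedral series, carbonyl flip classification, circular
# densities, and the M4 helix orientation angle against a reference.

#' Backbone psi dihedral time series for one residue
#'
#' psi is the signed dihedral of N-CA-C-N(next) in degrees, wrapped to
#' (-180, 180].
#'
#' @param traj a [trajectory()].
#' @param chain chain identifier.
#' @param resid residue number; the following residue of the same chain must
#'   exist (chain-terminal residues have no psi).
#' @return data.frame of class `dihedral_series` with columns `time`, `psi`;
#'   the residue identity travels as attributes.
#' @export
psi_series <- function(traj, chain, resid) {
  sys <- traj$system
  pick <- function(ch, rs, nm) {
    i <- which(sys$chain_id == ch & sys$residue_id == rs &
                 toupper(sys$atom_name) == nm)
    if (length(i) != 1) {
      stop("psi undefined: need exactly one ", nm, " atom in chain ", ch,
           " residue ", rs, " (found ", length(i), ")")
    }
    i
  }
  iN <- pick(chain, resid, "N")
  iCA <- pick(chain, resid, "CA")
  iC <- pick(chain, resid, "C")
  iN2 <- tryCatch(pick(chain, resid + 1L, "N"),
                  error = function(e) stop("psi undefined for chain-terminal ",
                                           "residue ", resid, " of chain ",
                                           chain))
  psi <- vapply(seq_len(n_frames(traj)), function(f) {
    dihedral_angle(traj$coords[iN, , f], traj$coords[iCA, , f],
                   traj$coords[iC, , f], traj$coords[iN2, , f])
  }, numeric(1))
  out <- data.frame(time = traj$times, psi = psi)
  attr(out, "residue") <- list(chain = chain, resid = resid,
                               name = sys$residue_name[iCA])
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' Classify carbonyl flip states from a psi series
#'
#' A frame is "crystallographic" when psi lies within the circular band
#' around `band_center` (half-width `band_halfwidth`). A Schmitt-trigger
#' hysteresis suppresses chatter at the band edge: leaving the
#' crystallographic state requires the circular distance from the band centre
#' to exceed `band_halfwidth + hysteresis`, while returning requires it to
#' drop below `band_halfwidth`. With zero hysteresis this reduces exactly to
#' plain band membership.
#'
#' @param series a [psi_series()] result (or any data.frame with `time`,
#'   `psi`).
#' @param band_center crystallographic psi in degrees (e.g. the reference
#'   structure's value).
#' @param band_halfwidth band half-width in degrees (< 90).
#' @param hysteresis hysteresis margin in degrees.
#' @return list of class `flip_summary`: `state` (factor per frame),
#'   `flip_fraction`, `first_flip_time` (NA when never flipped), `dwell`
#'   (data.frame of state dwell segments).
#' @export
classify_flips <- function(series, band_center, band_halfwidth = 40,
                           hysteresis = 10) {
  if (2 * band_halfwidth >= 180) stop("band width must be below 180 degrees")
  d <- circ_dist(series$psi, band_center)
  n <- length(d)
  state <- logical(n)  # TRUE = flipped
  state[1] <- d[1] > band_halfwidth
  for (f in seq_len(n)[-1]) {
    state[f] <- if (state[f - 1]) {
      d[f] >= band_halfwidth            # return only once back inside band
    } else {
      d[f] > band_halfwidth + hysteresis  # leave only past the margin
    }
  }
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  dwell <- data.frame(
    state = ifelse(runs$values, "flipped", "crystallographic"),
    t_start = series$time[starts], t_end = series$time[ends],
    frames = runs$lengths
  )
  first_flip <- if (any(state)) series$time[which(state)[1]] else NA_real_
  out <- list(
    state = factor(ifelse(state, "flipped", "crystallographic"),
                   levels = c("crystallographic", "flipped")),
    flip_fraction = mean(state),
    first_flip_time = first_flip,
    dwell = dwell
  )
  class(out) <- "flip_summary"
  out
}

#' @export
print.flip_summary <- function(x, ...) {
  cat(sprintf("flip_summary: flipped %.1f%% of frames; first flip at %s ns\n",
              100 * x$flip_fraction,
              ifelse(is.na(x$first_flip_time), "never",
                     format(x$first_flip_time))))
  invisible(x)
}

#' Circular (wrapped) kernel density of an angle sample
#'
#' Wrapped-Gaussian kernel density on (-180, 180], normalized so the density
#' integrates to 1 over the circle.
#'
#' @param angles sample of angles in degrees (>= 2 values).
#' @param bandwidth kernel standard deviation in degrees.
#' @param n number of evaluation points.
#' @return data.frame with columns `angle` and `density` (per degree).
#' @export
angle_distribution <- function(angles, bandwidth = 10, n = 361) {
  if (length(angles) < 2) stop("need at least 2 samples")
  grid <- seq(-180, 180, length.out = n)
  dens <- numeric(n)
  for (k in -2:2) {
    for (g in seq_len(n)) {
      dens[g] <- dens[g] +
        sum(stats::dnorm(grid[g] - angles + 360 * k, sd = bandwidth))
    }
  }
  dens <- dens / length(angles)
  data.frame(angle = grid, density = dens)
}

#' M4 helix orientation angle against a reference structure
#'
#' The helix vector runs from the CA atom of the first residue of the range
#' to the geometric centre of the CA atoms of the whole (inclusive) range.
#' theta is the angle in degrees between the per-frame vector and the same
#' vector in the reference coordinates; it is unsigned, in [0, 180].
#'
#' @param traj a [trajectory()].
#' @param chain chain identifier.
#' @param ref_system reference [particle_system()].
#' @param ref_coords reference coordinate matrix (angstrom).
#' @param resid_start,resid_end residue range (defaults: Y315-K333 of
#'   TREK-2 numbering).
#' @return data.frame of class `helix_orientation` with columns `time`,
#'   `theta`; the reference vector travels as an attribute.
#' @export
m4_theta <- function(traj, chain, ref_system, ref_coords,
                     resid_start = 315, resid_end = 333) {
  sel_expr <- sprintf("chain %s and resid %d-%d and name CA",
                      chain, resid_start, resid_end)
  idx_frame <- select_atoms(traj$system, sel_expr)
  idx_ref <- select_atoms(ref_system, sel_expr)
  if (!length(idx_frame) || !length(idx_ref)) {
    stop("helix residue range missing in frame or reference")
  }
  if (length(idx_frame) != length(idx_ref)) {
    stop("selection mismatch: ", length(idx_frame), " CA atoms in frame vs ",
         length(idx_ref), " in reference")
  }
  anchor_expr <- sprintf("chain %s and resid %d and name CA", chain,
                         resid_start)
  a_frame <- select_atoms(traj$system, anchor_expr)
  a_ref <- select_atoms(ref_system, anchor_expr)
  v_ref <- colMeans(ref_coords[idx_ref + 1L, , drop = FALSE]) -
    ref_coords[a_ref + 1L, ]
  v_ref <- v_ref / sqrt(sum(v_ref^2))
  theta <- vapply(seq_len(n_frames(traj)), function(f) {
    v <- colMeans(traj$coords[idx_frame + 1L, , f, drop = FALSE]) -
      traj$coords[a_frame + 1L, , f]
    v <- v / sqrt(sum(v^2))
    acos(max(-1, min(1, sum(v * v_ref)))) * 180 / pi
  }, numeric(1))
  out <- data.frame(time = traj$times, theta = theta)
  attr(out, "reference_vector") <- v_ref
  class(out) <- c("helix_orientation", "data.frame")
  out
}
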