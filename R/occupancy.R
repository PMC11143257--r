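# Axial and radial-axial ion occupancy with the per-0.001-A^3-per-1-us
# normalization, and binding-site assignment.

#' Ion occupancy profile along (and around) the pore axis
#'
#' Tallies ion-frames into z bins (1D) or (z, r) annular bins (2D) inside the
#' pore cylinder and normalizes the counts per 0.001 cubic angstrom of bin
#' volume per 1 us of summed trajectory time, so densities are comparable
#' across bin sizes and run lengths. 1D bin volume is `pi r_max^2 dz`; 2D
#' annular volume is `pi (r_out^2 - r_in^2) dz`.
#'
#' @param traj a [trajectory()].
#' @param ions 0-based ion atom indices.
#' @param axis a [compute_pore_axis()] result.
#' @param z_edges bin edges along the reported axis (angstrom).
#' @param r_edges optional radial bin edges; when supplied the result is 2D.
#' @param radius cylinder radius bounding the tally (angstrom); defaults to
#'   `max(r_edges)` in 2D mode.
#' @param total_time_ns total simulated time; defaults to frame spacing times
#'   frame count (use the summed time when pooling replicates).
#' @return data.frame of class `occupancy_grid` with columns `z_lo`, `z_hi`
#'   (and `r_lo`, `r_hi` in 2D), `counts`, `volume` (A^3) and `density`.
#' @export
occupancy_profile <- function(traj, ions, axis, z_edges, r_edges = NULL,
                              radius = 8, total_time_ns = NULL) {
  nf <- n_frames(traj)
  if (is.null(total_time_ns)) {
    dt <- if (nf > 1) stats::median(diff(traj$times)) else 1
    total_time_ns <- nf * dt
  }
  if (total_time_ns <= 0) stop("total time must be positive")
  if (!is.null(r_edges)) radius <- max(r_edges)
  ax <- axial_coordinates(traj, ions, axis)
  in_cyl <- ax$radial <= radius & ax$dz >= min(z_edges) & ax$dz <= max(z_edges)
  z_vals <- ax$dz[in_cyl]
  r_vals <- ax$radial[in_cyl]
  t_us <- total_time_ns / 1000
  nz <- length(z_edges) - 1L
  dz_w <- diff(z_edges)
  if (is.null(r_edges)) {
    zi <- findInterval(z_vals, z_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    counts <- tabulate(zi, nbins = nz)
    volume <- pi * radius^2 * dz_w
    out <- data.frame(z_lo = z_edges[-(nz + 1)], z_hi = z_edges[-1],
                      counts = counts, volume = volume,
                      density = counts / (volume / 0.001) / t_us)
  } else {
    nr <- length(r_edges) - 1L
    zi <- findInterval(z_vals, z_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ri <- findInterval(r_vals, r_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    keep <- r_vals >= min(r_edges)
    counts <- matrix(0, nz, nr)
    tab <- table(factor(zi[keep], levels = seq_len(nz)),
                 factor(ri[keep], levels = seq_len(nr)))
    counts[] <- as.numeric(tab)
    grid <- expand.grid(iz = seq_len(nz), ir = seq_len(nr))
    vol <- pi * (r_edges[grid$ir + 1]^2 - r_edges[grid$ir]^2) * dz_w[grid$iz]
    out <- data.frame(
      z_lo = z_edges[grid$iz], z_hi = z_edges[grid$iz + 1],
      r_lo = r_edges[grid$ir], r_hi = r_edges[grid$ir + 1],
      counts = counts[cbind(grid$iz, grid$ir)], volume = vol,
      density = counts[cbind(grid$iz, grid$ir)] / (vol / 0.001) / t_us
    )
  }
  attr(out, "total_time_ns") <- total_time_ns
  attr(out, "n_frames") <- nf
  attr(out, "radius") <- radius
  class(out) <- c("occupancy_grid", "data.frame")
  out
}

#' Default K+ binding-site intervals along the reported pore axis
#'
#' Contiguous 3.4 angstrom intervals descending from S0 at the filter top,
#' anchored so the SF backbone centre (+7 on the reported axis) sits at the
#' S2/S3 boundary. Half-open `[low, high)`; fully overridable.
#'
#' @param sf_center reported axial position of the SF centre.
#' @param site_height interval height in angstrom.
#' @return data.frame with columns `site`, `z_lo`, `z_hi` (S0 first).
#' @export
default_sites <- function(sf_center = 7, site_height = 3.4) {
  hi <- sf_center + (3:-3) * site_height
  data.frame(site = paste0("S", 0:5),
             z_lo = hi[2:7], z_hi = hi[1:6])
}

#' Per-site occupancy from a 1D occupancy grid
#'
#' Integrates density and averages ion counts over each site interval.
#'
#' @param grid 1D [occupancy_profile()] result.
#' @param sites data.frame with `site`, `z_lo`, `z_hi` (see
#'   [default_sites()]).
#' @return data.frame with `site`, `counts`, `fraction` (mean simultaneous
#'   ions in the interval per frame) and `density_integral`.
#' @export
assign_sites <- function(grid, sites) {
  if (!is.null(grid$r_lo)) stop("assign_sites expects a 1D occupancy grid")
  nfr <- attr(grid, "n_frames")
  mid <- (grid$z_lo + grid$z_hi) / 2
  out <- lapply(seq_len(nrow(sites)), function(i) {
    sel <- mid >= sites$z_lo[i] & mid < sites$z_hi[i]
    data.frame(site = sites$site[i],
               counts = sum(grid$counts[sel]),
               fraction = sum(grid$counts[sel]) / nfr,
               density_integral = sum(grid$density[sel] *
                                        (grid$z_hi[sel] - grid$z_lo[sel])))
  })
  do.call(rbind, out)
}
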