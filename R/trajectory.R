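#' Trajectory container
#'
#' In-memory trajectory: a [particle_system()] plus an `n_atoms x 3 x n_frames`
#' coordinate array (angstrom), per-frame times (ns) and per-frame box vectors
#' (angstrom). Times must be strictly increasing.
#'
#' @param system a [particle_system()].
#' @param coords numeric array `n_atoms x 3 x n_frames` (angstrom).
#' @param times numeric vector of frame times in ns.
#' @param box length-3 vector or `3 x n_frames` matrix of box lengths (angstrom).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(system, coords, times, box) {
  stopifnot(inherits(system, "particle_system"))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(system)) {
    stop("coordinate array has ", dim(coords)[1], " atoms but system has ",
         nrow(system))
  }
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = 3, ncol = n_frames)
  structure(list(system = system, coords = coords,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, %.3f-%.3f ns\n",
              dim(x$coords)[1], n_frames(x),
              x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Subset a trajectory to every stride-th frame
#' @param traj a [trajectory()].
#' @param stride positive integer.
#' @export
stride_frames <- function(traj, stride) {
  stopifnot(stride >= 1)
  idx <- seq(1, n_frames(traj), by = stride)
  trajectory(traj$system, traj$coords[, , idx, drop = FALSE],
             traj$times[idx], traj$box[, idx, drop = FALSE])
}

#' Read a coordinate trajectory
#'
#' Supports multi-frame GRO (text; frame times parsed from `t=` title stamps,
#' ps converted to ns), multi-model PDB (times from `frame_dt_ns`), and DCD
#' (binary, via bio3d; times from `frame_dt_ns`). The atom count of every
#' frame must match `system` when one is supplied.
#'
#' @param path trajectory file.
#' @param system optional [particle_system()] to validate against (required
#'   for DCD, which carries no topology).
#' @param stride keep every stride-th frame.
#' @param frame_dt_ns frame spacing in ns for formats without time stamps.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, system = NULL, stride = 1, frame_dt_ns = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    gro = read_trajectory_gro(path, system),
    pdb = read_trajectory_pdb(path, system, frame_dt_ns),
    dcd = read_trajectory_dcd(path, system, frame_dt_ns),
    stop("unsupported trajectory format '.", ext, "'")
  )
  if (stride > 1) traj <- stride_frames(traj, stride) else traj
}

read_trajectory_gro <- function(path, system) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  times <- numeric()
  boxes <- list()
  frame_i <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    frame_i <- frame_i + 1L
    title <- lines[pos]
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n)) {
      stop("GRO trajectory ", path, ": corrupt frame ", frame_i,
           " at line ", pos + 1L)
    }
    if (pos + 1L + n + 1L > length(lines)) {
      stop("GRO trajectory ", path, ": truncated frame ", frame_i)
    }
    parsed <- parse_gro_atoms(lines[(pos + 2L):(pos + 1L + n)], path,
                              offset = pos + 1L)
    box <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[pos + 2L + n]), "\\s+")[[1]])
    )
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    t_ns <- if (length(tm)) {
      as.numeric(sub("t=\\s*", "", tm)) / 1000
    } else {
      frame_i - 1
    }
    frames[[frame_i]] <- parsed$coords
    times[frame_i] <- t_ns
    boxes[[frame_i]] <- box[1:3] * 10
    pos <- pos + n + 3L
  }
  if (frame_i == 0L) stop("no frames found in ", path)
  first_parsed <- NULL
  if (is.null(system)) {
    first_parsed <- parse_gro_atoms(lines[3:(2 + nrow(frames[[1]]))], path, 2L)
    system <- particle_system(first_parsed$atom_name, first_parsed$residue_name,
                              first_parsed$residue_id, first_parsed$chain_id)
  }
  check_atom_count(nrow(frames[[1]]), system, path)
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, frame_i))
  trajectory(system, coords, times, do.call(cbind, boxes))
}

read_trajectory_pdb <- function(path, system, frame_dt_ns) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  if (is.null(system)) system <- load_system_pdb(path)$system
  check_atom_count(na, system, path)
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  dt <- if (is.null(frame_dt_ns)) 1 else frame_dt_ns
  trajectory(system, coords, (seq_len(nf) - 1) * dt, rep(9999, 3))
}

read_trajectory_dcd <- function(path, system, frame_dt_ns) {
  if (is.null(system)) stop("reading DCD requires a topology (system = ...)")
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  check_atom_count(na, system, path)
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  dt <- if (is.null(frame_dt_ns)) 1 else frame_dt_ns
  trajectory(system, coords, (seq_len(nf) - 1) * dt, rep(9999, 3))
}

check_atom_count <- function(n_found, system, path) {
  if (n_found != nrow(system)) {
    stop("atom count mismatch: trajectory ", path, " has ", n_found,
         " atoms, system has ", nrow(system))
  }
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Each frame carries its time (ns converted to ps) in the `t=` title stamp,
#' so a round trip through [read_trajectory()] preserves times.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    write_gro_frame(con, traj$system, traj$coords[, , f], traj$box[, f],
                    "poreflux frame", time_ps = traj$times[f] * 1000)
  }
  invisible(path)
}
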