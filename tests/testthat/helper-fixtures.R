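# Fixtures are built in code at test time; nothing binary ships with the
# package.

# One fixed-column PDB ATOM line.
pdb_line <- function(serial, name, resn, chain, resid, xyz) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, nm, resn, chain, resid, xyz[1], xyz[2], xyz[3])
}

# Dimer fixture: chains A and B, CA-only residues 315..333 (19 each) on a
# straight line, plus one N atom per residue so `backbone` has variety.
write_dimer_pdb <- function(path, resid_range = 315:333) {
  lines <- character(0)
  serial <- 0
  for (chain in c("A", "B")) {
    for (r in resid_range) {
      off <- if (chain == "A") 0 else 50
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "N", "ALA", chain, r,
                                 c(r - 315, off, 0)))
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "CA", "ALA", chain, r,
                                 c(r - 315, off, 1.5)))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}

# A minimal trajectory: one heavy "SF" marker atom fixed at `origin` plus one
# ion whose raw z follows `ion_z` (x, y follow ion_xy). Used to drive the
# permeation state machine by hand.
make_ion_traj <- function(ion_z, origin = c(20, 20, 40), ion_xy = NULL,
                          box = c(40, 40, 80), dt = 1) {
  nf <- length(ion_z)
  if (is.null(ion_xy)) ion_xy <- matrix(origin[1:2], nf, 2, byrow = TRUE)
  sys <- particle_system(c("CA", "K"), c("GLY", "K"), c(1L, 2L), c("A", "I"))
  coords <- array(0, c(2, 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- origin
    coords[2, , f] <- c(ion_xy[f, 1], ion_xy[f, 2], ion_z[f])
  }
  trajectory(sys, coords, (seq_len(nf) - 1) * dt, box)
}

# Backbone fragment giving an exact psi: N-CA-C of residue 1 plus N of
# residue 2 placed so the signed dihedral equals `psi_deg` analytically.
make_psi_traj <- function(psi_deg, n_frames = 1) {
  sys <- particle_system(c("N", "CA", "C", "N"), rep("ALA", 4),
                         c(1L, 1L, 1L, 2L), rep("A", 4))
  base <- rbind(
    c(1, 0, 0),
    c(0, 0, 0),
    c(0, 0, 1.5),
    c(cos(psi_deg * pi / 180), sin(psi_deg * pi / 180), 1.5)
  )
  coords <- array(rep(base, n_frames), c(4, 3, n_frames))
  trajectory(sys, coords, seq_len(n_frames) - 1, c(999, 999, 999))
}

# Straight CA helix along +x for the theta-angle tests.
make_helix_system <- function(resids = 315:333, chain = "A") {
  n <- length(resids)
  sys <- particle_system(rep("CA", n), rep("ALA", n), resids, rep(chain, n))
  coords <- cbind(1.5 * (seq_len(n) - 1), rep(0, n), rep(0, n))
  colnames(coords) <- c("x", "y", "z")
  list(system = sys, coords = coords)
}

traj_from_coords <- function(system, coords_list, dt = 1, box = c(999, 999, 999)) {
  nf <- length(coords_list)
  arr <- array(unlist(coords_list), c(nrow(system), 3, nf))
  trajectory(system, arr, (seq_len(nf) - 1) * dt, box)
}

# Exhaustive simple-path enumeration: the independent shortest-path oracle.
brute_force_shortest <- function(edges, from, to) {
  # edges: data.frame(from, to, weight); undirected
  nodes <- unique(c(edges$from, edges$to))
  best <- list(cost = Inf, path = NULL)
  recurse <- function(path, cost) {
    cur <- path[length(path)]
    if (cur == to) {
      if (cost < best$cost) best <<- list(cost = cost, path = path)
      return(invisible())
    }
    hit <- which((edges$from == cur & !(edges$to %in% path)) |
                   (edges$to == cur & !(edges$from %in% path)))
    for (e in hit) {
      nxt <- if (edges$from[e] == cur) edges$to[e] else edges$from[e]
      recurse(c(path, nxt), cost + edges$weight[e])
    }
  }
  recurse(from, 0)
  best
}

# Random connected toy graph with positive weights.
random_toy_graph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- as.character(seq_len(n_nodes))
  # spanning chain guarantees connectivity, plus random extras
  edges <- data.frame(from = nodes[-n_nodes], to = nodes[-1],
                      weight = runif(n_nodes - 1, 0.1, 2))
  n_extra <- sample(1:4, 1)
  for (k in seq_len(n_extra)) {
    pair <- sample(nodes, 2)
    edges <- rbind(edges, data.frame(from = pair[1], to = pair[2],
                                     weight = runif(1, 0.1, 2)))
  }
  edges[!duplicated(t(apply(edges[, 1:2], 1, sort))), ]
}
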