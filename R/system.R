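#' Particle system container
#'
#' A `particle_system` is a data.frame with one row per atom and the columns
#' `atom_index` (0-based, dense), `atom_name`, `residue_name`, `residue_id`
#' (1-based as in the source file), `chain_id`, `element` and `mass` (amu).
#'
#' @param atom_name,residue_name,chain_id character vectors, one entry per atom.
#' @param residue_id integer vector of residue numbers.
#' @param element optional character vector of element symbols; guessed from
#'   atom/residue names when `NULL`.
#' @param mass optional numeric vector of atomic masses (amu); looked up from
#'   `element` when `NULL`.
#' @return object of class `particle_system`.
#' @export
particle_system <- function(atom_name, residue_name, residue_id, chain_id,
                            element = NULL, mass = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_id) == n,
            length(chain_id) == n)
  if (is.null(element)) element <- guess_element(atom_name, residue_name)
  if (is.null(mass)) mass <- mass_from_element(element)
  sys <- data.frame(
    atom_index = seq_len(n) - 1L,
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    chain_id = as.character(chain_id),
    element = display_element(element),
    mass = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  class(sys) <- c("particle_system", "data.frame")
  sys
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d atoms, %d residues, chains: %s\n",
              nrow(x),
              length(unique(paste(x$chain_id, x$residue_id))),
              paste(unique(x$chain_id), collapse = " ")))
  invisible(x)
}

#' Load a molecular structure file
#'
#' Reads a PDB or GRO file into a [particle_system()] plus first-frame
#' coordinates. Coordinates are always returned in angstrom (GRO nm values are
#' multiplied by 10). Residue numbering is taken verbatim from the file.
#' PDB atoms without chain identifiers are split into chains at TER records
#' when present, otherwise assigned chain "A", with a warning either way.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @return list with elements `system` ([particle_system()]) and `coords`
#'   (n x 3 matrix, angstrom), plus `box` (length-3, angstrom) for GRO input.
#' @export
load_system <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = load_system_pdb(path),
    gro = load_system_gro(path),
    stop("unsupported structure format '.", ext, "' (expected .pdb or .gro)")
  )
}

load_system_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  chain <- at$chain
  if (anyNA(chain) || any(!nzchar(chain))) {
    chain <- assign_chains_by_ter(path, nrow(at), chain)
  }
  sys <- particle_system(
    atom_name = at$elety,
    residue_name = at$resid,
    residue_id = at$resno,
    chain_id = chain
  )
  coords <- cbind(at$x, at$y, at$z)
  colnames(coords) <- c("x", "y", "z")
  list(system = sys, coords = coords)
}

# Fallback chain assignment for PDB files lacking chain IDs: advance a letter
# at every TER record; single chain "A" when no TER is present.
assign_chains_by_ter <- function(path, n_atoms, chain) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_ter <- startsWith(rec, "TER")
  if (!any(is_ter)) {
    warning("PDB file has atoms without chain IDs and no TER records; ",
            "assigning all to chain A")
    chain[is.na(chain) | !nzchar(chain)] <- "A"
    return(chain)
  }
  warning("PDB file has atoms without chain IDs; assigning chains by TER records")
  grp <- cumsum(is_ter)[is_atom] + 1L
  grp <- grp[seq_len(n_atoms)]
  filled <- LETTERS[pmin(grp, 26L)]
  missing <- is.na(chain) | !nzchar(chain)
  chain[missing] <- filled[missing]
  chain
}

# GRO fixed-column format; coordinates in nm, converted to angstrom here.
load_system_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO format error in ", path, " line 2: expected atom count")
  if (length(lines) < 2 + n + 1) stop("GRO file truncated: ", path)
  atom_lines <- lines[3:(2 + n)]
  parsed <- parse_gro_atoms(atom_lines, path, offset = 2L)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3])) {
    stop("GRO format error in ", path, ": unreadable box line")
  }
  sys <- particle_system(
    atom_name = parsed$atom_name,
    residue_name = parsed$residue_name,
    residue_id = parsed$residue_id,
    chain_id = parsed$chain_id
  )
  list(system = sys, coords = parsed$coords, box = box[1:3] * 10)
}

parse_gro_atoms <- function(atom_lines, path, offset) {
  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  aname <- trimws(substr(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("GRO format error in ", path, " line ", bad[1] + offset,
         ": unparsable atom record")
  }
  # GRO carries no chain column; chains delimited by residue-number decreases.
  chain_breaks <- c(FALSE, diff(resid) < 0)
  chain <- LETTERS[pmin(cumsum(chain_breaks) + 1L, 26L)]
  coords <- cbind(x, y, z) * 10
  colnames(coords) <- c("x", "y", "z")
  list(atom_name = aname, residue_name = resname, residue_id = resid,
       chain_id = chain, coords = coords)
}

#' Write a structure as a GRO file
#'
#' @param system a [particle_system()].
#' @param coords n x 3 coordinate matrix in angstrom.
#' @param path output path.
#' @param box length-3 box vector in angstrom.
#' @param title title line content.
#' @param time_ps optional time stamp embedded as `t= <ps>` in the title.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, coords, path, box = c(100, 100, 100),
                      title = "poreflux", time_ps = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_gro_frame(con, system, coords, box, title, time_ps)
  invisible(path)
}

write_gro_frame <- function(con, system, coords, box, title, time_ps) {
  if (!is.null(time_ps)) title <- sprintf("%s t= %.5f", title, time_ps)
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(system)), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   system$residue_id %% 100000L,
                   substr(system$residue_name, 1, 5),
                   substr(system$atom_name, 1, 5),
                   (system$atom_index + 1L) %% 100000L,
                   coords[, 1] / 10, coords[, 2] / 10, coords[, 3] / 10)
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10),
             con)
}
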