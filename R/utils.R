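# Internal geometry and unit helpers shared across modules.

# Boltzmann constant times 300 K in kJ/mol; matches the simulation temperature.
KBT_300K <- 2.494

# Elementary charge in coulomb.
ELEMENTARY_CHARGE <- 1.602176634e-19

#' Wrap angles into (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles; -180 maps to +180 so the interval is half-open.
#' @keywords internal
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Circular distance |a - b| on the 360-degree circle.
circ_dist <- function(a, b) abs(wrap_angle(a - b))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking down the p2-p3 bond, the angle is positive for a
#' clockwise rotation of the far bond relative to the near one.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

# Minimum-image convention for displacement components under an orthorhombic box.
min_image <- function(dx, box) {
  dx - box * round(dx / box)
}

#' Optimal rotation (Kabsch) superposing moving onto fixed
#'
#' Both coordinate sets are centered; the returned function maps arbitrary
#' coordinates with the fitted rigid-body transform.
#'
#' @param moving,fixed n x 3 matrices of paired coordinates.
#' @return list(R = 3x3 rotation, transform = function(coords)).
#' @keywords internal
kabsch_fit <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(
    R = R,
    transform = function(coords) {
      sweep(sweep(coords, 2, cm) %*% t(R), 2, cf, "+")
    }
  )
}

# Rotation matrix about a (unit) axis by angle degrees (Rodrigues).
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Atomic masses (amu) by element symbol; covers protein heavy atoms plus the
# ions and lipid atoms encountered in channel systems.
ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  K = 39.0983, NA_ = 22.98977, CL = 35.45, MG = 24.305, CA_ION = 40.078,
  F = 18.998, ZN = 65.38
)

ION_RESNAMES <- c(
  K = "K", POT = "K", "K+" = "K",
  "NA" = "NA_", SOD = "NA_", "NA+" = "NA_",
  CL = "CL", CLA = "CL", "CL-" = "CL",
  MG = "MG", CAL = "CA_ION", ZN = "ZN"
)

#' Guess element symbol from atom and residue names
#' @keywords internal
guess_element <- function(atom_name, residue_name) {
  res <- toupper(trimws(residue_name))
  out <- character(length(atom_name))
  is_ion <- res %in% names(ION_RESNAMES)
  out[is_ion] <- ION_RESNAMES[res[is_ion]]
  stripped <- gsub("[0-9'\"]", "", toupper(trimws(atom_name[!is_ion])))
  first2 <- substr(stripped, 1, 2)
  first1 <- substr(stripped, 1, 1)
  guess <- ifelse(first2 %in% c("CL", "MG", "ZN"), first2, first1)
  out[!is_ion] <- guess
  out
}

mass_from_element <- function(element) {
  m <- ELEMENT_MASS[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; assigning carbon mass")
    m[is.na(m)] <- ELEMENT_MASS[["C"]]
  }
  unname(m)
}

# Pretty element for output: internal codes back to plain symbols.
display_element <- function(element) {
  sub("_ION$", "", sub("_$", "", element))
}
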