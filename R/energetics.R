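# Well-tempered metadynamics FES reconstruction, basin detection by
# persistence flooding, and adiabatic-bias force bookkeeping.

#' Reconstruct a well-tempered free-energy surface from a hills log
#'
#' Sums the deposited Gaussians over a periodic grid of the two (angular)
#' collective variables, `V(s) = sum_i h_i exp(-sum_d wrap(s_d - s_id)^2 /
#' (2 sigma_d^2))`, and converts the accumulated bias to free energy with
#' the well-tempered factor, `F(s) = -(gamma / (gamma - 1)) V(s)`, shifted so
#' `min F = 0`. Hill heights are taken as already well-tempered-scaled (the
#' PLUMED convention). The reconstruction is exactly linear in hill heights.
#'
#' @param hills a `hills_log` data.frame ([read_hills()] / [gen_hills()]);
#'   the bias factor must be constant and > 1 across records.
#' @param cv1_grid,cv2_grid evaluation grids in degrees.
#' @param contour_step,contour_cap plotting conventions carried as metadata
#'   (kJ/mol).
#' @return list of class `free_energy_surface`: `cv1`, `cv2`, `F` (matrix,
#'   kJ/mol, min 0), `bias_factor`, `contour_step`, `contour_cap`.
#' @export
reconstruct_fes <- function(hills, cv1_grid = seq(-180, 175, by = 5),
                            cv2_grid = seq(-180, 175, by = 5),
                            contour_step = 4, contour_cap = 80) {
  V <- matrix(0, length(cv1_grid), length(cv2_grid))
  gamma <- NA_real_
  if (nrow(hills)) {
    gamma <- hills$biasf[1]
    if (any(hills$biasf != gamma)) {
      stop("mixed bias factors in hills log; cannot reconstruct")
    }
    if (gamma <= 1) stop("bias factor must exceed 1")
    for (i in seq_len(nrow(hills))) {
      gx <- exp(-wrap_angle(cv1_grid - hills$cv1[i])^2 /
                  (2 * hills$sigma1[i]^2))
      gy <- exp(-wrap_angle(cv2_grid - hills$cv2[i])^2 /
                  (2 * hills$sigma2[i]^2))
      V <- V + hills$height[i] * outer(gx, gy)
    }
  }
  F <- if (nrow(hills)) -(gamma / (gamma - 1)) * V else V
  F <- F - min(F)
  structure(list(cv1 = cv1_grid, cv2 = cv2_grid, F = F,
                 bias_factor = gamma, contour_step = contour_step,
                 contour_cap = contour_cap),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %d x %d grid, range 0-%.1f kJ/mol\n",
              length(x$cv1), length(x$cv2), max(x$F)))
  invisible(x)
}

#' Detect basins on a periodic free-energy surface
#'
#' Flood-fill in order of increasing free energy on the periodic grid
#' (4-neighbourhood). When two catchments meet at a saddle, the shallower one
#' survives as a distinct basin only if its depth below the saddle is at
#' least `min_depth` (persistence criterion); otherwise it merges. The global
#' minimum is always a basin.
#'
#' @param fes a [reconstruct_fes()] result.
#' @param min_depth minimum basin depth relative to its lowest connecting
#'   saddle, kJ/mol (default 4, one contour step).
#' @return data.frame with columns `cv1`, `cv2` (basin minimum location),
#'   `F_min` and `persistence` (Inf for the global minimum), ordered by
#'   `F_min`.
#' @export
find_basins <- function(fes, min_depth = 4) {
  F <- fes$F
  n1 <- nrow(F)
  n2 <- ncol(F)
  ncell <- n1 * n2
  ord <- order(F)
  parent <- seq_len(ncell)
  storage.mode(parent) <- "integer"
  comp_min <- rep(Inf, ncell)   # minimum F of each component root
  comp_cell <- integer(ncell)   # cell index of that minimum
  is_basin <- logical(ncell)    # roots confirmed as basins
  persistence <- rep(NA_real_, ncell)
  assigned <- logical(ncell)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  neighbors <- function(cell) {
    i <- ((cell - 1L) %% n1) + 1L
    j <- ((cell - 1L) %/% n1) + 1L
    ip <- if (i == n1) 1L else i + 1L
    im <- if (i == 1L) n1 else i - 1L
    jp <- if (j == n2) 1L else j + 1L
    jm <- if (j == 1L) n2 else j - 1L
    as.integer(c(im + (j - 1L) * n1, ip + (j - 1L) * n1,
                 i + (jm - 1L) * n1, i + (jp - 1L) * n1))
  }

  for (cell in ord) {
    nb <- neighbors(cell)
    nb <- nb[assigned[nb]]
    assigned[cell] <- TRUE
    if (!length(nb)) {
      comp_min[cell] <- F[cell]
      comp_cell[cell] <- cell
      next
    }
    roots <- unique(vapply(nb, find_root, integer(1)))
    # attach to the deepest neighbouring component
    main <- roots[which.min(comp_min[roots])]
    parent[cell] <- main
    for (r in setdiff(roots, main)) {
      pers <- F[cell] - comp_min[r]
      if (pers >= min_depth) {
        # r survives as a real basin; record once at its lowest saddle
        if (!is_basin[r]) {
          is_basin[r] <- TRUE
          persistence[r] <- pers
        }
      }
      if (!is_basin[r]) {
        parent[r] <- main
        if (comp_min[r] < comp_min[main]) {
          comp_min[main] <- comp_min[r]
          comp_cell[main] <- comp_cell[r]
        }
      } else {
        parent[r] <- main  # catchments join, but basin r stays recorded
      }
    }
  }
  global_root <- find_root(ord[1])
  basins <- which(is_basin)
  cells <- comp_cell[basins]
  pers <- persistence[basins]
  # the global minimum component is always a basin
  if (!(ord[1] %in% cells)) {
    cells <- c(ord[1], cells)
    pers <- c(Inf, pers)
  }
  i <- ((cells - 1) %% n1) + 1
  j <- ((cells - 1) %/% n1) + 1
  out <- data.frame(cv1 = fes$cv1[i], cv2 = fes$cv2[j],
                    F_min = F[cells], persistence = pers)
  out[order(out$F_min), , drop = FALSE]
}

#' Adiabatic-bias force bookkeeping along a collective-variable series
#'
#' The ratchet reference `rho_best(t)` is the running extremum of the CV
#' toward the target; the bias exerts a restoring force only when the CV
#' retreats from `rho_best`, with magnitude `k * |retreat|`. Both total-force
#' readings are reported: the summed magnitude `sum |F|` and the summed
#' square `sum F^2`.
#'
#' @param times time stamps in ns.
#' @param rho CV values (nm).
#' @param k harmonic force constant, kJ/mol/nm^2 (default 5000).
#' @param target CV target value in nm (default 0.5).
#' @param direction `"down"` when the CV approaches the target from above,
#'   `"up"` from below; inferred from the first value when `NULL`.
#' @return list of class `abmd_record`: `times`, `rho`, `rho_best`, `force`
#'   (kJ/mol/nm per frame), `total_force_abs`, `total_force_sq`, `k`,
#'   `target`, `direction`.
#' @export
abmd_force <- function(times, rho, k = 5000, target = 0.5, direction = NULL) {
  stopifnot(length(times) == length(rho), all(is.finite(rho)))
  if (is.null(direction)) {
    direction <- if (rho[1] >= target) "down" else "up"
  }
  direction <- match.arg(direction, c("down", "up"))
  if (direction == "down") {
    rho_best <- cummin(rho)
    retreat <- rho - rho_best
  } else {
    rho_best <- cummax(rho)
    retreat <- rho_best - rho
  }
  force <- k * pmax(0, retreat)
  structure(list(times = times, rho = rho, rho_best = rho_best,
                 force = force,
                 total_force_abs = sum(force),
                 total_force_sq = sum(force^2),
                 k = k, target = target, direction = direction),
            class = "abmd_record")
}

#' @export
print.abmd_record <- function(x, ...) {
  cat(sprintf("abmd_record: %d frames %s toward %.2f nm; sum|F| = %.4g, sum F^2 = %.4g\n",
              length(x$rho), x$direction, x$target,
              x$total_force_abs, x$total_force_sq))
  invisible(x)
}
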