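# Protein structure network: fluctuation correlations, contact-weighted
# graphs, correlation-filtered shortest communication paths and the metapath
# of most frequent edges.

#' Dynamic cross-correlation of atomic fluctuations
#'
#' Frames are first superposed onto the reference (default: the first frame)
#' by a rigid-body fit over the selection; the normalized covariance of the
#' displacement vectors about their time means is then
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`.
#'
#' @param traj a [trajectory()].
#' @param selection 0-based atom indices (typically CA atoms).
#' @param fit superpose frames before computing correlations?
#' @param ref_frame frame used as the superposition reference.
#' @return symmetric correlation matrix with unit diagonal, dimnames
#'   `chain:resid`; zero-variance atoms yield NA rows with a warning.
#' @export
correlation_matrix <- function(traj, selection, fit = TRUE, ref_frame = 1L) {
  rows <- selection + 1L
  nf <- n_frames(traj)
  na <- length(rows)
  X <- array(0, c(na, 3, nf))
  ref <- traj$coords[rows, , ref_frame, drop = TRUE]
  if (na == 1) ref <- matrix(ref, 1, 3)
  for (f in seq_len(nf)) {
    fr <- traj$coords[rows, , f, drop = TRUE]
    if (na == 1) fr <- matrix(fr, 1, 3)
    X[, , f] <- if (fit && na >= 3) kabsch_fit(fr, ref)$transform(fr) else fr
  }
  mu <- apply(X, c(1, 2), mean)
  cov_ij <- matrix(0, na, na)
  for (k in 1:3) {
    D <- X[, k, ] - mu[, k]
    if (is.null(dim(D))) D <- matrix(D, nrow = na)
    cov_ij <- cov_ij + D %*% t(D) / nf
  }
  v <- diag(cov_ij)
  zero <- v <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s) excluded from correlations")
  }
  denom <- sqrt(outer(v, v))
  C <- cov_ij / denom
  C[zero, ] <- NA
  C[, zero] <- NA
  diag(C)[!zero] <- 1
  sys <- traj$system
  labels <- paste0(sys$chain_id[rows], ":", sys$residue_id[rows])
  dimnames(C) <- list(labels, labels)
  C
}

#' Build a protein structure network from contact records
#'
#' Residues become nodes; every pair with contact probability p > 0 gets an
#' undirected edge of weight `-log(p)`, so frequent contacts are short and
#' path cost is additive in contact log-frequency.
#'
#' @param contacts a [contact_probability()] result.
#' @return an igraph graph with vertex names `chain:resid`, edge attributes
#'   `weight` (`-log p`) and `p`.
#' @export
build_graph <- function(contacts) {
  keep <- contacts$p > 0
  edges <- data.frame(
    from = paste0(contacts$chain_a[keep], ":", contacts$resid_a[keep]),
    to = paste0(contacts$chain_b[keep], ":", contacts$resid_b[keep]),
    weight = -log(contacts$p[keep]),
    p = contacts$p[keep]
  )
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Correlation-filtered shortest communication paths and metapath
#'
#' Computes the weighted shortest (Dijkstra) path for every source-target
#' node pair, discards paths whose interior nodes are not fluctuation-
#' correlated with at least one of the two endpoints of interest (absolute
#' correlation >= `correlation_cutoff`), and assembles the metapath from the
#' edges appearing in at least `metapath_frac` of the retained paths.
#'
#' @param graph a [build_graph()] result.
#' @param sources,targets vertex names (`chain:resid`).
#' @param correlations optional correlation matrix from
#'   [correlation_matrix()]; `NULL` disables the filter.
#' @param correlation_cutoff dimensionless cutoff (default 0.8).
#' @param metapath_frac metapath edge-frequency threshold (default 0.2).
#' @return list of class `psn_paths`: `paths` (list of vertex-name vectors),
#'   `costs`, `discarded` (count removed by the filter), `metapath`
#'   (data.frame `from`, `to`, `frequency`). Empty when no path is retained.
#' @export
shortest_paths_psn <- function(graph, sources, targets, correlations = NULL,
                               correlation_cutoff = 0.8, metapath_frac = 0.2) {
  vnames <- igraph::V(graph)$name
  sources <- intersect(sources, vnames)
  targets <- intersect(targets, vnames)
  paths <- list()
  costs <- numeric(0)
  discarded <- 0L
  for (s in sources) {
    res <- igraph::shortest_paths(graph, from = s, to = targets,
                                  weights = igraph::E(graph)$weight,
                                  output = "vpath")
    for (k in seq_along(res$vpath)) {
      vp <- res$vpath[[k]]
      if (length(vp) < 2) next  # unreachable or trivial
      nm <- igraph::as_ids(vp)
      if (!is.null(correlations)) {
        interior <- setdiff(nm, c(nm[1], nm[length(nm)]))
        ok <- all(vapply(interior, function(node) {
          cs <- abs(c(correlations[node, nm[1]],
                      correlations[node, nm[length(nm)]]))
          any(!is.na(cs) & cs >= correlation_cutoff)
        }, logical(1)))
        if (!ok) {
          discarded <- discarded + 1L
          next
        }
      }
      paths[[length(paths) + 1L]] <- nm
      costs <- c(costs, path_cost(graph, nm))
    }
  }
  metapath <- metapath_edges(paths, metapath_frac)
  structure(list(paths = paths, costs = costs, discarded = discarded,
                 metapath = metapath),
            class = "psn_paths")
}

path_cost <- function(graph, vnames) {
  if (length(vnames) < 2) return(0)
  w <- igraph::E(graph)$weight
  sum(vapply(seq_len(length(vnames) - 1), function(i) {
    e <- igraph::get_edge_ids(graph, c(vnames[i], vnames[i + 1]))
    w[e]
  }, numeric(1)))
}

metapath_edges <- function(paths, frac) {
  if (!length(paths)) {
    return(data.frame(from = character(0), to = character(0),
                      frequency = numeric(0)))
  }
  edge_keys <- unlist(lapply(paths, function(p) {
    if (length(p) < 2) return(character(0))
    a <- p[-length(p)]
    b <- p[-1]
    paste(pmin(a, b), pmax(a, b), sep = "->")
  }))
  tab <- table(edge_keys) / length(paths)
  keep <- tab[tab >= frac]
  if (!length(keep)) {
    return(data.frame(from = character(0), to = character(0),
                      frequency = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(names(keep), "->", fixed = TRUE))
  out <- data.frame(from = parts[, 1], to = parts[, 2],
                    frequency = as.numeric(keep))
  out[order(-out$frequency), , drop = FALSE]
}

#' @export
print.psn_paths <- function(x, ...) {
  cat(sprintf("psn_paths: %d retained path(s), %d discarded by filter, %d metapath edge(s)\n",
              length(x$paths), x$discarded, nrow(x$metapath)))
  invisible(x)
}
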