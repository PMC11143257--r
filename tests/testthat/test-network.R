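# Fluctuation correlations, contact-weighted graphs, and correlation-
# filtered shortest paths against a brute-force oracle.

random_walk_traj <- function(n_atoms, n_frames, seed, paired = NULL) {
  set.seed(seed)
  sys <- particle_system(rep("CA", n_atoms), rep("ALA", n_atoms),
                         seq_len(n_atoms), rep("A", n_atoms))
  coords <- array(0, c(n_atoms, 3, n_frames))
  for (i in seq_len(n_atoms)) {
    for (k in 1:3) coords[i, k, ] <- cumsum(rnorm(n_frames, 0, 0.3)) + 10 * i
  }
  if (!is.null(paired)) {
    # atom paired[2] copies (or mirrors) atom paired[1]'s displacements
    base <- coords[paired[1], , ] -
      apply(coords[paired[1], , ], 1, mean)
    coords[paired[2], , ] <- 10 * paired[2] + paired[3] * base
  }
  trajectory(sys, coords, seq_len(n_frames) - 1, c(999, 999, 999))
}

test_that("dynamic cross-correlations hit the analytic anchors", {
  tr <- random_walk_traj(4, 200, seed = 2, paired = c(1, 2, 1))
  C <- correlation_matrix(tr, 0:3, fit = FALSE)
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_equal(C[1, 2], 1, tolerance = 1e-10)   # identical displacements
  tr_anti <- random_walk_traj(4, 200, seed = 3, paired = c(1, 2, -1))
  C2 <- correlation_matrix(tr_anti, 0:3, fit = FALSE)
  expect_equal(C2[1, 2], -1, tolerance = 1e-10) # opposite displacements
  expect_true(isSymmetric(C))

  # zero-variance atoms are excluded with a warning
  tr$coords[3, , ] <- 5
  expect_warning(C3 <- correlation_matrix(tr, 0:3, fit = FALSE),
                 "zero-variance")
  expect_true(all(is.na(C3[3, ])))
})

test_that("correlations agree with the bio3d cross-check", {
  tr <- random_walk_traj(6, 300, seed = 9)
  C1 <- correlation_matrix(tr, 0:5, fit = FALSE)
  xyz <- t(apply(tr$coords, 3, function(m) as.vector(t(m))))
  C2 <- bio3d::dccm.xyz(xyz)
  expect_equal(max(abs(unname(C1) - unname(C2))), 0, tolerance = 1e-10)
})

test_that("graph edges carry -log p weights; p = 0 yields no edge", {
  rec <- data.frame(chain_a = c("A", "A", "A"), resid_a = c(1, 1, 2),
                    chain_b = c("A", "A", "A"), resid_b = c(2, 3, 3),
                    p = c(1, 0.5, 0), n_frames = 10)
  g <- build_graph(rec)
  expect_equal(igraph::ecount(g), 2)  # p = 0 dropped
  w <- igraph::E(g)$weight
  expect_equal(sort(w), sort(c(0, -log(0.5))))
})

test_that("two cheap hops beat one expensive edge", {
  rec <- data.frame(chain_a = "A", resid_a = c(1, 2, 1),
                    chain_b = "A", resid_b = c(2, 3, 3),
                    p = exp(-c(1, 1, 3)), n_frames = 10)
  g <- build_graph(rec)
  res <- shortest_paths_psn(g, "A:1", "A:3")
  expect_equal(res$paths[[1]], c("A:1", "A:2", "A:3"))
  expect_equal(res$costs[1], 2)
})

test_that("Dijkstra equals brute-force enumeration on toy graphs", {
  for (seed in 1:6) {
    n <- sample(4:10, 1)
    edges <- random_toy_graph(n, seed = 100 + seed)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    nodes <- igraph::V(g)$name
    for (pair in list(c(nodes[1], nodes[n]), sample(nodes, 2))) {
      oracle <- brute_force_shortest(edges, pair[1], pair[2])
      got <- igraph::distances(g, pair[1], pair[2],
                               weights = igraph::E(g)$weight)[1, 1]
      expect_equal(got, oracle$cost, tolerance = 1e-12)
      sp <- shortest_paths_psn(g, pair[1], pair[2])
      expect_equal(sp$costs[1], oracle$cost, tolerance = 1e-12)
    }
  }
})

test_that("the correlation filter discards uncorrelated paths entirely", {
  rec <- data.frame(chain_a = "A", resid_a = c(1, 2), chain_b = "A",
                    resid_b = c(2, 3), p = c(0.9, 0.9), n_frames = 10)
  g <- build_graph(rec)
  C <- matrix(0.1, 3, 3, dimnames = list(paste0("A:", 1:3),
                                         paste0("A:", 1:3)))
  diag(C) <- 1
  res <- shortest_paths_psn(g, "A:1", "A:3", correlations = C,
                            correlation_cutoff = 0.8)
  expect_length(res$paths, 0)
  expect_equal(res$discarded, 1L)
  # raising the interior correlation readmits the path
  C["A:2", "A:1"] <- C["A:1", "A:2"] <- 0.95
  res2 <- shortest_paths_psn(g, "A:1", "A:3", correlations = C,
                             correlation_cutoff = 0.8)
  expect_length(res2$paths, 1)
})

test_that("metapath edges are frequent edges of the retained paths", {
  # star-plus-chain: most paths share the hub edges
  edges <- data.frame(
    from = c("s1", "s2", "s3", "h", "m", "s1"),
    to = c("h", "h", "h", "m", "t", "t"),
    weight = c(0.2, 0.2, 0.2, 0.3, 0.3, 5)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  res <- shortest_paths_psn(g, c("s1", "s2", "s3"), "t",
                            metapath_frac = 0.5)
  expect_length(res$paths, 3)
  union_edges <- unique(unlist(lapply(res$paths, function(p) {
    paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]), sep = "->")
  })))
  meta_keys <- paste(pmin(res$metapath$from, res$metapath$to),
                     pmax(res$metapath$from, res$metapath$to), sep = "->")
  expect_true(all(meta_keys %in% union_edges))
  # h-m and m-t lie on every retained path
  expect_true(all(c("h->m", "m->t") %in% meta_keys))
  expect_true(all(res$metapath$frequency[meta_keys %in% c("h->m", "m->t")] == 1))
})
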