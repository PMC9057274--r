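test_that("degree moments match a two-pass oracle and the honeycomb degenerates", {
  net <- build_honeycomb(5, 5)
  dm <- degree_moments(net)
  expect_identical(dm$mean_k, 3)
  expect_identical(dm$mu2_k, 0)
  # degrees {2, 3, 4}
  tri <- planar_network(rbind(c(1, 1), c(2, 1), c(1.5, 2), c(1.5, 0.2)),
                        rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4)),
                        list(width = 3, height = 3, periodic = FALSE))
  dm2 <- degree_moments(tri)
  expect_equal(dm2$mean_k, mean(c(3, 3, 2, 2)))
  # random degree multiset against the oracle
  set.seed(18)
  x <- sample(2:9, 1000, replace = TRUE)
  o <- oracle_moments(x)
  m <- mean(x)
  expect_equal(mean((x - m)^2), unname(o["mu2"]), tolerance = 1e-12)
})

test_that("second central moment is translation invariant and zero for constants", {
  o <- oracle_moments(rep(6, 50))
  expect_identical(unname(o["mu2"]), 0)
  set.seed(19)
  x <- rpois(200, 5)
  expect_equal(unname(oracle_moments(x)["mu2"]),
               unname(oracle_moments(x + 7)["mu2"]), tolerance = 1e-12)
})

test_that("ring statistics on simple fixtures", {
  net <- build_honeycomb(4, 4)
  rs <- ring_stats(net)
  expect_equal(rs$mean_n, 6)
  expect_equal(rs$mu2_n, 0)
  expect_equal(rs$N_rings, 16L)
  # sizes {5, 7} -> mean 6, mu2 1 (after one accepted switch)
  expect_equal(oracle_moments(c(5, 7))[["mu2"]], 1)
})

test_that("Euler finite-size correction gives 5.94 at 100 rings", {
  expect_equal(finite_ring_mean(100), 5.94)
  expect_lt(finite_ring_mean(40), 6)
  # cross-validated on the explicit trivalent patch: V = 2(N-1), E = 3(N-1)
  patch <- trivalent_patch(100)
  expect_true(all(lengths(patch$adjacency) == 3))
  expect_equal(length(patch$rings), 100)
  expect_equal(nrow(patch$positions), 198)
  E <- network_edge_count(patch)
  expect_equal(E, 297)
  expect_equal(2 * E / length(patch$rings), finite_ring_mean(100))
  expect_true(validate_network(patch)$all_passed)
})

test_that("ring adjacency yields one dual edge per shared primal edge", {
  net <- build_honeycomb(3, 3)
  dual <- ring_adjacency(net)
  expect_equal(nrow(dual), 27)  # = E on a periodic net
  expect_true(all(dual == 6))
  # single finite hexagon: no interior shared edges
  th <- 2 * pi * (0:5) / 6
  hexn <- planar_network(cbind(2 + cos(th), 2 + sin(th)),
                         cbind(1:6, c(2:6, 1)),
                         list(width = 4, height = 4, periodic = FALSE))
  expect_equal(nrow(ring_adjacency(hexn)), 0)
})

test_that("assortativity matches the brute-force Pearson oracle", {
  # perfectly alternating pairs are maximally disassortative
  alt <- cbind(rep(4, 8), rep(8, 8))
  expect_equal(ring_assortativity(alt), -1, tolerance = 1e-12)
  # mixed multiset with explicit multiplicities
  pairs <- rbind(matrix(rep(c(5, 5), 2), ncol = 2, byrow = TRUE),
                 c(5, 7), c(7, 5),
                 matrix(rep(c(7, 7), 2), ncol = 2, byrow = TRUE))
  expect_equal(ring_assortativity(pairs), oracle_assortativity(pairs),
               tolerance = 1e-12)
  # random lists
  set.seed(20)
  for (i in 1:20) {
    p <- cbind(sample(3:9, 30, TRUE), sample(3:9, 30, TRUE))
    expect_equal(ring_assortativity(p), oracle_assortativity(p),
                 tolerance = 1e-12)
  }
  # zero-variance case is undefined, not zero
  expect_true(is.na(ring_assortativity(cbind(rep(6, 5), rep(6, 5)))))
  expect_error(ring_assortativity(alt[0, , drop = FALSE]), "empty")
})

test_that("assortativity is symmetric, permutation invariant, and null-centred", {
  set.seed(22)
  p <- cbind(sample(4:9, 40, TRUE), sample(4:9, 40, TRUE))
  expect_equal(ring_assortativity(p), ring_assortativity(p[, 2:1]),
               tolerance = 1e-12)
  expect_equal(ring_assortativity(p), ring_assortativity(p[sample(40), ]),
               tolerance = 1e-12)
  # i.i.d. re-pairing of a fixed size multiset: r ~ 0 within 3 sigma of the
  # permutation distribution
  sizes <- sample(c(4, 5, 6, 6, 7, 8), 60, TRUE)
  rs <- vapply(1:200, function(i) {
    idx <- matrix(sample(length(sizes)), ncol = 2)
    ring_assortativity(cbind(sizes[idx[, 1]], sizes[idx[, 2]]))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)) + 0.02)
})

test_that("boundary pruning removes clipped edges and keeps the net valid", {
  # interior-only network is untouched
  th <- 2 * pi * (0:5) / 6
  hexn <- planar_network(cbind(3 + cos(th), 3 + sin(th)),
                         cbind(1:6, c(2:6, 1)),
                         list(width = 6, height = 6, periodic = FALSE))
  pr <- boundary_prune(hexn)
  expect_equal(nrow(pr$positions), 6)
  expect_equal(network_edge_count(pr), 6)
  # honeycomb patch clipped by a window: pruned net is valid with mean_k < 3
  net <- unwrap_network(build_honeycomb(5, 5))
  clip <- boundary_prune(net, boundary = c(0.5, 0.5,
                                           net$cell$width - 0.5,
                                           net$cell$height - 0.5))
  expect_lt(degree_moments(clip)$mean_k, 3)
  expect_true(all(lengths(clip$adjacency) >= 2))
  v <- validate_network(clip)
  expect_true(v$all_passed)
})

test_that("the metric report assembles all fields and is label invariant", {
  net <- build_honeycomb(10, 10)
  rep <- network_report(net)
  expect_equal(rep$mean_k, 3)
  expect_equal(rep$mu2_k, 0)
  expect_equal(rep$mean_n, 6)
  expect_equal(rep$mu2_n, 0)
  expect_equal(rep$N_rings, 100L)
  expect_true(is.na(rep$r_assort))
  expect_equal(rep$V, 200L)
  expect_equal(rep$E, 300L)
  expect_true(rep$valid)
  expect_equal(rep$mean_n * rep$N_rings, 2 * rep$E)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
  # permuted node ids leave the report unchanged
  set.seed(23)
  perm <- sample(200)
  inv <- order(perm)
  ed <- network_edges(net)
  net2 <- planar_network(net$positions[inv, ],
                         cbind(perm[ed[, 1]], perm[ed[, 2]]), net$cell)
  rep2 <- network_report(net2)
  expect_equal(as.data.frame(rep2), as.data.frame(rep))
})

test_that("a disordered network reports finite metrics with r in [-1, 1]", {
  set.seed(24)
  net <- build_honeycomb(6, 6)
  res <- run_fixed_T(net, schedule = fixed_t_schedule(T_fixed = 0.3, steps = 1500))
  rep <- network_report(res$network)
  expect_true(is.finite(rep$mu2_k))
  expect_true(is.finite(rep$mean_n))
  expect_true(is.na(rep$r_assort) ||
                (rep$r_assort >= -1 && rep$r_assort <= 1))
})
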