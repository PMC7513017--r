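test_that("generated networks are reproducible, symmetric and have exactly m weighted edges", {
  for (family in c("random", "lattice", "ring_lattice", "small_world")) {
    for (m in c(16, 40, 120)) {
      C <- generate_network(family, n = 16, m = m, seed = 123)
      expect_s3_class(C, "connectivity")
      expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
      expect_equal(sum(C[upper.tri(C)] > 0), m)
      expect_true(all(C[C > 0] > 0 & C[C > 0] < 1))
      expect_identical(unclass(generate_network(family, 16, m, seed = 123)),
                       unclass(C))
      expect_false(identical(unclass(generate_network(family, 16, m, seed = 124)),
                             unclass(C)))
    }
  }
})

test_that("edge counts at the extremes give complete and ring topologies", {
  # m = n(n-1)/2 is the complete graph for the random family
  C <- generate_network("random", n = 16, m = 120, seed = 1)
  expect_true(all(C[upper.tri(C)] > 0))
  # a ring lattice with m = n edges is a single ring: all degrees 2
  R <- generate_network("ring_lattice", n = 16, m = 16, seed = 1)
  expect_equal(unname(rowSums(R > 0)), rep(2, 16))
  # m = k n gives near-regular degree 2k
  R2 <- generate_network("ring_lattice", n = 16, m = 48, seed = 1)
  expect_equal(unname(rowSums(R2 > 0)), rep(6, 16))
  expect_error(generate_network("random", n = 16, m = 121), "out of range")
  expect_error(generate_network("random", n = 16, m = 0), "out of range")
})

test_that("lattice boundaries lower the minimum degree relative to the ring lattice", {
  for (m in c(32, 48, 64)) {
    L <- generate_network("lattice", n = 16, m = m, seed = 2)
    R <- generate_network("ring_lattice", n = 16, m = m, seed = 2)
    expect_lt(min(rowSums(L > 0)), min(rowSums(R > 0)))
  }
})

test_that("small-world networks are more modular than random ones at matched size", {
  # known contiguous two-node modules versus the same partition on a random graph
  membership <- rep(1:8, each = 2)
  q <- function(C) {
    g <- igraph::graph_from_adjacency_matrix(unclass(C) > 0, mode = "undirected")
    igraph::modularity(g, membership)
  }
  qs <- vapply(1:20, function(s) {
    c(sw = q(generate_network("small_world", 16, 116, cluster_size = 2, seed = s)),
      rnd = q(generate_network("random", 16, 116, seed = s)))
  }, c(sw = 0, rnd = 0))
  expect_gt(mean(qs["sw", ]), mean(qs["rnd", ]))
})

test_that("small-world generation covers both sparse and dense regimes", {
  # below the intra-module total: all edges intra-module
  mem <- rep(1:4, each = 4)
  Cs <- generate_network("small_world", n = 16, m = 10, cluster_size = 4, seed = 9)
  idx <- which(upper.tri(Cs) & Cs > 0, arr.ind = TRUE)
  expect_true(all(mem[idx[, 1]] == mem[idx[, 2]]))
  # above it: every intra-module pair present plus inter-module extras
  Cd <- generate_network("small_world", n = 16, m = 60, cluster_size = 4, seed = 9)
  for (b in 1:4) {
    block <- unclass(Cd)[mem == b, mem == b]
    expect_true(all(block[upper.tri(block)] > 0))
  }
  expect_equal(sum(Cd[upper.tri(Cd)] > 0), 60)
})

test_that("sweeps cover the requested grid, clamp overshoot and record usable seeds", {
  tab <- edge_sweep("random", n = 16, m_values = c(20, 60, 130),
                    replicates = 2, seed = 77)
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$m)), c(20, 60, 120))  # 130 clamped to complete
  expect_equal(tab$density, 2 * tab$m / (16 * 15))
  # rows are reproducible from their recorded seed
  row <- tab[3, ]
  C <- generate_network("random", n = 16, m = row$m, seed = row$seed)
  g <- global_measures(random_walk_model(C))
  expect_equal(g$H, row$H)
  expect_equal(g$EMI, row$EMI)
  # node sweep sets m from the density
  nt <- node_sweep("ring_lattice", n_values = c(8, 16), density = 0.4,
                   replicates = 1, seed = 5)
  expect_equal(nt$m, as.integer(round(0.4 * nt$n * (nt$n - 1) / 2)))
  # identical master seed reproduces the whole table
  expect_identical(edge_sweep("random", 16, c(20, 60), replicates = 2, seed = 1),
                   edge_sweep("random", 16, c(20, 60), replicates = 2, seed = 1))
})
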