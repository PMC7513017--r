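test_that("worked examples give the closed-form transition matrix and stationary law", {
  # 4-node unit cycle: uniform mu, each row splits 1/2 over the two neighbours
  m <- random_walk_model(cycle_graph(4))
  expect_equal(as.numeric(coef(m)), rep(1 / 4, 4))
  expect_equal(unname(rowSums(m$P > 0)), rep(2, 4))
  expect_true(all(m$P[m$P > 0] == 0.5))

  # a single edge: equal stationary mass regardless of the weight
  for (w in c(1, 0.2, 17)) {
    C <- as_connectivity(matrix(c(0, w, w, 0), 2))
    m2 <- random_walk_model(C)
    expect_equal(as.numeric(coef(m2)), c(0.5, 0.5))
    expect_equal(unname(m2$P), matrix(c(0, 1, 1, 0), 2))
  }

  # 3-node path: strengths (1,2,1), C_T = 4
  m3 <- random_walk_model(path_graph(3))
  expect_equal(as.numeric(coef(m3)), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(unname(m3$P[2, ]), c(1 / 2, 0, 1 / 2))
  expect_equal(m3$total_weight, 4)
})

test_that("symmetrize copies the upper triangle, zeroes the diagonal and is idempotent", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- 0.7
  C <- symmetrize(M)
  expect_equal(C[2, 1], 0.7)
  expect_equal(C[1, 2], 0.7)

  M2 <- diag(c(1, 2, 3))
  M2[1, 3] <- 2
  expect_equal(unname(diag(symmetrize(M2))), c(0, 0, 0))

  S <- unclass(cycle_graph(4))
  expect_equal(unclass(symmetrize(S)), unclass(S), ignore_attr = TRUE)
  expect_error(symmetrize(matrix(1, 2, 3)), "non-square")
})

test_that("model invariants hold on randomized graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    C <- random_connectivity(n, density = runif(1, 0.1, 0.9))
    m <- random_walk_model(C)
    s <- m$strengths
    # row-stochastic where strength > 0
    expect_true(all(abs(rowSums(m$P)[s > 0] - 1) < 1e-12))
    expect_true(all(rowSums(m$P)[s == 0] == 0))
    expect_lt(abs(sum(m$mu) - 1), 1e-12)
    # detailed balance mu_i P_ij = mu_j P_ji
    F <- m$mu * m$P
    expect_lt(max(abs(F - t(F))), 1e-12)
    # mu_i = 0 iff the node is isolated
    expect_equal(m$mu == 0, unname(s == 0), ignore_attr = TRUE)
  }
})

test_that("stationary probabilities are local: rewiring elsewhere at fixed total weight leaves mu_i unchanged", {
  set.seed(7)
  C <- random_connectivity(10, density = 0.6)
  m <- random_walk_model(C)
  # move weight between two edges not touching node 1, keeping C_T fixed
  others <- unclass(C)
  stopifnot(others[2, 3] > 0, others[4, 5] > 0)
  delta <- min(others[4, 5], 0.9 * others[4, 5])
  others[2, 3] <- others[2, 3] + delta; others[3, 2] <- others[2, 3]
  others[4, 5] <- others[4, 5] - delta; others[5, 4] <- others[4, 5]
  m2 <- random_walk_model(as_connectivity(others))
  expect_equal(m2$total_weight, m$total_weight)
  expect_equal(m2$mu[[1]], m$mu[[1]], tolerance = 1e-12)
})

test_that("transition matrix and stationary law are scale invariant", {
  set.seed(11)
  C <- random_connectivity(8, density = 0.5)
  m <- random_walk_model(C)
  m2 <- random_walk_model(as_connectivity(unclass(C) * 37.5))
  expect_equal(m2$P, m$P, tolerance = 1e-12)
  expect_equal(m2$mu, m$mu, tolerance = 1e-12)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(random_walk_model(matrix(0, 3, 3)), "no edges")
  A <- matrix(c(0, 0, 1, 0), 2)   # single entry above the diagonal
  expect_error(as_connectivity(A), "asymmetric")
  expect_equal(as_connectivity(A, symmetrize = TRUE)[2, 1], 1)
  Nn <- matrix(c(0, -0.3, -0.3, 0), 2)
  expect_error(as_connectivity(Nn), "negative weight")
  expect_equal(sum(as_connectivity(Nn, clip_negative = TRUE)), 0)
  expect_error(as_connectivity(matrix(1, 2, 3)), "square")
})

test_that("isolated nodes stay in the model with zero mass", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 1
  m <- random_walk_model(as_connectivity(C))
  expect_equal(sum(m$isolated), 2)
  expect_equal(as.numeric(m$mu), c(0.5, 0.5, 0, 0))
  expect_true(all(m$P[3:4, ] == 0))
})
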