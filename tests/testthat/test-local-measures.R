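test_that("local measures reproduce the worked toy graphs", {
  m <- random_walk_model(cycle_graph(4))
  # every cycle node: surprise -log2(2/8) = 2 bits, I1 = I2 = I1e = 1 bit
  expect_equal(as.numeric(entropic_surprise(m)), rep(2, 4))
  expect_equal(as.numeric(mutual_surprise(m)), rep(1, 4))
  expect_equal(as.numeric(mutual_predictability(m)), rep(1, 4))
  expect_equal(as.numeric(erasure_surprise(m)), rep(1, 4))

  expect_equal(as.numeric(entropic_surprise(random_walk_model(path_graph(2)))),
               c(1, 1))

  m3 <- random_walk_model(path_graph(3))
  loc <- local_measures(m3)
  expect_equal(loc$E, c(2, 1, 2))
  expect_equal(loc$I1, c(1, 1, 1))
  expect_equal(loc$I2, c(1.5, 0.5, 1.5))
  expect_equal(loc$I1e, c(1, 1, 1))

  # star: centre and leaves both carry 1 bit of mutual surprise
  ms <- random_walk_model(star_graph(4))
  I1 <- mutual_surprise(ms)
  expect_equal(as.numeric(I1), c(1, rep(1, 4)))
  g <- global_measures(ms)
  expect_equal(sum(coef(ms) * I1), g$MI, tolerance = 1e-12)
})

test_that("each local measure decomposes its global counterpart exactly", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(2:48, 1)
    C <- random_connectivity(n, density = runif(1, 0.05, 0.9))
    m <- random_walk_model(C)
    g <- global_measures(m)
    loc <- local_measures(m)
    wsum <- function(v) sum((m$mu * v)[m$mu > 0])
    expect_equal(wsum(loc$E), g$H, tolerance = 1e-9)
    expect_equal(wsum(loc$I1), g$MI, tolerance = 1e-9)
    expect_equal(wsum(loc$I2), g$MI, tolerance = 1e-9)
    expect_equal(wsum(loc$I1e), g$EMI, tolerance = 1e-9)
    # nonnegativity (I2 exempt by design) and the H bound on I2
    expect_true(all(loc$E[!is.na(loc$E)] >= 0))
    expect_true(all(loc$I1[!is.na(loc$I1)] >= 0))
    expect_true(all(loc$I1e[!is.na(loc$I1e)] >= 0))
    expect_true(all(loc$I2[!is.na(loc$I2)] <= g$H + 1e-12))
  }
})

test_that("local vectors agree with the brute-force enumerator on small graphs", {
  set.seed(321)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    C <- random_connectivity(n, density = runif(1, 0.2, 1))
    m <- random_walk_model(C)
    o <- oracle_measures(C)
    expect_equal(as.numeric(entropic_surprise(m)), o$E, tolerance = 1e-9)
    expect_equal(as.numeric(mutual_surprise(m)), o$I1, tolerance = 1e-9)
    expect_equal(as.numeric(mutual_predictability(m)), o$I2, tolerance = 1e-9)
    expect_equal(as.numeric(erasure_surprise(m)), o$I1e, tolerance = 1e-9)
  }
})

test_that("entropic surprise is the exact log transform of strength", {
  set.seed(17)
  C <- random_connectivity(20, density = 0.4)
  m <- random_walk_model(C)
  E <- entropic_surprise(m)
  ok <- !is.na(E)
  expect_equal(as.numeric(E[ok]),
               -log2(as.numeric(m$strengths[ok]) / m$total_weight),
               tolerance = 1e-12)
  # E_i + log2(strength_i) is the same constant log2(C_T) for all nodes
  expect_equal(as.numeric(E[ok] + log2(m$strengths[ok])),
               rep(log2(m$total_weight), sum(ok)), tolerance = 1e-9)
})

test_that("a bridge between cliques has higher erasure surprise than clique interiors", {
  C <- bridged_cliques()
  m <- random_walk_model(C)
  I1e <- erasure_surprise(m)
  interiors <- c(2, 3, 4, 6, 7, 8)    # same strength as the bridge node 9
  expect_equal(as.numeric(m$strengths[c(interiors, 9)]), rep(3, 7))
  expect_gt(I1e[[9]], max(I1e[interiors]))
  # cross-checked against the enumeration oracle
  o <- oracle_measures(C)
  expect_equal(as.numeric(I1e), o$I1e, tolerance = 1e-9)
})

test_that("isolated nodes are reported as not applicable, never zero", {
  C <- matrix(0, 5, 5)
  C[1, 2] <- C[2, 1] <- 2
  C[2, 3] <- C[3, 2] <- 1
  loc <- local_measures(random_walk_model(as_connectivity(C)))
  expect_true(all(is.na(loc[4:5, c("E", "I1", "I2", "I1e")])))
  expect_true(all(!is.na(loc[1:3, c("E", "I1", "I2", "I1e")])))
})
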