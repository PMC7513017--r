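# Fixture graphs built in code.

cycle_graph <- function(n = 4, w = 1) {
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    C[i, j] <- C[j, i] <- w
  }
  as_connectivity(C)
}

path_graph <- function(n = 3, w = 1) {
  C <- matrix(0, n, n)
  for (i in seq_len(n - 1)) C[i, i + 1] <- C[i + 1, i] <- w
  as_connectivity(C)
}

star_graph <- function(leaves = 4, w = 1) {
  n <- leaves + 1
  C <- matrix(0, n, n)
  C[1, 2:n] <- C[2:n, 1] <- w
  as_connectivity(C)
}

complete_graph <- function(n, w = 1) {
  C <- matrix(w, n, n)
  diag(C) <- 0
  as_connectivity(C)
}

# two 4-cliques joined through a single bridge node whose strength matches
# the interior clique nodes
bridged_cliques <- function() {
  C <- matrix(0, 9, 9)
  C[1:4, 1:4] <- 1
  C[5:8, 5:8] <- 1
  diag(C) <- 0
  C[9, 1] <- C[1, 9] <- 1.5
  C[9, 5] <- C[5, 9] <- 1.5
  as_connectivity(C)
}

# random weighted connectivity; may contain isolated nodes
random_connectivity <- function(n, density = 0.5) {
  repeat {
    C <- matrix(0, n, n)
    ut <- upper.tri(C)
    on <- ut & matrix(runif(n * n) < density, n, n)
    C[on] <- runif(sum(on))
    if (any(C > 0)) break
  }
  as_connectivity(C, symmetrize = TRUE)
}
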