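# Benchmark network generators: random, lattice, ring lattice and
# small-world topologies with a prescribed number of undirected edges and
# i.i.d. uniform(0,1) edge weights.

NETWORK_FAMILIES <- c("random", "lattice", "ring_lattice", "small_world")

# pairs (i, j), i < j, as a 2-column matrix, in the generator's fill order
lattice_pairs <- function(n, wrap) {
  pairs <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    if (wrap) {
      if (2 * k > n) break
      i <- if (2 * k == n) seq_len(n / 2) else seq_len(n)
      j <- ((i + k - 1) %% n) + 1
    } else {
      i <- seq_len(n - k)
      j <- i + k
    }
    pairs[[k]] <- cbind(pmin(i, j), pmax(i, j))
  }
  do.call(rbind, pairs)
}

all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

# module membership: contiguous blocks of cluster_size nodes
module_membership <- function(n, cluster_size) {
  rep(seq_len(ceiling(n / cluster_size)), each = cluster_size)[seq_len(n)]
}

#' Generate a synthetic benchmark network
#'
#' Builds a weighted undirected network with `n` nodes and exactly `m` edges
#' from one of four topology families, then assigns each edge an independent
#' uniform(0,1) weight (zero excluded, so edge presence and positive weight
#' coincide):
#'
#' * `"random"`: `m` node pairs drawn uniformly without replacement.
#' * `"lattice"`: pairs filled in increasing band order away from the
#'   diagonal, without wraparound, so end nodes have fewer connections.
#' * `"ring_lattice"`: the same band fill with wraparound, giving a
#'   boundary-free near-regular ring.
#' * `"small_world"`: nodes are partitioned into contiguous fully connected
#'   modules of `cluster_size` nodes; remaining edges are placed uniformly at
#'   random between modules (if `m` is below the intra-module total, a
#'   uniform subsample of intra-module edges is used).
#'
#' @param family one of `"random"`, `"lattice"`, `"ring_lattice"`,
#'   `"small_world"`.
#' @param n node count.
#' @param m undirected edge count, `1 <= m <= n(n-1)/2`.
#' @param cluster_size nodes per module (small-world only); default
#'   `ceiling(n/8)`, i.e. eight modules.
#' @param seed optional integer seed; the same spec and seed reproduce the
#'   matrix bit for bit.
#' @return a `"connectivity"` matrix with a `"network_spec"` attribute
#'   recording the generator parameters.
#' @examples
#' C <- generate_network("ring_lattice", n = 16, m = 16, seed = 7)
#' table(rowSums(C > 0))  # every node has exactly two neighbours
#' @export
generate_network <- function(family = NETWORK_FAMILIES, n, m,
                             cluster_size = NULL, seed = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  m <- as.integer(m)
  max_m <- n * (n - 1) / 2
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (m < 1 || m > max_m) {
    stop(sprintf("edge count m = %d out of range [1, %d] for n = %d",
                 m, max_m, n), call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  pairs <- switch(family,
    random = {
      p <- all_pairs(n)
      p[sample.int(nrow(p), m), , drop = FALSE]
    },
    lattice = lattice_pairs(n, wrap = FALSE)[seq_len(m), , drop = FALSE],
    ring_lattice = lattice_pairs(n, wrap = TRUE)[seq_len(m), , drop = FALSE],
    small_world = {
      if (is.null(cluster_size)) cluster_size <- max(2L, ceiling(n / 8))
      if (cluster_size < 2) stop("cluster_size must be at least 2",
                                 call. = FALSE)
      mem <- module_membership(n, cluster_size)
      p <- all_pairs(n)
      intra <- mem[p[, 1]] == mem[p[, 2]]
      n_intra <- sum(intra)
      if (m >= n_intra) {
        extra <- which(!intra)
        rbind(p[intra, , drop = FALSE],
              p[sample(extra, m - n_intra), , drop = FALSE])
      } else {
        p[sample(which(intra), m), , drop = FALSE]
      }
    })
  w <- stats::runif(m)
  while (any(w == 0)) w[w == 0] <- stats::runif(sum(w == 0))  # open interval
  C <- matrix(0, n, n)
  C[cbind(pairs[, 1], pairs[, 2])] <- w
  C <- as_connectivity(C, symmetrize = TRUE)
  attr(C, "network_spec") <- list(family = family, n = n, m = m,
                                  cluster_size = cluster_size,
                                  weight_law = "uniform(0,1)", seed = seed)
  C
}

# per-run reproducible seeds derived from one master seed
derive_seeds <- function(seed, k) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  sample.int(.Machine$integer.max - 1L, k)
}

sweep_row <- function(family, n, m, replicate, seed, cluster_size) {
  C <- generate_network(family, n = n, m = m, cluster_size = cluster_size,
                        seed = seed)
  g <- global_measures(random_walk_model(C))
  data.frame(family = family, n = n, m = m, replicate = replicate,
             seed = seed, density = edge_density(n, m),
             H = g$H, MI = g$MI, EMI = g$EMI,
             H_cond_past = g$H_cond_past,
             H_cond_context = g$H_cond_context,
             stringsAsFactors = FALSE)
}

#' Sweep the global measures over an edge-count grid
#'
#' For each edge count in `m_values` and each replicate, generates a network
#' of the given family at fixed `n`, fits the random-walk model and records
#' all global measures. Edge counts exceeding the complete graph are clamped
#' to `n(n-1)/2` (a grid in fixed steps may overshoot the complete graph).
#'
#' @param family network family (see [generate_network()]).
#' @param n node count.
#' @param m_values integer vector of edge counts.
#' @param replicates networks per grid point.
#' @param seed master seed; per-run seeds are derived from it and recorded.
#' @param cluster_size small-world module size (see [generate_network()]).
#' @return a long-format data frame: `family`, `n`, `m`, `replicate`,
#'   `seed`, `density`, `H`, `MI`, `EMI`, `H_cond_past`, `H_cond_context`.
#' @export
edge_sweep <- function(family, n, m_values, replicates = 10, seed = NULL,
                       cluster_size = NULL) {
  m_values <- pmin(as.integer(m_values), as.integer(n * (n - 1) / 2))
  grid <- expand.grid(replicate = seq_len(replicates), m = m_values)
  seeds <- derive_seeds(seed, nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(r) {
    sweep_row(family, n, grid$m[r], grid$replicate[r], seeds[r], cluster_size)
  })
  do.call(rbind, out)
}

#' Sweep the global measures over a node-count grid at fixed density
#'
#' For each `n` in `n_values`, sets `m = round(density * n(n-1)/2)` and
#' proceeds as [edge_sweep()].
#'
#' @inheritParams edge_sweep
#' @param n_values integer vector of node counts.
#' @param density fraction of possible edges, in (0, 1].
#' @return as [edge_sweep()].
#' @export
node_sweep <- function(family, n_values, density = 0.4, replicates = 10,
                       seed = NULL, cluster_size = NULL) {
  stopifnot(density > 0, density <= 1)
  n_values <- as.integer(n_values)
  grid <- expand.grid(replicate = seq_len(replicates), n = n_values)
  grid$m <- pmax(1L, as.integer(round(density * grid$n * (grid$n - 1) / 2)))
  seeds <- derive_seeds(seed, nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(r) {
    sweep_row(family, grid$n[r], grid$m[r], grid$replicate[r], seeds[r],
              cluster_size)
  })
  do.call(rbind, out)
}
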