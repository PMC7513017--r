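# Per-node decompositions of the global measures. Each local vector v
# satisfies an exact identity sum_i mu_i v_i = (global counterpart); isolated
# nodes (mu_i = 0) get NA so tables never mix conventions.

#' Entropic surprise of each node
#'
#' `E_i = -log2(mu_i)`: the surprise of finding the walker on node `i` under
#' the stationary distribution. Low for strongly connected (high-strength)
#' nodes, high for weakly connected ones; `sum_i mu_i E_i = H(mu)`. Since
#' `mu_i = strength_i / C_T`, `E_i` is an exact log transform of the node
#' strength: `E_i = log2(C_T) - log2(strength_i)`.
#'
#' @param model a [random_walk_model()] fit.
#' @return named vector of surprises in bits (`NA` for isolated nodes).
#' @export
entropic_surprise <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  E <- rep(NA_real_, model$n)
  ok <- !model$isolated
  E[ok] <- -log2(model$mu[ok])
  stats::setNames(E, model$labels)
}

#' Mutual surprise of each node
#'
#' `I1_i = sum_j P_ij log2(P_ij / mu_j)`: the Kullback-Leibler divergence
#' between the walker's next-step distribution from node `i` and the
#' stationary distribution. Always nonnegative; high when node `i` is
#' connected to nodes that are unlikely under the stationary distribution
#' (i.e., poorly connected neighbours); `sum_i mu_i I1_i = MI`.
#'
#' @param model a [random_walk_model()] fit.
#' @return named vector in bits (`NA` for isolated nodes).
#' @export
mutual_surprise <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  I1 <- rep(NA_real_, model$n)
  for (i in which(!model$isolated)) {
    s <- which(model$P[i, ] > 0)
    p <- model$P[i, s]
    I1[i] <- clamp0(sum(p * log2(p / model$mu[s])), sprintf("I1[%d]", i))
  }
  stats::setNames(I1, model$labels)
}

#' Mutual predictability of each node
#'
#' `I2_i = H(mu) - H(Xt+1 | Xt = i) = H(mu) + sum_j P_ij log2(P_ij)`: how
#' much less uncertain the next step is from node `i` than a stationary draw.
#' Unlike the mutual surprise it can be negative (a node whose next step is
#' more uncertain than the network average); it is additive over observations
#' and satisfies `sum_i mu_i I2_i = MI`.
#'
#' @param model a [random_walk_model()] fit.
#' @return named vector in bits (`NA` for isolated nodes).
#' @export
mutual_predictability <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  H <- stationary_entropy(model)
  I2 <- rep(NA_real_, model$n)
  ok <- !model$isolated
  I2[ok] <- H + rowSums(xlog2x(model$P))[ok]
  stats::setNames(I2, model$labels)
}

#' Erasure surprise of each node
#'
#' The per-node decomposition of the erasure mutual information:
#' `I1e_i = sum_{j,k} p(j,k | i) log2( p(j,k | i) / p(j,k) )`, the
#' Kullback-Leibler divergence between the (past, future) pair distribution
#' conditioned on the present node `i` and its stationary marginal
#' `p(j,k) = mu_j Q_jk`, `Q = P %*% P`. By reversibility the backward step
#' probability `p(Xt-1 = j | Xt = i) = mu_j P_ji / mu_i` equals `P_ij`, so
#' `p(j,k | i) = P_ij P_ik`. Always nonnegative; high for bridge-like nodes
#' that lie on unique paths between otherwise unconnected regions, low for
#' nodes inside densely interconnected clusters;
#' `sum_i mu_i I1e_i = EMI`.
#'
#' @param model a [random_walk_model()] fit.
#' @return named vector in bits (`NA` for isolated nodes).
#' @export
erasure_surprise <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  P <- model$P
  mu <- model$mu
  Q <- P %*% P
  I1e <- rep(NA_real_, model$n)
  for (i in which(!model$isolated)) {
    s <- which(P[i, ] > 0)           # neighbours: both backward and forward support
    W <- outer(P[i, s], P[i, s])     # p(j,k | i)
    den <- mu[s] * Q[s, s, drop = FALSE]  # mu_j Q_jk (mu recycles down rows)
    I1e[i] <- clamp0(sum(W * log2(W / den)), sprintf("I1e[%d]", i))
  }
  stats::setNames(I1e, model$labels)
}

#' Per-node table of all local measures
#'
#' @param model a [random_walk_model()] fit.
#' @return a data frame with one row per node: `node` (label), `strength`,
#'   and the four local measures `E`, `I1`, `I2`, `I1e` in bits (`NA` for
#'   isolated nodes).
#' @examples
#' path3 <- as_connectivity(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' local_measures(random_walk_model(path3))
#' @export
local_measures <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  data.frame(
    node = model$labels,
    strength = as.numeric(model$strengths),
    E = as.numeric(entropic_surprise(model)),
    I1 = as.numeric(mutual_surprise(model)),
    I2 = as.numeric(mutual_predictability(model)),
    I1e = as.numeric(erasure_surprise(model)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# all nodes attaining the max / min of a measure (ties reported together)
extreme_nodes <- function(values, labels) {
  ok <- !is.na(values)
  if (!any(ok)) return(list(max = character(0), min = character(0)))
  list(max = labels[ok][values[ok] == max(values[ok])],
       min = labels[ok][values[ok] == min(values[ok])])
}
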