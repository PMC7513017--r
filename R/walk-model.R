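#' Fit the stationary random-walk model of a connectome
#'
#' Interprets a weighted undirected connectivity matrix `C` as the arena of a
#' random walk: from node `i` the walker moves to a neighbour `j` with
#' probability proportional to the edge weight, `P[i,j] = C[i,j] / C_i`, where
#' `C_i = sum_j C[i,j]` is the node strength. Because the graph is undirected
#' the chain is reversible and its stationary distribution has the closed form
#' `mu_i = C_i / C_T`, with `C_T = sum(C)` the total (bidirectional) weight.
#' All information-theoretic measures in this package are functionals of the
#' fitted pair `(P, mu)`.
#'
#' Isolated nodes (strength 0) are kept in the model with `mu_i = 0` and an
#' all-zero transition row; they contribute nothing to the global measures
#' (the `0 log 0 = 0` convention) and their local measures are reported as
#' `NA`.
#'
#' @param C connectivity matrix (anything accepted by [as_connectivity()]).
#' @inheritParams as_connectivity
#' @return an object of class `"random_walk_model"`: a list with elements
#'   `C` (the validated connectivity matrix), `P` (row-stochastic transition
#'   matrix), `mu` (stationary distribution), `strengths`, `total_weight`
#'   (`C_T`, sum over all directed entries), `n`, `m` (undirected edge count),
#'   `density`, `isolated` (logical per node) and `labels`.
#' @examples
#' cyc <- as_connectivity(rbind(c(0, 1, 0, 1),
#'                              c(1, 0, 1, 0),
#'                              c(0, 1, 0, 1),
#'                              c(1, 0, 1, 0)))
#' fit <- random_walk_model(cyc)
#' coef(fit)            # stationary distribution: 1/4 each
#' global_measures(fit) # H = 2, MI = 1, EMI = 1 bits
#' @seealso [global_measures()], [local_measures()], [reference_measures()]
#' @export
random_walk_model <- function(C, symmetrize = FALSE, clip_negative = FALSE) {
  cl <- match.call()
  C <- as_connectivity(C, symmetrize = symmetrize,
                       clip_negative = clip_negative)
  strengths <- rowSums(C)
  total <- sum(strengths)
  if (total <= 0) {
    stop("no edges: the connectivity matrix has zero total weight",
         call. = FALSE)
  }
  n <- nrow(C)
  isolated <- strengths == 0
  P <- C / ifelse(isolated, 1, strengths)   # all-zero rows for isolated nodes
  mu <- strengths / total
  stopifnot(abs(sum(mu) - 1) < 1e-12)
  structure(list(
    C = C,
    P = unclass(P),
    mu = stats::setNames(mu, rownames(C)),
    strengths = stats::setNames(strengths, rownames(C)),
    total_weight = total,
    n = n,
    m = n_edges(C),
    density = edge_density(n, n_edges(C)),
    isolated = isolated,
    labels = rownames(C),
    call = cl
  ), class = "random_walk_model")
}

#' @export
print.random_walk_model <- function(x, digits = 4, ...) {
  cat("Stationary random-walk model of a weighted undirected network\n")
  cat(sprintf("  nodes: %d   edges: %d   density: %.4f   isolated nodes: %d\n",
              x$n, x$m, x$density, sum(x$isolated)))
  g <- global_measures(x)
  cat(sprintf("  H = %.*f bits   MI = %.*f bits   EMI = %.*f bits\n",
              digits, g$H, digits, g$MI, digits, g$EMI))
  invisible(x)
}

#' Stationary distribution of a fitted random-walk model
#'
#' @param object a [random_walk_model()] fit.
#' @param ... unused.
#' @return named numeric vector `mu` (one probability per node).
#' @export
coef.random_walk_model <- function(object, ...) object$mu

#' Summarise a random-walk connectome model
#'
#' Collects the global measures, the per-node local measures and the standard
#' reference measures into one object.
#'
#' @param object a [random_walk_model()] fit.
#' @param reference include strength/eccentricity/clustering columns.
#' @param ... unused.
#' @return an object of class `"summary.random_walk_model"` with elements
#'   `global` ([global_measures()]), `nodes` (the [local_measures()] table,
#'   with reference columns when requested) and `model` metadata.
#' @export
summary.random_walk_model <- function(object, reference = TRUE, ...) {
  nodes <- local_measures(object)
  if (reference) {
    ref <- reference_measures(object$C)
    nodes <- cbind(nodes, ref[, c("eccentricity", "clustering")])
  }
  structure(list(
    global = global_measures(object),
    nodes = nodes,
    n = object$n, m = object$m, density = object$density,
    isolated = sum(object$isolated)
  ), class = "summary.random_walk_model")
}

#' @export
print.summary.random_walk_model <- function(x, digits = 4, ...) {
  cat(sprintf("Random-walk connectome model: %d nodes, %d edges, density %.4f\n\n",
              x$n, x$m, x$density))
  print(x$global, digits = digits)
  cat("\nPer-node measures (bits):\n")
  print(utils::head(x$nodes, 10), digits = digits)
  if (nrow(x$nodes) > 10) cat(sprintf("  ... %d more nodes\n", nrow(x$nodes) - 10))
  invisible(x)
}

#' Predict the state distribution of the random walk
#'
#' Propagates a distribution over nodes through `steps` transitions of the
#' chain. With no starting point the stationary distribution is returned
#' (it is invariant under `P`).
#'
#' @param object a [random_walk_model()] fit.
#' @param from starting node (label or index), or a probability vector over
#'   nodes; `NULL` means the stationary distribution.
#' @param steps number of transitions (nonnegative integer).
#' @param ... unused.
#' @return named probability vector over the nodes.
#' @export
predict.random_walk_model <- function(object, from = NULL, steps = 1, ...) {
  n <- object$n
  if (is.null(from)) {
    p <- object$mu
  } else if (length(from) == 1) {
    i <- resolve_node(object, from)
    if (object$isolated[i]) {
      stop(sprintf("node '%s' is isolated: the walk cannot start there",
                   object$labels[i]), call. = FALSE)
    }
    p <- numeric(n)
    p[i] <- 1
  } else {
    stopifnot(length(from) == n, all(from >= 0), abs(sum(from) - 1) < 1e-8)
    p <- from / sum(from)
  }
  steps <- as.integer(steps)
  stopifnot(steps >= 0)
  for (k in seq_len(steps)) p <- as.numeric(p %*% object$P)
  stats::setNames(as.numeric(p), object$labels)
}

resolve_node <- function(model, node) {
  if (is.character(node)) {
    i <- match(node, model$labels)
    if (is.na(i)) stop(sprintf("unknown node label '%s'", node), call. = FALSE)
  } else {
    i <- as.integer(node)
    if (i < 1 || i > model$n) stop("node index out of range", call. = FALSE)
  }
  i
}

#' Simulate random walks on the fitted chain
#'
#' Draws walk trajectories from the fitted Markov chain, starting from the
#' stationary distribution (or a given node), so the simulated paths are
#' themselves stationary.
#'
#' @param object a [random_walk_model()] fit.
#' @param nsim number of independent walks.
#' @param seed optional integer seed.
#' @param length_out number of states per walk.
#' @param start optional fixed starting node (label or index).
#' @param ... unused.
#' @return a data frame with `length_out` rows and `nsim` columns of node
#'   labels, one column per simulated walk.
#' @export
simulate.random_walk_model <- function(object, nsim = 1, seed = NULL,
                                       length_out = 100, start = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  n <- object$n
  idx <- which(!object$isolated)
  walks <- vapply(seq_len(nsim), function(s) {
    path <- integer(length_out)
    path[1] <- if (is.null(start)) {
      sample(idx, 1, prob = object$mu[idx])
    } else resolve_node(object, start)
    for (t in seq_len(length_out - 1)) {
      path[t + 1] <- sample.int(n, 1, prob = object$P[path[t], ])
    }
    object$labels[path]
  }, character(length_out))
  as.data.frame(walks, col.names = paste0("walk_", seq_len(nsim)),
                stringsAsFactors = FALSE)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plot local measures against node strength
#'
#' Scatter plots of the four local measures versus node strength with the
#' best-fitting logarithmic curve `a + b log2(x)` overlaid, the standard way
#' the information measures are compared with conventional node measures.
#'
#' @param x a [random_walk_model()] fit.
#' @param which measures to plot (subset of `"E"`, `"I1"`, `"I2"`, `"I1e"`).
#' @param ... forwarded to [graphics::plot()].
#' @return invisibly, the [correlate_measures()] fit table used for the
#'   overlays.
#' @export
plot.random_walk_model <- function(x, which = c("E", "I1", "I2", "I1e"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  loc <- local_measures(x)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
  on.exit(graphics::par(op), add = TRUE)
  fits <- lapply(which, function(meas) {
    ok <- !is.na(loc[[meas]]) & loc$strength > 0
    graphics::plot(loc$strength[ok], loc[[meas]][ok],
                   xlab = "strength", ylab = paste(meas, "(bits)"), ...)
    fit <- tryCatch(fit_log_curve(loc$strength[ok], loc[[meas]][ok]),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      xs <- seq(min(loc$strength[ok]), max(loc$strength[ok]), length.out = 100)
      graphics::lines(xs, fit$a + fit$b * log2(xs))
    }
    fit
  })
  invisible(fits)
}
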