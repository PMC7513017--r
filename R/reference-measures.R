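# Standard node measures used to benchmark the information-theoretic ones:
# strength, eccentricity and the weighted clustering coefficient.

#' Node strength
#'
#' Sum of the weights of the edges incident to each node. The entropic
#' surprise is an exact log transform of it:
#' `E_i = log2(C_T) - log2(strength_i)`.
#'
#' @param C connectivity matrix (see [as_connectivity()]).
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(C) {
  C <- as_connectivity(C)
  rowSums(C)
}

#' Node eccentricity
#'
#' Maximal shortest-path distance from each node to any other node. By
#' default edges are given length `1/weight` (the usual conversion of
#' connectivity into distance: strong connections are short); with
#' `weighted = FALSE` every edge has length 1. Nodes that cannot reach every
#' other node (disconnected graphs) get `NA`.
#'
#' @param C connectivity matrix.
#' @param weighted use `1/weight` edge lengths (`TRUE`, default) or
#'   hop counts on the binarized graph (`FALSE`).
#' @return named numeric vector of eccentricities (`NA` where undefined).
#' @export
node_eccentricity <- function(C, weighted = TRUE) {
  C <- as_connectivity(C)
  g <- igraph::graph_from_adjacency_matrix(unclass(C), mode = "undirected",
                                           weighted = TRUE)
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  d <- igraph::distances(g, weights = w)
  diag(d) <- 0
  ecc <- apply(d, 1, max)
  ecc[!is.finite(ecc)] <- NA_real_
  if (nrow(C) == 1) ecc[] <- 0
  stats::setNames(ecc, rownames(C))
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) weighted clustering coefficient: with weights
#' normalised by the maximum weight, node `i` gets the total geometric-mean
#' intensity of the triangles through it divided by `k_i (k_i - 1)` possible
#' ordered neighbour pairs (`k_i` = binary degree). Values lie in `[0, 1]`;
#' nodes with fewer than two neighbours get 0.
#'
#' @param C connectivity matrix.
#' @return named numeric vector of clustering coefficients in `[0, 1]`.
#' @export
node_clustering <- function(C) {
  C <- as_connectivity(C)
  n <- nrow(C)
  k <- rowSums(C > 0)
  mx <- max(C)
  if (mx == 0) return(stats::setNames(numeric(n), rownames(C)))
  W <- (unclass(C) / mx)^(1 / 3)
  cyc3 <- diag(W %*% W %*% W)   # 2x the geometric-mean triangle intensity
  cc <- numeric(n)
  ok <- k >= 2
  cc[ok] <- cyc3[ok] / (k[ok] * (k[ok] - 1))
  stats::setNames(pmin(pmax(cc, 0), 1), rownames(C))
}

#' All reference measures as a table
#'
#' @param C connectivity matrix.
#' @param weighted_eccentricity passed to [node_eccentricity()].
#' @return a data frame with columns `node`, `strength`, `eccentricity`,
#'   `clustering`.
#' @export
reference_measures <- function(C, weighted_eccentricity = TRUE) {
  C <- as_connectivity(C)
  data.frame(
    node = rownames(C),
    strength = as.numeric(node_strength(C)),
    eccentricity = as.numeric(node_eccentricity(C, weighted_eccentricity)),
    clustering = as.numeric(node_clustering(C)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# least-squares fit of y = a + b log2(x); x must be positive
fit_log_curve <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop(sprintf("fewer than 3 valid pairs (%d) for the log-curve fit",
                 length(x)), call. = FALSE)
  }
  lx <- log2(x)
  if (stats::sd(lx) == 0) {
    a <- mean(y); b <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, lx), y)
    a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  }
  res <- y - (a + b * lx)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  # a constant response carries no information about a varying predictor
  # (R^2 = 0); if both are constant the log relation is exact (R^2 = 1)
  r2 <- if (ss_tot <= 1e-24) {
    if (stats::sd(lx) == 0 && ss_res <= 1e-12) 1 else 0
  } else 1 - ss_res / ss_tot
  list(a = a, b = b, r_squared = min(max(r2, 0), 1), n = length(x))
}

#' Log-curve fits between local and reference measures
#'
#' For each requested (local measure, reference measure) pair, fits the
#' logarithmic curve `f(x) = a + b log2(x)` of the local measure against the
#' reference measure by least squares and reports the coefficients and the
#' determination coefficient R-squared. Not-applicable entries and
#' nonpositive reference values (where `log2` is undefined) are dropped
#' pairwise; fewer than 3 remaining pairs is an error.
#'
#' @param local per-node local-measure table from [local_measures()] (or a
#'   [random_walk_model()], from which it is computed).
#' @param ref per-node reference table from [reference_measures()]; computed
#'   from the model when omitted and `local` is a model.
#' @param measures local columns to fit (default `E`, `I1`, `I2`, `I1e`).
#' @param against reference columns to fit against (default `strength`,
#'   `eccentricity`, `clustering`).
#' @return a data frame with one row per pair: `local`, `reference`, `a`,
#'   `b`, `r_squared`, `n` (pairs used).
#' @examples
#' C <- generate_network("small_world", n = 32, m = 150, seed = 1)
#' fit <- random_walk_model(C)
#' correlate_measures(fit)
#' @export
correlate_measures <- function(local, ref = NULL,
                               measures = c("E", "I1", "I2", "I1e"),
                               against = c("strength", "eccentricity",
                                           "clustering")) {
  if (inherits(local, "random_walk_model")) {
    if (is.null(ref)) ref <- reference_measures(local$C)
    local <- local_measures(local)
  }
  if (is.null(ref)) stop("a reference_measures table is required",
                         call. = FALSE)
  if (nrow(local) != nrow(ref)) {
    stop("local and reference tables must cover the same node set",
         call. = FALSE)
  }
  rows <- lapply(measures, function(mname) {
    lapply(against, function(rname) {
      f <- fit_log_curve(ref[[rname]], local[[mname]])
      data.frame(local = mname, reference = rname, a = f$a, b = f$b,
                 r_squared = f$r_squared, n = f$n,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  row.names(out) <- NULL
  out
}
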