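#' Validate or coerce a connectivity matrix
#'
#' A connectivity matrix is the weighted adjacency matrix of an undirected
#' brain graph: square, symmetric, nonnegative, with a zero diagonal (the
#' diagonal is always dropped, mirroring the usual treatment of connectome
#' matrices where self-connections are meaningless).
#'
#' @param M numeric square matrix of connection weights.
#' @param labels optional character vector of node labels; defaults to
#'   existing row names or `"1"..."n"`.
#' @param symmetrize if `TRUE`, entries above the diagonal are copied below it
#'   (see [symmetrize()]); if `FALSE` an asymmetric input is an error.
#' @param clip_negative if `TRUE`, negative weights are set to zero (the usual
#'   treatment of thresholded functional correlation matrices); if `FALSE`
#'   they are an error.
#' @param tol absolute tolerance used when checking symmetry.
#' @return a numeric matrix of class `"connectivity"` with node labels as
#'   dimnames.
#' @examples
#' C <- as_connectivity(rbind(c(0, 1, 0, 1),
#'                            c(1, 0, 1, 0),
#'                            c(0, 1, 0, 1),
#'                            c(1, 0, 1, 0)))
#' @seealso [random_walk_model()], [read_connectivity()]
#' @export
as_connectivity <- function(M, labels = NULL, symmetrize = FALSE,
                            clip_negative = FALSE, tol = 1e-12) {
  if (inherits(M, "connectivity") && is.null(labels) && !symmetrize &&
      !clip_negative) {
    return(M)
  }
  M <- as.matrix(M)
  if (!is.numeric(M)) {
    stop("connectivity matrix must be numeric", call. = FALSE)
  }
  if (nrow(M) != ncol(M)) {
    stop(sprintf("connectivity matrix must be square (got %d x %d)",
                 nrow(M), ncol(M)), call. = FALSE)
  }
  first_cell <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]  # row-major order
  }
  if (anyNA(M)) {
    bad <- first_cell(is.na(M))
    stop(sprintf("missing value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(M < 0)) {
    if (clip_negative) {
      M[M < 0] <- 0
    } else {
      bad <- first_cell(M < 0)
      stop(sprintf(
        "negative weight %g at row %d, column %d (use clip_negative = TRUE to zero it)",
        M[bad[1L], bad[2L]], bad[1L], bad[2L]), call. = FALSE)
    }
  }
  if (symmetrize) {
    M <- symmetrize_matrix(M)
  } else {
    d <- abs(M - t(M))
    if (any(d > tol)) {
      bad <- first_cell(d > tol)
      stop(sprintf(
        "asymmetric input: C[%d,%d] = %g but C[%d,%d] = %g (use symmetrize = TRUE)",
        bad[1L], bad[2L], M[bad[1L], bad[2L]],
        bad[2L], bad[1L], M[bad[2L], bad[1L]]), call. = FALSE)
    }
    diag(M) <- 0
  }
  n <- nrow(M)
  if (is.null(labels)) {
    labels <- rownames(M)
    if (is.null(labels)) labels <- as.character(seq_len(n))
  }
  if (length(labels) != n) {
    stop("length of labels must match the number of nodes", call. = FALSE)
  }
  dimnames(M) <- list(labels, labels)
  class(M) <- c("connectivity", "matrix", "array")
  M
}

# upper triangle wins, diagonal zeroed
symmetrize_matrix <- function(M) {
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 0
  M
}

#' Symmetrize a square weight matrix
#'
#' Copies the entries above the diagonal below it and zeroes the diagonal,
#' the standard conversion of a directed weight matrix into an undirected
#' connectivity matrix.
#'
#' @param M nonnegative square numeric matrix.
#' @inheritParams as_connectivity
#' @return a `"connectivity"` matrix with `C[i,j] = C[j,i] = M[i,j]` for
#'   `i < j` and a zero diagonal.
#' @export
symmetrize <- function(M, labels = NULL) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) {
    stop(sprintf("cannot symmetrize a non-square matrix (%d x %d)",
                 nrow(M), ncol(M)), call. = FALSE)
  }
  as_connectivity(M, labels = labels, symmetrize = TRUE)
}

#' @export
print.connectivity <- function(x, ...) {
  n <- nrow(x)
  m <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("Connectivity matrix: %d nodes, %d undirected edges (density %.4f)\n",
              n, m, edge_density(n, m)))
  print(unclass(x), ...)
  invisible(x)
}

edge_density <- function(n, m) {
  if (n < 2) return(0)
  2 * m / (n * (n - 1))
}

n_edges <- function(C) sum(C[upper.tri(C)] > 0)
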