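# All measures use base-2 logarithms and are reported in bits, with the
# 0 log 0 = 0 convention applied by skipping zero-probability terms.

xlog2x <- function(p) {
  out <- p
  out[] <- 0
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

# clamp tiny negative results of cancellation; larger ones are a genuine bug
clamp0 <- function(x, what, tol = 1e-9) {
  if (x < 0) {
    if (x < -tol) {
      stop(sprintf("internal consistency error: %s = %g < 0", what, x),
           call. = FALSE)
    }
    x <- 0
  }
  x
}

#' Stationary entropy of the random walk
#'
#' Shannon entropy `H(mu) = -sum_i mu_i log2 mu_i` of the stationary
#' distribution, in bits. High when all nodes carry similar total weight,
#' at most `log2(n)`, lower when connectivity is concentrated on few nodes.
#'
#' @param model a [random_walk_model()] fit.
#' @return entropy in bits.
#' @export
stationary_entropy <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  clamp0(-sum(xlog2x(model$mu)), "H")
}

# entropy rate h = H(Xt+1 | Xt) of the stationary chain
entropy_rate <- function(model) {
  clamp0(-sum(model$mu * rowSums(xlog2x(model$P))), "H(Xt+1|Xt)")
}

#' Mutual information between consecutive walk states
#'
#' `I(Xt; Xt+1) = sum_i mu_i sum_j P_ij log2(P_ij / mu_j)`, in bits: the
#' information the present node carries about the next one. It equals the
#' stationary entropy minus the entropy rate `H(Xt+1|Xt)` and, for a
#' stationary Markov chain, coincides with the excess entropy, so it can be
#' read as a measure of network structure.
#'
#' @param model a [random_walk_model()] fit.
#' @return mutual information in bits.
#' @export
mutual_information <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  P <- model$P
  mu <- model$mu
  nz <- which(P > 0)
  muj <- mu[col(P)[nz]]
  mui <- mu[row(P)[nz]]
  clamp0(sum(mui * P[nz] * log2(P[nz] / muj)), "MI")
}

#' Erasure mutual information of the random walk
#'
#' `I-(X) = I(Xt; (Xt-1, Xt+1)) = H(mu) - H(Xt | Xt-1, Xt+1)`, in bits: the
#' reduction in uncertainty about the present node when both the previous and
#' the next node of the walk are known. High values indicate predictable,
#' unique paths; it always satisfies `MI <= EMI <= H`.
#'
#' The conditional entropy is evaluated through the reversible-chain identity
#' `H(Xt | Xt-1, Xt+1) = 2 H(Xt+1|Xt) - H(Xt+1|Xt-1)`, where the two-step
#' conditional entropy uses `Q = P %*% P`; this avoids forming the
#' `n^3` joint over (past, present, future) while being exactly equivalent to
#' it for the stationary chain.
#'
#' @param model a [random_walk_model()] fit.
#' @return erasure mutual information in bits.
#' @export
erasure_mutual_information <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  stationary_entropy(model) - context_conditional_entropy(model)
}

# H(Xt | Xt-1, Xt+1) = 2 h - H(Xt+1 | Xt-1), with Q = P^2 the two-step chain
context_conditional_entropy <- function(model) {
  h <- entropy_rate(model)
  Q <- model$P %*% model$P
  h2 <- clamp0(-sum(model$mu * rowSums(xlog2x(Q))), "H(Xt+1|Xt-1)")
  clamp0(2 * h - h2, "H(Xt|Xt-1,Xt+1)")
}

#' All global measures of a random-walk connectome model
#'
#' @param model a [random_walk_model()] fit.
#' @return an object of class `"global_measures"`: a list with entries `H`
#'   (stationary entropy), `MI` (mutual information between consecutive
#'   states), `EMI` (erasure mutual information), `H_cond_past`
#'   (`H(Xt+1|Xt)`, the entropy rate) and `H_cond_context`
#'   (`H(Xt|Xt-1,Xt+1)`), all in bits, plus `n`, `m` and `density` metadata.
#' @examples
#' cyc <- as_connectivity(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
#'                              c(0, 1, 0, 1), c(1, 0, 1, 0)))
#' global_measures(random_walk_model(cyc))
#' @export
global_measures <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  H <- stationary_entropy(model)
  h <- entropy_rate(model)
  hcc <- context_conditional_entropy(model)
  structure(list(
    H = H,
    MI = clamp0(H - h, "MI"),
    EMI = clamp0(H - hcc, "EMI"),
    H_cond_past = h,
    H_cond_context = hcc,
    n = model$n, m = model$m, density = model$density,
    units = "bits"
  ), class = "global_measures")
}

#' @export
print.global_measures <- function(x, digits = 4, ...) {
  cat("Global random-walk measures (bits):\n")
  cat(sprintf("  H (stationary entropy)        %.*f\n", digits, x$H))
  cat(sprintf("  MI (consecutive states)       %.*f\n", digits, x$MI))
  cat(sprintf("  EMI (past & future context)   %.*f\n", digits, x$EMI))
  cat(sprintf("  H(Xt+1|Xt)                    %.*f\n", digits, x$H_cond_past))
  cat(sprintf("  H(Xt|Xt-1,Xt+1)               %.*f\n", digits, x$H_cond_context))
  invisible(x)
}

#' @export
as.data.frame.global_measures <- function(x, ...) {
  data.frame(H = x$H, MI = x$MI, EMI = x$EMI,
             H_cond_past = x$H_cond_past,
             H_cond_context = x$H_cond_context)
}
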