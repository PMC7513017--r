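# Brute-force oracle: materialises the full joint distributions of the
# stationary walk over (present, next) pairs and (past, present, future)
# triples and evaluates every measure directly from the definitions of
# entropy, conditional entropy and Kullback-Leibler divergence. Only
# feasible for small n; kept deliberately independent of the package's
# algebraic shortcuts.

oracle_measures <- function(C) {
  C <- unname(unclass(C))
  n <- nrow(C)
  s <- rowSums(C)
  CT <- sum(C)
  mu <- s / CT
  P <- C / ifelse(s > 0, s, 1)

  plog <- function(p) if (p > 0) p * log2(p) else 0

  H <- -sum(vapply(mu, plog, 0))

  # joint over consecutive states
  J <- outer(mu, rep(1, n)) * P
  MI <- 0
  h <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (J[i, j] > 0) {
        MI <- MI + J[i, j] * log2(J[i, j] / (mu[i] * mu[j]))
        h <- h - J[i, j] * log2(P[i, j])
      }
    }
  }

  # triple joint p(past = j, present = i, future = k)
  Tr <- array(0, c(n, n, n))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        Tr[j, i, k] <- mu[j] * P[j, i] * P[i, k]
      }
    }
  }
  pjk <- apply(Tr, c(1, 3), sum)   # marginal over the present state
  Hcc <- 0
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        if (Tr[j, i, k] > 0) {
          Hcc <- Hcc - Tr[j, i, k] * log2(Tr[j, i, k] / pjk[j, k])
        }
      }
    }
  }
  EMI <- H - Hcc

  # local measures, from the same joints
  E <- ifelse(mu > 0, -log2(ifelse(mu > 0, mu, 1)), NA_real_)
  I1 <- I2 <- I1e <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (mu[i] == 0) next
    acc1 <- 0; rowH <- 0
    for (j in seq_len(n)) {
      if (P[i, j] > 0) {
        acc1 <- acc1 + P[i, j] * log2(P[i, j] / mu[j])
        rowH <- rowH - P[i, j] * log2(P[i, j])
      }
    }
    I1[i] <- acc1
    I2[i] <- H - rowH
    acc <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        cond <- Tr[j, i, k] / mu[i]   # p(j, k | present = i)
        if (cond > 0) acc <- acc + cond * log2(cond / pjk[j, k])
      }
    }
    I1e[i] <- acc
  }

  list(H = H, MI = MI, EMI = EMI, H_cond_past = h, H_cond_context = Hcc,
       mu = mu, E = E, I1 = I1, I2 = I2, I1e = I1e)
}
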