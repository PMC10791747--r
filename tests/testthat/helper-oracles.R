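# Independent brute-force oracles, deliberately written with plain loops and
# no code shared with the package internals.

# Loop-based evaluator of the 3-guild growth equations, species by species.
naive_rhs <- function(state, mats, params) {
  P <- state$P; M <- state$M; H <- state$H
  S_P <- length(P); S_M <- length(M); S_H <- length(H)
  dP <- numeric(S_P); dM <- numeric(S_M); dH <- numeric(S_H)
  for (i in seq_len(S_P)) {
    comp <- 0
    for (j in seq_len(S_P)) comp <- comp + mats$beta_P[i, j] * P[j]
    mut_set <- which(mats$Theta_MP[, i] == 1)     # pollinators of plant i
    denom_i <- 1 + params$h * sum(M[mut_set])
    gain <- 0
    for (j in seq_len(S_M)) gain <- gain + mats$gamma[i, j] * M[j] / denom_i
    loss <- 0
    for (j in seq_len(S_H)) {
      plant_set_j <- which(mats$Theta_HP[j, ] == 1) # plants of herbivore j
      denom_j <- 1 + params$h * sum(P[plant_set_j])
      loss <- loss + mats$tau[i, j] * H[j] / denom_j
    }
    dP[i] <- P[i] * (params$r_P - comp + gain - loss)
  }
  for (i in seq_len(S_M)) {
    comp <- 0
    for (j in seq_len(S_M)) comp <- comp + mats$beta_M[i, j] * M[j]
    plant_set <- which(mats$Theta_MP[i, ] == 1)
    denom <- 1 + params$h * sum(P[plant_set])
    gain <- 0
    for (j in seq_len(S_P)) gain <- gain + mats$gamma[j, i] * P[j] / denom
    dM[i] <- M[i] * (params$r_M - comp + gain)
  }
  for (i in seq_len(S_H)) {
    comp <- 0
    for (j in seq_len(S_H)) comp <- comp + mats$beta_H[i, j] * H[j]
    plant_set <- which(mats$Theta_HP[i, ] == 1)
    denom <- 1 + params$h * sum(P[plant_set])
    gain <- 0
    for (j in seq_len(S_P)) gain <- gain + params$eps * mats$tau[j, i] * P[j] / denom
    dH[i] <- H[i] * (params$r_H - comp + gain)
  }
  c(dP, dM, dH)
}

# Central finite-difference Jacobian with relative step.
fd_jacobian <- function(state, mats, params, step = 1e-6) {
  y0 <- c(state$P, state$M, state$H)
  n <- length(y0)
  f <- function(y) unname(rhs(triguild:::vector_state(y, mats), mats, params))
  J <- matrix(0, n, n)
  for (l in seq_len(n)) {
    hl <- step * max(1, abs(y0[l]))
    yp <- y0; yp[l] <- yp[l] + hl
    ym <- y0; ym[l] <- ym[l] - hl
    J[, l] <- (f(yp) - f(ym)) / (2 * hl)
  }
  J
}

# Pair-loop NODF, straight from the definition.
naive_nodf <- function(A) {
  n_r <- nrow(A); n_c <- ncol(A)
  k <- rowSums(A); d <- colSums(A)
  total <- 0
  for (i in seq_len(n_r - 1)) for (j in (i + 1):n_r) {
    hi <- if (k[i] >= k[j]) i else j
    lo <- if (k[i] >= k[j]) j else i
    if (k[hi] > k[lo] && k[lo] > 0)
      total <- total + sum(A[hi, ] == 1 & A[lo, ] == 1) / k[lo]
  }
  for (i in seq_len(n_c - 1)) for (j in (i + 1):n_c) {
    hi <- if (d[i] >= d[j]) i else j
    lo <- if (d[i] >= d[j]) j else i
    if (d[hi] > d[lo] && d[lo] > 0)
      total <- total + sum(A[, hi] == 1 & A[, lo] == 1) / d[lo]
  }
  100 * total / (n_r * (n_r - 1) / 2 + n_c * (n_c - 1) / 2)
}

# All set partitions of 1..n as label vectors (restricted growth strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return()
    }
    for (g in seq_len(k + 1L)) rec(c(labels, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

# Exact maximum Barber modularity: enumerate all partitions of the rows; for
# each, every column independently joins its best module (or none, since a
# module without rows contributes nothing).
exhaustive_modularity <- function(A, parts = set_partitions(nrow(A))) {
  m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  B <- A - outer(k, d) / m
  best <- -Inf
  for (lab in parts) {
    agg <- rowsum(B, lab)
    q <- sum(pmax(0, apply(agg, 2, max)))
    if (q > best) best <- q
  }
  best / m
}

# Spearman rank correlation from first principles (average ranks for ties).
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Small random community used across dynamics/rewiring tests.
make_test_net <- function(S = 6, seed = 1, omega_c = 0.05, omega_m = 0.1,
                          omega_p = 0.1, C = 0.3, ...) {
  p <- model_params(omega_c = omega_c, omega_m = omega_m, omega_p = omega_p,
                    C_mut = C, C_ant = C, ...)
  generate_network(S, S, S, p, seed = seed)
}

random_state <- function(net, seed = 1) {
  withr::with_seed(seed, community_state(
    runif(net$community$S_P, 0.2, 1.5),
    runif(net$community$S_M, 0.2, 1.5),
    runif(net$community$S_H, 0.2, 1.5)))
}
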