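# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Spearman by explicit rank-then-Pearson (mid-ranks for ties).
oracle_spearman <- function(M) {
  R <- apply(M, 2, rank)
  stats::cor(R)
}

# O(n^2) dominance oracle for the Pareto front (maximise both objectives).
oracle_pareto_idx <- function(titre, od) {
  n <- length(titre)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- any(titre >= titre[i] & od >= od[i] & (titre > titre[i] | od > od[i]))
    keep[i] <- !dominated
  }
  idx <- which(keep)
  idx[!duplicated(cbind(titre, od)[idx, , drop = FALSE])]
}

# Gauss-Hermite nodes/weights by Golub-Welsch (for the q = 2 qNEI oracle).
oracle_gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1)) {
    J[k, k + 1] <- sqrt(k / 2)
    J[k + 1, k] <- sqrt(k / 2)
  }
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# E[max(0, max(X1, X2) - t)] for X ~ N(mu, S) by dense 2-D Gauss-Hermite.
oracle_batch_ei_2d <- function(mu, S, t0, n_nodes = 80) {
  L <- t(chol(S))
  q <- oracle_gauss_hermite(n_nodes)
  tot <- 0
  for (i in seq_along(q$x)) {
    for (j in seq_along(q$x)) {
      x <- mu + drop(L %*% (sqrt(2) * c(q$x[i], q$x[j])))
      tot <- tot + q$w[i] * q$w[j] / pi * max(0, max(x) - t0)
    }
  }
  tot
}

# Quartiles by explicit linear interpolation between order statistics.
oracle_iqr_mask <- function(v, k = 1.5) {
  qlin <- function(p) {
    s <- sort(v)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  med <- qlin(0.5)
  iqr <- qlin(0.75) - qlin(0.25)
  v >= med - k * iqr & v <= med + k * iqr
}

# Uniform seeded sample of compositions over a design space.
sample_compositions <- function(n, seed, space = design_space()) {
  U <- withr::with_seed(seed, matrix(stats::runif(2 * n), ncol = 2))
  X <- cbind(space$lo[1] + U[, 1] * (space$hi[1] - space$lo[1]),
             space$lo[2] + U[, 2] * (space$hi[2] - space$lo[2]))
  colnames(X) <- c("glucose_pct", "nh4cl_mM")
  X
}

# Small fixed GP test scenario reused by surrogate/acquisition tests.
gp_test_scenario <- function() {
  X <- rbind(c(0.35, 20), c(1.05, 95), c(1.7, 40), c(0.7, 60), c(1.4, 110))
  colnames(X) <- c("glucose_pct", "nh4cl_mM")
  list(X = X,
       y = c(1.0, 1.4, 0.8, 2.2, 1.1),
       noise_var = c(0.01, 0.02, 0.005, 0.03, 0.01),
       hyper = list(ls = c(0.3, 0.5), sf2 = 1.3, sn2 = 1e-4))
}
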