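# Batch candidate proposal: analytic expected improvement (validation
# oracle), Monte-Carlo q-noisy expected improvement, and greedy-sequential
# batch construction over seeded space-filling candidate pools.

#' Acquisition configuration
#'
#' @param q batch size (default 7, one plate's worth of combinations).
#' @param mc_samples Monte-Carlo sample count for qNEI.
#' @param xi exploration offset added to the incumbent (the acquisition's
#'   "eta"-type exploration/exploitation balance; default 0.01).
#' @param pool_size candidate-pool size per greedy step.
#' @param seed integer seed for pools and posterior draws.
#' @param min_sep minimum pairwise separation between batch members, on the
#'   unit-square scale (default 0.18, about a fifth of each axis range).
#'   Greedy qNEI batches otherwise collapse onto the current optimum;
#'   enforcing well-separated batch members keeps the plate's seven
#'   combinations experimentally distinguishable and preserves the
#'   exploration that drives the iteration-on-iteration uncertainty decrease.
#' @param incumbent `"posterior_mean"` (max posterior mean at observed
#'   points; the standard noisy-incumbent choice) or `"max_y"`.
#' @return object of class `acq_config`.
#' @export
acq_config <- function(q = 7, mc_samples = 4096, xi = 0.01, pool_size = 2048,
                       seed = 1, min_sep = 0.18,
                       incumbent = c("posterior_mean", "max_y")) {
  stopifnot(q >= 1, mc_samples >= 1, xi >= 0, pool_size >= 1, min_sep >= 0)
  structure(list(q = as.integer(q), mc_samples = as.integer(mc_samples),
                 xi = xi, pool_size = as.integer(pool_size),
                 seed = as.integer(seed), min_sep = min_sep,
                 incumbent = match.arg(incumbent)),
            class = "acq_config")
}

#' Analytic expected improvement
#'
#' `EI = (mu - f* - xi) Phi(z) + sigma phi(z)`, `z = (mu - f* - xi)/sigma`;
#' for `sigma = 0` it degenerates to `max(0, mu - f* - xi)`. Used as the
#' independent oracle for the Monte-Carlo qNEI estimator at `q = 1`.
#'
#' @param mean posterior mean(s).
#' @param sd posterior standard deviation(s), `>= 0`.
#' @param incumbent current best value `f*`.
#' @param xi exploration offset.
#' @return expected improvement (vectorised).
#' @export
analytic_ei <- function(mean, sd, incumbent, xi = 0) {
  stopifnot(all(sd >= 0))
  delta <- mean - incumbent - xi
  out <- pmax(delta, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- delta[pos] / sd[pos]
    out[pos] <- delta[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  out
}

# Incumbent value (original scale) under the configured convention.
acq_incumbent <- function(model, cfg) {
  ds <- model$dataset
  if (ds$n == 0) return(-Inf)
  if (cfg$incumbent == "max_y") return(max(ds$y))
  max(stats::predict(model, ds$X, se = FALSE)$mean)
}

# Draw joint posterior samples of the latent function at the observed and
# extra points, on the ORIGINAL titre scale. In low joint dimension,
# randomised-shift Halton quasi-Monte-Carlo normal draws are used (the
# standard variance-reduction choice for batch expected-improvement
# estimators); in high dimension (large candidate pools) antithetic
# pseudo-Monte-Carlo pairs are used instead. Returns mc x npts matrix.
qnei_samples <- function(model, U_extra, mc, seed, qmc_max_dim = 12) {
  ds <- model$dataset
  U_all <- rbind(ds$U, U_extra)
  d <- nrow(U_all)
  post <- gp_joint_posterior(model, U_all)
  R <- chol_safe(post$cov + diag(1e-10, d))
  if (d <= qmc_max_dim) {
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
    shifts <- with_seed_(seed, stats::runif(d))
    Z <- vapply(seq_len(d), function(j) {
      stats::qnorm(pmin(pmax(halton_seq(mc, primes[j], shifts[j]), 1e-12), 1 - 1e-12))
    }, numeric(mc))
    Z <- matrix(Z, nrow = mc)
  } else {
    mh <- ceiling(mc / 2)
    Zh <- with_seed_(seed, matrix(stats::rnorm(mh * d), nrow = mh))
    Z <- rbind(Zh, -Zh)[seq_len(mc), , drop = FALSE]
  }
  S_z <- sweep(Z %*% R, 2, post$mean, "+")
  ds$y_mu + ds$y_sd * S_z
}

# Core improvement computation shared by qnei() and the nested-set
# monotonicity property: given per-sample values at observed points and at
# candidate points, the qNEI estimate for any candidate subset.
qnei_from_samples <- function(S_obs, S_cand, incumbent, xi) {
  obs_best <- if (ncol(S_obs) > 0) {
    pmax(apply(S_obs, 1, max), incumbent)
  } else rep(incumbent, nrow(S_cand))
  cand_best <- apply(S_cand, 1, max)
  imp <- pmax(cand_best - (obs_best + xi), 0)
  list(value = mean(imp), se = mc_se(imp))
}

# MC standard error honouring the antithetic pair layout (rows i and
# i + mc/2 share the same underlying normal draw).
mc_se <- function(imp) {
  n <- length(imp)
  if (n >= 4 && n %% 2 == 0) {
    half <- n / 2
    pm <- (imp[seq_len(half)] + imp[half + seq_len(half)]) / 2
    stats::sd(pm) / sqrt(half)
  } else {
    stats::sd(imp) / sqrt(n)
  }
}

#' Monte-Carlo q-noisy expected improvement
#'
#' Draws joint posterior samples of the latent function at the union of the
#' observed and candidate points; per sample, the improvement is
#' `max(0, max over candidates - (max over observed + xi))`; the acquisition
#' value is the sample mean. With no observations the incumbent falls back
#' to `-Inf` offsets, i.e. a pure-prior expected maximum, unless an explicit
#' `incumbent` is supplied.
#'
#' @param model a fitted `gp_model` (or [gp_prior_model()]).
#' @param candidates candidate compositions (q x 2).
#' @param cfg an [acq_config()].
#' @param incumbent optional explicit incumbent on the original titre scale.
#' @return list with `value` (qNEI estimate) and `se` (MC standard error).
#' @export
qnei <- function(model, candidates, cfg = acq_config(), incumbent = NULL) {
  Xc <- as_composition_matrix(candidates)
  ds <- model$dataset
  Uc <- to_unit(Xc, ds$space)
  S <- qnei_samples(model, Uc, cfg$mc_samples, cfg$seed)
  n_obs <- ds$n
  S_obs <- S[, seq_len(n_obs), drop = FALSE]
  S_cand <- S[, n_obs + seq_len(nrow(Uc)), drop = FALSE]
  inc <- incumbent %||% if (n_obs == 0) -Inf else acq_incumbent(model, cfg)
  if (n_obs == 0 && is.infinite(inc)) {
    # pure-prior case: expected batch maximum (no reference level)
    cand_best <- apply(S_cand, 1, max)
    return(list(value = mean(cand_best), se = mc_se(cand_best)))
  }
  qnei_from_samples(S_obs, S_cand, inc, cfg$xi)
}

#' Propose the next batch of media compositions
#'
#' Greedy-sequential qNEI maximisation: a seeded space-filling candidate
#' pool (Halton draws plus the current posterior-mean grid argmax) is scored
#' under shared joint posterior samples; at each of `q` steps the candidate
#' maximising the batch qNEI given the already-selected (pending) points is
#' added, subject to a minimum pairwise separation.
#'
#' @param model a fitted `gp_model`.
#' @param space the [design_space()].
#' @param cfg an [acq_config()].
#' @param grid_res resolution of the grid used to locate the posterior-mean
#'   argmax added to the pool.
#' @return an `acq_batch`: data.frame of `q` compositions with the batch
#'   acquisition value and its MC standard error as attributes.
#' @export
propose_batch <- function(model, space = design_space(), cfg = acq_config(),
                          grid_res = 61) {
  ds <- model$dataset
  U_pool <- halton_pool(cfg$pool_size, derive_seed(cfg$seed, 1))
  grid <- make_grid(space, grid_res)
  gmean <- stats::predict(model, grid, se = FALSE)$mean
  U_best <- to_unit(grid[which.max(gmean), , drop = FALSE], space)
  U_pool <- rbind(U_pool, as.matrix(U_best))
  npool <- nrow(U_pool)
  S <- qnei_samples(model, U_pool, cfg$mc_samples, derive_seed(cfg$seed, 2))
  S_obs <- S[, seq_len(ds$n), drop = FALSE]
  S_pool <- S[, ds$n + seq_len(npool), drop = FALSE]
  inc <- acq_incumbent(model, cfg)
  ref <- if (ds$n > 0) pmax(apply(S_obs, 1, max), inc) + cfg$xi else rep(cfg$xi, nrow(S_pool))
  pend_best <- rep(-Inf, nrow(S_pool))
  chosen <- integer(0)
  available <- rep(TRUE, npool)
  for (step in seq_len(cfg$q)) {
    if (!any(available)) {
      stop(sprintf("candidate pool exhausted at batch member %d under min_sep = %g; reduce q or min_sep",
                   step, cfg$min_sep))
    }
    M <- pmax(S_pool, pend_best)
    V <- M - ref
    V[V < 0] <- 0
    scores <- colMeans(V)
    scores[!available] <- -Inf
    pick <- which.max(scores)
    chosen <- c(chosen, pick)
    pend_best <- pmax(pend_best, S_pool[, pick])
    d2 <- (U_pool[, 1] - U_pool[pick, 1])^2 + (U_pool[, 2] - U_pool[pick, 2])^2
    available <- available & d2 > cfg$min_sep^2
  }
  batch <- as.data.frame(from_unit(U_pool[chosen, , drop = FALSE], space))
  final <- mean(pmax(pend_best - ref, 0))
  imp <- pmax(pend_best - ref, 0)
  structure(batch, class = c("acq_batch", "data.frame"),
            acq_value = final, acq_se = mc_se(imp),
            incumbent = inc)
}

#' @rdname propose_batch
#' @param batch an `acq_batch`.
#' @param path file path.
#' @param iteration iteration label stored in the CSV.
#' @export
write_batch_csv <- function(batch, path, iteration = NA) {
  df <- data.frame(iteration = iteration,
                   candidate_index = seq_len(nrow(batch)),
                   glucose_pct = batch$glucose_pct, nh4cl_mM = batch$nh4cl_mM,
                   acq_value = attr(batch, "acq_value"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
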