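# Heteroskedastic Gaussian-process surrogate: Matern-5/2 kernel with
# per-axis lengthscales, fixed per-point observation-noise variances
# (replicate SEM^2), exact inference and analytic marginal-likelihood
# gradients for multi-start hyperparameter optimisation.

#' Assemble a GP training dataset
#'
#' Inputs are mapped to the unit square and outputs z-scored; both
#' transforms are stored so predictions are returned on the original
#' relative-titre scale. Per-point noise variances (replicate SEM^2 on the
#' original scale) carry the heteroskedasticity.
#'
#' @param X compositions (n x 2 matrix/data.frame, glucose_pct / nh4cl_mM).
#' @param y observed relative titres (replicate means), length n.
#' @param noise_var per-point observation-noise variances (scalar or length
#'   n); use replicate SEM^2.
#' @param space the [design_space()] used for input scaling.
#' @return object of class `gp_dataset`.
#' @export
gp_dataset <- function(X, y, noise_var = 0, space = design_space()) {
  X <- as_composition_matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)) || n == 0)
  if (length(noise_var) == 1L) noise_var <- rep(noise_var, n)
  stopifnot(length(noise_var) == n, all(noise_var >= 0))
  y_mu <- if (n > 0) mean(y) else 0
  y_sd <- if (n > 1) stats::sd(y) else 1
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  structure(list(X = X, U = to_unit(X, space), y = as.numeric(y),
                 yz = (as.numeric(y) - y_mu) / y_sd,
                 noise_var = as.numeric(noise_var),
                 noise_var_z = as.numeric(noise_var) / y_sd^2,
                 y_mu = y_mu, y_sd = y_sd, space = space, n = n),
            class = "gp_dataset")
}

# Matern-5/2 cross-covariance between scaled inputs (rows).
matern52 <- function(U1, U2, ls, sf2) {
  a1 <- sweep(U1, 2, ls, "/")
  a2 <- sweep(U2, 2, ls, "/")
  d2 <- outer(rowSums(a1^2), rowSums(a2^2), "+") - 2 * tcrossprod(a1, a2)
  d2[d2 < 0] <- 0
  t <- sqrt(5 * d2)
  sf2 * (1 + t + t^2 / 3) * exp(-t)
}

# Kernel derivative helpers used by the analytic LML gradient:
# dK/dlog(ls_a) = sf2 * (5/3) * (1 + t) * exp(-t) * (delta_a/ls_a)^2.
matern52_grad_ls <- function(U1, U2, ls, sf2, axis) {
  a1 <- sweep(U1, 2, ls, "/")
  a2 <- sweep(U2, 2, ls, "/")
  d2 <- outer(rowSums(a1^2), rowSums(a2^2), "+") - 2 * tcrossprod(a1, a2)
  d2[d2 < 0] <- 0
  t <- sqrt(5 * d2)
  da <- outer(U1[, axis] / ls[axis], U2[, axis] / ls[axis], "-")^2
  sf2 * (5 / 3) * (1 + t) * exp(-t) * da
}

#' GP fitting configuration
#'
#' @param n_restarts multi-start count for hyperparameter optimisation.
#' @param seed integer seed for restart initialisation.
#' @param ls_bounds lengthscale bounds on the unit-square scale.
#' @param var_bounds bounds for the signal variance and jitter variance.
#' @param fixed optional named list `list(ls=, sf2=, sn2=)`; when given,
#'   hyperparameters are fixed and no optimisation is run.
#' @param prior `"weak"` (default) places weak log-normal priors on the log
#'   hyperparameters and fits by MAP, mirroring the regularised defaults of
#'   standard Bayesian-optimisation frameworks; without them, maximum
#'   marginal likelihood on a handful of early-iteration points routinely
#'   selects a boundary lengthscale and becomes degenerately overconfident.
#'   `"none"` fits by pure maximum marginal likelihood.
#' @param prior_mean,prior_sd location/scale of the log-normal priors on
#'   `(ls1, ls2, sf2, sn2)` (log scale; defaults centre lengthscales at 0.3
#'   of the unit square and the signal variance at the z-scored unit).
#' @return object of class `gp_fit_config`.
#' @export
gp_fit_config <- function(n_restarts = 8, seed = 1,
                          ls_bounds = c(0.05, 5), var_bounds = c(1e-6, 10),
                          fixed = NULL, prior = c("weak", "none"),
                          prior_mean = log(c(0.3, 0.3, 1, 1e-4)),
                          prior_sd = c(0.8, 0.8, 0.8, 2)) {
  structure(list(n_restarts = n_restarts, seed = seed,
                 ls_bounds = ls_bounds, var_bounds = var_bounds, fixed = fixed,
                 prior = match.arg(prior),
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "gp_fit_config")
}

# theta = c(log ls1, log ls2, log sf2, log sn2)
gp_build_K <- function(dataset, theta) {
  ls <- exp(theta[1:2]); sf2 <- exp(theta[3]); sn2 <- exp(theta[4])
  K <- matern52(dataset$U, dataset$U, ls, sf2)
  diag(K) <- diag(K) + dataset$noise_var_z + sn2
  K
}

# Cholesky with jitter escalation; returns upper-triangular R (K = R'R).
chol_safe <- function(K, max_tries = 7) {
  jit <- 0
  for (i in seq_len(max_tries)) {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) {
      attr(R, "jitter") <- jit
      return(R)
    }
    jit <- if (jit == 0) 1e-10 else jit * 10
  }
  stop("covariance matrix not positive definite after jitter escalation")
}

# Negative log marginal likelihood and its analytic gradient in theta.
gp_nlml <- function(theta, dataset, grad = FALSE) {
  n <- dataset$n
  K <- gp_build_K(dataset, theta)
  R <- chol_safe(K)
  alpha <- backsolve(R, backsolve(R, dataset$yz, transpose = TRUE))
  nll <- 0.5 * sum(dataset$yz * alpha) + sum(log(diag(R))) + 0.5 * n * log(2 * pi)
  if (!grad) return(nll)
  Kinv <- chol2inv(R)
  W <- tcrossprod(alpha) - Kinv # d(LML)/dK = W/2
  ls <- exp(theta[1:2]); sf2 <- exp(theta[3]); sn2 <- exp(theta[4])
  g <- numeric(4)
  for (a in 1:2) {
    dK <- matern52_grad_ls(dataset$U, dataset$U, ls, sf2, a)
    g[a] <- -0.5 * sum(W * dK)
  }
  dK_sf <- matern52(dataset$U, dataset$U, ls, sf2) # = K_f = dK/dlog sf2
  g[3] <- -0.5 * sum(W * dK_sf)
  g[4] <- -0.5 * sum(diag(W)) * sn2
  attr(nll, "gradient") <- g
  nll
}

#' Log marginal likelihood of a GP model or dataset
#'
#' `-1/2 y'K^-1 y - 1/2 log|K| - n/2 log(2 pi)` on the z-scored scale, with
#' `K = K_f + diag(noise_var) + sn2 I`.
#'
#' @param object a fitted `gp_model`, or a `gp_dataset`.
#' @param hyper when `object` is a dataset: named list `list(ls=, sf2=, sn2=)`.
#' @param gradient also return the analytic gradient with respect to the log
#'   hyperparameters (attribute `"gradient"`).
#' @return the log marginal likelihood (numeric scalar).
#' @export
log_marginal_likelihood <- function(object, hyper = NULL, gradient = FALSE) {
  if (inherits(object, "gp_model")) {
    dataset <- object$dataset
    hyper <- object$hyper
  } else dataset <- object
  stopifnot(inherits(dataset, "gp_dataset"), !is.null(hyper))
  theta <- log(c(hyper$ls[1], hyper$ls[2], hyper$sf2, hyper$sn2))
  nll <- gp_nlml(theta, dataset, grad = gradient)
  out <- -as.numeric(nll)
  if (gradient) attr(out, "gradient") <- -attr(nll, "gradient")
  out
}

#' Fit the heteroskedastic GP surrogate
#'
#' Maximises the log marginal likelihood over per-axis Matern-5/2
#' lengthscales, signal variance and a homoscedastic jitter variance, by
#' bounded multi-start L-BFGS-B with analytic gradients. Per-point noise
#' variances from the dataset are held fixed (they encode the replicate
#' SEM^2 heteroskedasticity).
#'
#' @param dataset a [gp_dataset()].
#' @param cfg a [gp_fit_config()].
#' @return object of class `gp_model`.
#' @export
fit_gp <- function(dataset, cfg = gp_fit_config()) {
  stopifnot(inherits(dataset, "gp_dataset"))
  if (!is.null(cfg$fixed)) {
    hyper <- cfg$fixed
  } else if (dataset$n < 2) {
    hyper <- list(ls = c(0.3, 0.3), sf2 = 1, sn2 = 1e-6)
  } else {
    lb <- c(log(cfg$ls_bounds[1]), log(cfg$ls_bounds[1]),
            log(cfg$var_bounds[1]), log(cfg$var_bounds[1]))
    ub <- c(log(cfg$ls_bounds[2]), log(cfg$ls_bounds[2]),
            log(cfg$var_bounds[2]), log(cfg$var_bounds[2]))
    starts <- list(log(c(0.3, 0.3, 1, 1e-4)))
    if (cfg$n_restarts > 1) {
      rnd <- with_seed_(cfg$seed, matrix(stats::runif((cfg$n_restarts - 1) * 4), ncol = 4))
      for (i in seq_len(nrow(rnd))) starts[[i + 1]] <- lb + rnd[i, ] * (ub - lb)
    }
    use_prior <- identical(cfg$prior, "weak")
    obj <- function(th) {
      v <- gp_nlml(th, dataset)
      if (use_prior) v <- v + sum((th - cfg$prior_mean)^2 / (2 * cfg$prior_sd^2))
      v
    }
    obj_gr <- function(th) {
      g <- attr(gp_nlml(th, dataset, grad = TRUE), "gradient")
      if (use_prior) g <- g + (th - cfg$prior_mean) / cfg$prior_sd^2
      g
    }
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, fn = obj, gr = obj_gr,
                     method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("GP hyperparameter optimisation failed from all starts")
    th <- best$par
    hyper <- list(ls = exp(th[1:2]), sf2 = exp(th[3]), sn2 = exp(th[4]))
  }
  K <- if (dataset$n > 0) gp_build_K(dataset, log(c(hyper$ls, hyper$sf2, hyper$sn2))) else matrix(0, 0, 0)
  R <- if (dataset$n > 0) chol_safe(K) else NULL
  alpha <- if (dataset$n > 0) backsolve(R, backsolve(R, dataset$yz, transpose = TRUE)) else numeric(0)
  structure(list(dataset = dataset, hyper = hyper, R = R, alpha = alpha,
                 lml = if (dataset$n > 0) log_marginal_likelihood(dataset, hyper) else NA_real_),
            class = "gp_model")
}

#' A data-free GP prior model
#'
#' Useful for prior predictions and prior-only acquisition checks.
#'
#' @param hyper named list `list(ls=, sf2=, sn2=)`.
#' @param space a [design_space()].
#' @return a `gp_model` with an empty dataset.
#' @export
gp_prior_model <- function(hyper = list(ls = c(0.3, 0.3), sf2 = 1, sn2 = 1e-6),
                           space = design_space()) {
  ds <- gp_dataset(matrix(numeric(0), 0, 2,
                          dimnames = list(NULL, c("glucose_pct", "nh4cl_mM"))),
                   numeric(0), numeric(0), space)
  structure(list(dataset = ds, hyper = hyper, R = NULL, alpha = numeric(0),
                 lml = NA_real_), class = "gp_model")
}

#' Posterior prediction on the original titre scale
#'
#' Returns the posterior mean and, optionally, the standard deviation of
#' the latent mean (observation noise and jitter are excluded: the reported
#' uncertainty is that of the underlying titre surface, matching the
#' standard-error-of-the-mean convention of the uncertainty maps).
#'
#' @param object a fitted `gp_model`.
#' @param X query compositions.
#' @param se return posterior standard deviations.
#' @param ... unused.
#' @return list with `mean` and (if `se`) `sd`, both on the original scale.
#' @export
predict.gp_model <- function(object, X, se = TRUE, ...) {
  X <- as_composition_matrix(X)
  ds <- object$dataset
  U <- to_unit(X, ds$space)
  hy <- object$hyper
  if (ds$n == 0) {
    mean_z <- rep(0, nrow(U))
    var_z <- rep(hy$sf2, nrow(U))
  } else {
    Ks <- matern52(ds$U, U, hy$ls, hy$sf2)
    mean_z <- drop(crossprod(Ks, object$alpha))
    var_z <- NULL
    if (se) {
      v <- backsolve(object$R, Ks, transpose = TRUE)
      var_z <- pmax(hy$sf2 - colSums(v^2), 0)
    }
  }
  out <- list(mean = ds$y_mu + ds$y_sd * mean_z)
  if (se) out$sd <- ds$y_sd * sqrt(var_z)
  out
}

# Joint posterior of the latent function at query points (z-scored scale).
gp_joint_posterior <- function(model, U) {
  ds <- model$dataset
  hy <- model$hyper
  Kqq <- matern52(U, U, hy$ls, hy$sf2)
  if (ds$n == 0) return(list(mean = rep(0, nrow(U)), cov = Kqq))
  Ks <- matern52(ds$U, U, hy$ls, hy$sf2)
  v <- backsolve(model$R, Ks, transpose = TRUE)
  list(mean = drop(crossprod(Ks, model$alpha)), cov = Kqq - crossprod(v))
}

#' Serialise / restore a GP model as JSON
#'
#' Stores hyperparameters, the training data and the input/output
#' transforms; restoring rebuilds the Cholesky factors.
#'
#' @param model a `gp_model`.
#' @param path JSON file path.
#' @return `gp_from_json` returns the restored `gp_model`.
#' @export
gp_to_json <- function(model, path) {
  ds <- model$dataset
  obj <- list(hyper = model$hyper,
              X = unname(as.matrix(ds$X)), y = ds$y, noise_var = ds$noise_var,
              space = list(lo = unname(ds$space$lo), hi = unname(ds$space$hi)),
              fingerprint = sprintf("n=%d;sum=%.12g", ds$n, sum(ds$y)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gp_to_json
#' @export
gp_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- design_space(glucose = c(obj$space$lo[1], obj$space$hi[1]),
                        nh4cl = c(obj$space$lo[2], obj$space$hi[2]))
  X <- matrix(obj$X, ncol = 2)
  ds <- gp_dataset(X, obj$y, obj$noise_var, space)
  hyper <- list(ls = as.numeric(obj$hyper$ls), sf2 = obj$hyper$sf2, sn2 = obj$hyper$sn2)
  fit_gp(ds, gp_fit_config(fixed = hyper))
}
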