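test_that("posterior mean and sd match the closed-form Cholesky oracle", {
  sc <- gp_test_scenario()
  space <- design_space()
  m <- fit_gp(gp_dataset(sc$X, sc$y, sc$noise_var, space),
              gp_fit_config(fixed = sc$hyper))
  Xq <- sample_compositions(6, seed = 31)
  pr <- predict(m, Xq)
  # independent dense linear-algebra computation
  U <- mediaopt:::to_unit(sc$X, space)
  Uq <- mediaopt:::to_unit(Xq, space)
  hy <- sc$hyper
  mat <- function(A, B) {
    a <- sweep(A, 2, hy$ls, "/"); b <- sweep(B, 2, hy$ls, "/")
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    t_ <- sqrt(pmax(5 * d2, 0))
    hy$sf2 * (1 + t_ + t_^2 / 3) * exp(-t_)
  }
  ymu <- mean(sc$y); ysd <- stats::sd(sc$y)
  K <- mat(U, U) + diag(sc$noise_var / ysd^2 + hy$sn2)
  Ks <- mat(U, Uq)
  mu_o <- ymu + ysd * drop(t(Ks) %*% solve(K, (sc$y - ymu) / ysd))
  sd_o <- ysd * sqrt(diag(mat(Uq, Uq) - t(Ks) %*% solve(K, Ks)))
  expect_lt(max(abs(pr$mean - mu_o)), 1e-8)
  expect_lt(max(abs(pr$sd - sd_o)), 1e-8)
})

test_that("one-point log marginal likelihood matches the hand formula", {
  hy <- list(ls = c(0.3, 0.5), sf2 = 1.3, sn2 = 1e-4)
  nv <- 0.04
  ds <- gp_dataset(matrix(c(0.5, 50), 1), 1.7, nv, design_space())
  # n = 1: y_sd fixed at 1, z-scored observation is 0
  v <- hy$sf2 + nv + hy$sn2
  hand <- -0.5 * 0^2 / v - 0.5 * log(v) - 0.5 * log(2 * pi)
  expect_equal(log_marginal_likelihood(ds, hy), hand, tolerance = 1e-12)
})

test_that("well-separated points contribute independent likelihood terms", {
  hy <- list(ls = c(0.02, 0.02), sf2 = 0.8, sn2 = 1e-3)
  space <- design_space()
  X <- rbind(c(0.11, 6), c(1.99, 119)) # opposite corners, tiny lengthscale
  colnames(X) <- c("glucose_pct", "nh4cl_mM")
  y <- c(1.1, 2.3)
  nv <- c(0.02, 0.05)
  ds <- gp_dataset(X, y, nv, space)
  lml <- log_marginal_likelihood(ds, hy)
  yz <- (y - mean(y)) / stats::sd(y)
  v <- hy$sf2 + nv / stats::sd(y)^2 + hy$sn2
  indep <- sum(-0.5 * yz^2 / v - 0.5 * log(v) - 0.5 * log(2 * pi))
  expect_equal(lml, indep, tolerance = 1e-8)
})

test_that("analytic likelihood gradients match finite differences", {
  sc <- gp_test_scenario()
  ds <- gp_dataset(sc$X, sc$y, sc$noise_var, design_space())
  for (s in 1:3) {
    th <- withr::with_seed(s, c(log(stats::runif(2, 0.1, 1)),
                                log(stats::runif(1, 0.3, 2)),
                                log(stats::runif(1, 1e-4, 1e-2))))
    hy <- list(ls = exp(th[1:2]), sf2 = exp(th[3]), sn2 = exp(th[4]))
    g <- attr(log_marginal_likelihood(ds, hy, gradient = TRUE), "gradient")
    eps <- 1e-6
    fd <- sapply(1:4, function(i) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      hp <- list(ls = exp(tp[1:2]), sf2 = exp(tp[3]), sn2 = exp(tp[4]))
      hm <- list(ls = exp(tm[1:2]), sf2 = exp(tm[3]), sn2 = exp(tm[4]))
      (log_marginal_likelihood(ds, hp) - log_marginal_likelihood(ds, hm)) / (2 * eps)
    })
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("a single noiseless observation is interpolated", {
  ds <- gp_dataset(matrix(c(0.8, 50), 1), 2.4, 0, design_space())
  m <- fit_gp(ds)
  pr <- predict(m, matrix(c(0.8, 50), 1))
  expect_lt(abs(pr$mean - 2.4), 1e-6)
  expect_lt(pr$sd, 1e-3)
})

test_that("predictions revert to the prior far from all data", {
  hy <- list(ls = c(0.05, 0.05), sf2 = 1.2, sn2 = 1e-6)
  space <- design_space()
  ds <- gp_dataset(matrix(c(0.15, 8), 1), 2.0, 0, space)
  m <- fit_gp(ds, gp_fit_config(fixed = hy))
  pr <- predict(m, matrix(c(1.95, 118), 1))
  expect_lt(abs(pr$mean - 2.0), 0.01 * 2.0)            # training mean (n = 1)
  expect_lt(abs(pr$sd - sqrt(hy$sf2)), 0.01 * sqrt(hy$sf2)) # prior sd (y_sd = 1)
})

test_that("duplicate noisy observations shrink towards their average", {
  X <- rbind(c(0.8, 50), c(0.8, 50))
  colnames(X) <- c("glucose_pct", "nh4cl_mM")
  ds <- gp_dataset(X, c(1.0, 3.0), c(4, 4), design_space())
  m <- fit_gp(ds, gp_fit_config(fixed = list(ls = c(0.3, 0.3), sf2 = 1, sn2 = 1e-6)))
  pr <- predict(m, matrix(c(0.8, 50), 1))
  expect_gt(pr$mean, 1.0)
  expect_lt(pr$mean, 3.0)
})

test_that("grid prediction equals pointwise prediction and is order-invariant", {
  sc <- gp_test_scenario()
  m <- fit_gp(gp_dataset(sc$X, sc$y, sc$noise_var, design_space()),
              gp_fit_config(fixed = sc$hyper))
  Xq <- sample_compositions(10, seed = 17)
  batch <- predict(m, Xq)
  single <- t(sapply(seq_len(nrow(Xq)), function(i) {
    pr <- predict(m, Xq[i, , drop = FALSE]); c(pr$mean, pr$sd)
  }))
  expect_equal(batch$mean, single[, 1], tolerance = 1e-12)
  expect_equal(batch$sd, single[, 2], tolerance = 1e-12)
  # permuting training points leaves predictions unchanged
  perm <- c(3, 1, 5, 2, 4)
  m2 <- fit_gp(gp_dataset(sc$X[perm, ], sc$y[perm], sc$noise_var[perm], design_space()),
               gp_fit_config(fixed = sc$hyper))
  pr2 <- predict(m2, Xq)
  expect_equal(batch$mean, pr2$mean, tolerance = 1e-10)
  expect_equal(batch$sd, pr2$sd, tolerance = 1e-10)
})

test_that("posterior sd never exceeds the prior sd and information accumulates", {
  sc <- gp_test_scenario()
  space <- design_space()
  ds <- gp_dataset(sc$X, sc$y, sc$noise_var, space)
  m <- fit_gp(ds, gp_fit_config(fixed = sc$hyper))
  grid <- make_grid(space, 31)
  pr <- predict(m, grid)
  prior_sd <- ds$y_sd * sqrt(sc$hyper$sf2)
  expect_true(all(pr$sd <= prior_sd + 1e-9))
  # adding a noiseless observation under the same fixed kernel never
  # increases the latent posterior sd anywhere and collapses it locally
  # (compare on the dimensionless z scale, where the latent variance
  # depends only on the inputs and kernel)
  xnew <- c(1.0, 80)
  tiny_jit <- list(ls = sc$hyper$ls, sf2 = sc$hyper$sf2, sn2 = 1e-8)
  ds0 <- gp_dataset(sc$X, sc$y, 0, space)
  m0 <- fit_gp(ds0, gp_fit_config(fixed = tiny_jit))
  ds2 <- gp_dataset(rbind(sc$X, xnew), c(sc$y, 1.5), 0, space)
  m2 <- fit_gp(ds2, gp_fit_config(fixed = tiny_jit))
  sd0 <- predict(m0, grid)$sd / ds0$y_sd
  sd2 <- predict(m2, grid)$sd / ds2$y_sd
  expect_true(all(sd2 <= sd0 + 1e-7))
  at_new <- predict(m2, matrix(xnew, 1))
  expect_lt(at_new$sd, 1e-3)
})

test_that("known lengthscales are recovered within a factor of two", {
  space <- design_space()
  ls_true <- c(0.25, 0.4); sf2 <- 1.5
  ok <- sapply(1:20, function(s) {
    U <- withr::with_seed(s, matrix(stats::runif(120), ncol = 2))
    X <- cbind(0.1 + 1.9 * U[, 1], 5 + 115 * U[, 2])
    colnames(X) <- c("glucose_pct", "nh4cl_mM")
    K <- mediaopt:::matern52(U, U, ls_true, sf2) + diag(1e-8, 60)
    y <- withr::with_seed(s + 500, drop(t(chol(K)) %*% stats::rnorm(60))) + 1.5
    m <- fit_gp(gp_dataset(X, y, 1e-4, space), gp_fit_config(seed = s))
    all(m$hyper$ls / ls_true < 2 & m$hyper$ls / ls_true > 0.5)
  })
  expect_gte(sum(ok), 18)
})

test_that("models survive a JSON serialisation round trip", {
  sc <- gp_test_scenario()
  m <- fit_gp(gp_dataset(sc$X, sc$y, sc$noise_var, design_space()),
              gp_fit_config(fixed = sc$hyper))
  path <- tempfile(fileext = ".json")
  gp_to_json(m, path)
  m2 <- gp_from_json(path)
  Xq <- sample_compositions(5, seed = 77)
  p1 <- predict(m, Xq); p2 <- predict(m2, Xq)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-10)
})
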