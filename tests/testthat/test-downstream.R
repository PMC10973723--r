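test_that("Spearman correlation is rank-based and matches a brute-force oracle", {
  X <- withr::with_seed(1, matrix(stats::rnorm(15), 5, 3))
  colnames(X) <- paste0("s", 1:3)
  rho <- spearman_matrix(X)
  expect_equal(rho, oracle_spearman(X), tolerance = 1e-12)
  expect_equal(diag(rho), rep(1, 3), ignore_attr = TRUE)
  # monotone invariance
  Y <- cbind(a = X[, 1], b = exp(X[, 1]))
  expect_equal(spearman_matrix(Y)["a", "b"], 1)
})

test_that("constant signals yield missing correlations with a warning", {
  X <- cbind(a = c(1, 2, 3, 4), b = rep(2, 4))
  expect_warning(rho <- spearman_matrix(X), "constant")
  expect_true(is.na(rho["a", "b"]))
  expect_error(hierarchical_cluster(rho), "a ~ b")
})

test_that("hierarchical clustering recovers perfectly correlated blocks", {
  n <- 40
  z1 <- withr::with_seed(2, stats::rnorm(n))
  z2 <- withr::with_seed(3, stats::rnorm(n))
  X <- cbind(a = z1, b = 2 * z1 + 1, c = z2, d = 0.5 * z2 - 2)
  cl <- hierarchical_cluster(spearman_matrix(X), k = 2)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_equal(cl$labels[["c"]], cl$labels[["d"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
  expect_true(all(diff(cl$heights) >= -1e-12)) # average-linkage monotonicity
})

test_that("planted panel groups are recovered by clustering", {
  ari <- sapply(1:20, function(s) {
    pan <- make_metabolite_panel(panel_spec(within_group_weight = 0.9,
                                            between_group_weight = 0.05), seed = s)
    X <- sample_compositions(200, seed = 1000 + s)
    M <- sapply(pan$surfaces, function(f) f(X))
    cl <- hierarchical_cluster(spearman_matrix(M), k = 4)
    mclust::adjustedRandIndex(cl$labels, pan$groups)
  })
  expect_gte(sum(ari >= 0.9), 18)
})

test_that("cluster recovery degrades as the within-group weight decreases", {
  mean_ari <- sapply(c(0.95, 0.6, 0.2), function(w) {
    mean(sapply(1:5, function(s) {
      pan <- make_metabolite_panel(panel_spec(within_group_weight = w,
                                              between_group_weight = 0.05,
                                              n_asymmetric = 0), seed = s)
      X <- sample_compositions(200, seed = 4000 + s)
      M <- sapply(pan$surfaces, function(f) f(X))
      cl <- hierarchical_cluster(spearman_matrix(M), k = 4)
      mclust::adjustedRandIndex(cl$labels, pan$groups)
    }))
  })
  expect_true(all(diff(mean_ari) <= 0.05)) # monotone trend, small slack
})

test_that("PCA matches an independent eigendecomposition", {
  X <- withr::with_seed(4, matrix(stats::rnorm(60), 10, 6))
  colnames(X) <- paste0("s", 1:6)
  pc <- pca_signals(X, standardise = FALSE)
  ev <- eigen(stats::cov(scale(X, scale = FALSE)), symmetric = TRUE)
  frac <- ev$values / sum(ev$values)
  expect_equal(pc$explained, frac, tolerance = 1e-10)
  # scores equal up to component sign
  sc_o <- scale(X, scale = FALSE) %*% ev$vectors
  for (j in 1:6) {
    expect_true(max(abs(pc$scores[, j] - sc_o[, j])) < 1e-8 ||
                max(abs(pc$scores[, j] + sc_o[, j])) < 1e-8)
  }
  expect_lt(abs(sum(pc$explained) - 1), 1e-9)
  # orthogonal loadings
  expect_equal(crossprod(pc$loadings), diag(6), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA handles collinearity, permutations and zero variance", {
  z <- withr::with_seed(5, stats::rnorm(12))
  X <- cbind(a = z, b = 3 * z + 2)
  pc <- pca_signals(X, standardise = FALSE)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  # permuting samples permutes scores identically
  M <- withr::with_seed(6, matrix(stats::rnorm(40), 8, 5))
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  p1 <- pca_signals(M); p2 <- pca_signals(M[perm, ])
  expect_equal(p2$scores, p1$scores[perm, ], tolerance = 1e-9)
  expect_equal(p2$explained, p1$explained, tolerance = 1e-12)
  expect_error(pca_signals(cbind(a = z, b = rep(1, 12))), "zero-variance")
})

test_that("the Pareto front matches the quadratic dominance oracle", {
  # single point and mutual non-domination edge cases
  single <- data.frame(titre = 1.5, max_od = 0.9)
  expect_equal(pareto_front(single)$front_idx, 1L)
  curve <- data.frame(titre = 1:10, max_od = 10:1)
  expect_equal(sort(pareto_front(curve)$front_idx), 1:10)
  # random instances, including ties
  for (s in 1:30) {
    n <- 200
    p <- withr::with_seed(s, data.frame(titre = round(stats::rnorm(n), 2),
                                        max_od = round(stats::rnorm(n), 2)))
    got <- sort(pareto_front(p)$front_idx)
    want <- sort(oracle_pareto_idx(p$titre, p$max_od))
    expect_equal(got, want)
  }
})

test_that("tradeoff sampling pairs model predictions over the space", {
  titre <- make_landscape()
  od <- function(X) 0.25 + 1.15 * (X[, 1] / (X[, 1] + 0.25)) * (X[, 2] / (X[, 2] + 12))
  tp <- sample_tradeoff(titre, od, n = 100, seed = 4)
  expect_equal(nrow(tp), 100)
  expect_true(all(mediaopt:::in_space(as.matrix(tp[, 1:2]), design_space())))
  expect_equal(tp$titre, titre(as.matrix(tp[, 1:2])))
  pf <- pareto_front(tp)
  expect_true(all(pf$front_idx %in% seq_len(100)))
})

test_that("anisotropy profiles are flat on constant and symmetric surfaces", {
  space <- design_space()
  cfg <- anisotropy_config(centre = c(0.8, 50))
  const <- function(X) rep(2, nrow(X))
  p <- anisotropy_profile(const, cfg = cfg, space = space)
  expect_true(all(abs(p$gradient) < 1e-10))
  expect_equal(asymmetry_index(p), 0)
  # radially symmetric in ellipse-normalised coordinates
  sym <- function(X) {
    r2 <- ((X[, 1] - 0.8) / 0.6)^2 + ((X[, 2] - 50) / 24)^2
    exp(-r2)
  }
  ps <- anisotropy_profile(sym, cfg = cfg, space = space)
  expect_lt(diff(range(abs(ps$gradient))), 1e-6)
})

test_that("anisotropy of a linear surface is the directional cosine", {
  space <- design_space()
  cfg <- anisotropy_config(centre = c(0.8, 50), n_angles = 36, n_path = 100)
  a <- 1.7
  lin <- function(X) a * (X[, 1] - 0.8) / 0.6 # linear in radius-normalised glucose
  p <- anisotropy_profile(lin, cfg = cfg, space = space)
  th <- p$angle_deg * pi / 180
  expect_lt(max(abs(p$gradient - a * cos(th))), 1e-3)
  # antisymmetry of linear surfaces: g(theta) + g(theta + 180) = 0
  half <- cfg$n_angles / 2
  expect_lt(max(abs(p$gradient[1:half] + p$gradient[half + 1:half])), 1e-9)
})

test_that("gradient paths are clipped at the design-space boundary", {
  space <- design_space()
  cfg <- anisotropy_config(centre = c(0.15, 50)) # 0.6 % radius exits at low glucose
  lin <- function(X) X[, 1]
  p <- anisotropy_profile(lin, cfg = cfg, space = space)
  expect_true(any(p$clipped))
  expect_true(all(is.finite(p$gradient[!p$clipped])))
  expect_warning(
    anisotropy_profile(lin, cfg = anisotropy_config(centre = c(0.1, 50)), space = space),
    "boundary")
})

test_that("the asymmetry index flags a dominant direction", {
  angs <- seq(0, 350, by = 10)
  g <- rep(1, 36)
  g[angs == 140] <- 3 # spike in one direction, 3x all other angles
  prof <- structure(data.frame(angle_deg = angs, gradient = g,
                               clipped = FALSE),
                    class = c("anisotropy_profile", "data.frame"))
  idx <- asymmetry_index(prof)
  expect_gt(idx, 0.5)
  flat <- prof; flat$gradient <- rep(0.8, 36)
  res <- filter_asymmetric(list(spiky = prof, flat = flat), threshold = 0.5)
  expect_equal(res$signal[res$asymmetric], "spiky")
  expect_equal(res$dominant_angle_deg[res$signal == "spiky"], 140)
  expect_equal(asymmetry_index(flat), 0, tolerance = 1e-12)
})

test_that("exactly the planted anisotropic panel members pass the filter", {
  space <- design_space()
  for (s in c(2, 9, 17)) {
    pan <- make_metabolite_panel(seed = s)
    cfg <- anisotropy_config(centre = pan$centre)
    profs <- lapply(pan$surfaces, anisotropy_profile, cfg = cfg, space = space)
    res <- filter_asymmetric(profs)
    expect_setequal(res$signal[res$asymmetric], names(pan$surfaces)[pan$asymmetric])
  }
})

test_that("anisotropy exports write well-formed tables", {
  space <- design_space()
  cfg <- anisotropy_config(centre = c(0.8, 50), n_angles = 12)
  lin <- function(X) X[, 1]
  profs <- list(g = anisotropy_profile(lin, cfg = cfg, space = space))
  csvp <- tempfile(fileext = ".csv"); jsp <- tempfile(fileext = ".json")
  long <- write_anisotropy(profs, csvp, jsp)
  expect_equal(nrow(long), 12)
  back <- utils::read.csv(csvp)
  expect_equal(back$gradient, long$gradient, tolerance = 1e-9)
  expect_true(file.exists(jsp))
})
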