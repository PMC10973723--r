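# Post-loop analyses: Spearman correlation structure with hierarchical
# clustering, PCA of the loop samples, Pareto titre/growth trade-offs, and
# the directional (anisotropy) analysis of response surfaces around the
# titre maximum.

#' Spearman correlation matrix over panel signals
#'
#' Pairwise rank correlation (mid-rank ties) across samples. Constant
#' columns yield undefined correlations, emitted as `NA` with a warning.
#'
#' @param table numeric matrix/data.frame, samples x signals (>= 3 samples).
#' @param use observation handling: `"everything"` (default; missing values
#'   propagate to `NA` correlations) or `"pairwise"` (pairwise-complete
#'   observations, appropriate when outlier filtering removed different
#'   wells for different signals).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, use = c("everything", "pairwise")) {
  use <- match.arg(use)
  M <- as.matrix(table)
  stopifnot(nrow(M) >= 3)
  const <- apply(M, 2, function(v) {
    s <- stats::sd(v, na.rm = use == "pairwise")
    is.na(s) || s == 0
  })
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(M)[const], collapse = ", "),
            "; correlations undefined (NA)")
  }
  rho <- suppressWarnings(stats::cor(
    M, method = "spearman",
    use = if (use == "pairwise") "pairwise.complete.obs" else "everything"))
  diag(rho) <- 1
  rho
}

#' Hierarchical clustering of the correlation structure
#'
#' Agglomerative clustering on the dissimilarity `1 - rho` with average
#' linkage, as used to order correlation heatmaps and cut the dendrogram
#' into correlated subgroups.
#'
#' @param corr correlation matrix (no missing entries).
#' @param k number of groups to cut at.
#' @return list with `hclust` (merge history), `order` (leaf order),
#'   `labels` (integer cluster labels at `k`), `heights`.
#' @export
hierarchical_cluster <- function(corr, k = 4) {
  if (any(is.na(corr))) {
    bad <- which(is.na(corr), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pairs <- apply(bad, 1, function(ij) {
      paste(rownames(corr)[ij[1]] %||% ij[1], colnames(corr)[ij[2]] %||% ij[2], sep = " ~ ")
    })
    stop("missing correlations for signal pair(s): ", paste(pairs, collapse = "; "))
  }
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order,
       labels = stats::cutree(hc, k = k), heights = hc$height)
}

#' PCA of loop samples over panel signals
#'
#' Column-centred (optionally unit-variance scaled) singular value
#' decomposition, with explained-variance fractions from the squared
#' singular values and a deterministic sign convention: each component is
#' flipped so its largest-magnitude loading is positive.
#'
#' @param table numeric matrix/data.frame, samples x signals.
#' @param standardise scale columns to unit variance (default TRUE;
#'   appropriate when mixing signals of different magnitude).
#' @return list with `scores`, `loadings`, `explained` (variance fractions).
#' @export
pca_signals <- function(table, standardise = TRUE) {
  M <- as.matrix(table)
  stopifnot(nrow(M) >= 2, ncol(M) >= 2)
  if (standardise) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s) with standardise = TRUE: ",
           paste(colnames(M)[sds == 0], collapse = ", "))
    }
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = standardise)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Sample the titre/growth trade-off surface
#'
#' Uniform seeded sampling of the design space, with predicted titre and
#' predicted maximum OD per sampled composition.
#'
#' @param titre_model model (or surface function) for relative titre.
#' @param od_model model (or surface function) for maximum OD.
#' @param n number of sampled compositions.
#' @param seed integer seed.
#' @param space the [design_space()].
#' @return data.frame `glucose_pct, nh4cl_mM, titre, max_od`.
#' @export
sample_tradeoff <- function(titre_model, od_model, n = 200, seed = 1,
                            space = design_space()) {
  U <- with_seed_(seed, matrix(stats::runif(2 * n), ncol = 2))
  X <- from_unit(U, space)
  data.frame(glucose_pct = X[, 1], nh4cl_mM = X[, 2],
             titre = surface_mean(titre_model, X),
             max_od = surface_mean(od_model, X))
}

#' Pareto front under joint maximisation
#'
#' Extracts the non-dominated subset of sampled (titre, max OD) pairs: a
#' point is dominated if another point is >= in both objectives and > in at
#' least one. Sort-based sweep, O(n log n).
#'
#' @param pairs data.frame with `titre` and `max_od` columns (or a 2-column
#'   matrix).
#' @return list with `front_idx` (indices into `pairs`, sorted by titre),
#'   `front` (the non-dominated rows) and the input `pairs`.
#' @export
pareto_front <- function(pairs) {
  if (is.matrix(pairs)) pairs <- data.frame(titre = pairs[, 1], max_od = pairs[, 2])
  n <- nrow(pairs)
  if (n == 0) return(list(front_idx = integer(0), front = pairs, pairs = pairs))
  ord <- order(-pairs$titre, -pairs$max_od)
  keep <- logical(n)
  best_od <- -Inf
  i <- 1
  while (i <= n) {
    # handle titre ties as one group: within a tie group only max-OD points
    # can be non-dominated, and only if they beat every better-titre point
    j <- i
    while (j < n && pairs$titre[ord[j + 1]] == pairs$titre[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    grp_best <- max(pairs$max_od[grp])
    if (grp_best > best_od) keep[grp[pairs$max_od[grp] == grp_best]] <- TRUE
    best_od <- max(best_od, grp_best)
    i <- j + 1
  }
  # drop duplicated points (identical pairs dominate nothing, keep one copy)
  idx <- which(keep)
  dup <- duplicated(pairs[idx, c("titre", "max_od")])
  idx <- idx[!dup]
  idx <- idx[order(pairs$titre[idx])]
  list(front_idx = idx, front = pairs[idx, , drop = FALSE], pairs = pairs)
}

#' Anisotropy-analysis configuration
#'
#' @param radius_glucose half-axis of the sampling ellipse along glucose
#'   (% w/v; default 0.6).
#' @param radius_nh4 half-axis along NH4Cl (mM; default 24).
#' @param n_angles number of equally spaced directions over 0-360 degrees.
#' @param n_path samples along each straight radial path (>= 2).
#' @param centre optional explicit centre composition; by default the
#'   model-predicted titre argmax.
#' @return object of class `anisotropy_config`.
#' @export
anisotropy_config <- function(radius_glucose = 0.6, radius_nh4 = 24,
                              n_angles = 36, n_path = 100, centre = NULL) {
  stopifnot(radius_glucose > 0, radius_nh4 > 0, n_angles >= 1, n_path >= 2)
  structure(list(radius_glucose = radius_glucose, radius_nh4 = radius_nh4,
                 n_angles = as.integer(n_angles), n_path = as.integer(n_path),
                 centre = centre),
            class = "anisotropy_config")
}

#' Directional gradient profile of a response surface
#'
#' Starting at the titre maximum, straight radial paths are traced towards
#' the ellipse of half-axes (`radius_glucose`, `radius_nh4`) in `n_angles`
#' directions (0 deg = pure glucose increase, 90 deg = pure NH4Cl increase,
#' angles in ellipse-normalised coordinates). Along each path, `n_path`
#' equally spaced points of the signal's (posterior) mean are evaluated and
#' the mean of successive finite-difference slopes with respect to the
#' normalised arc length (centre to full radius = 1 unit) is the average
#' gradient `g(theta)`. Paths leaving the design space are clipped at the
#' boundary (logged); fully clipped angles are reported missing.
#'
#' @param signal_model surface to profile (a `gp_model` or surface function).
#' @param titre_model titre surface whose maximum defines the centre (used
#'   when `cfg$centre` is `NULL`).
#' @param cfg an [anisotropy_config()].
#' @param space the [design_space()].
#' @return an `anisotropy_profile`: data.frame `angle_deg, gradient,
#'   clipped`, with the centre as an attribute.
#' @export
anisotropy_profile <- function(signal_model, titre_model = NULL,
                               cfg = anisotropy_config(), space = design_space()) {
  centre <- cfg$centre
  if (is.null(centre)) {
    stopifnot(!is.null(titre_model))
    opt <- predicted_optimum_of(titre_model, space)
    centre <- c(opt$glucose_pct, opt$nh4cl_mM)
  }
  centre <- as.numeric(centre)
  on_boundary <- any(abs(centre - space$lo) < 1e-9) || any(abs(centre - space$hi) < 1e-9)
  if (on_boundary) warning("anisotropy centre lies on the design-space boundary")
  angles <- seq(0, 360, length.out = cfg$n_angles + 1)[-(cfg$n_angles + 1)]
  out <- data.frame(angle_deg = angles, gradient = NA_real_, clipped = FALSE)
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    delta <- c(cfg$radius_glucose * cos(th), cfg$radius_nh4 * sin(th))
    # largest t in [0,1] keeping centre + t*delta inside the space
    tmax <- 1
    for (ax in 1:2) {
      if (delta[ax] > 0) tmax <- min(tmax, (space$hi[ax] - centre[ax]) / delta[ax])
      if (delta[ax] < 0) tmax <- min(tmax, (space$lo[ax] - centre[ax]) / delta[ax])
    }
    tmax <- max(tmax, 0)
    if (tmax < 1e-6) { out$clipped[i] <- TRUE; next }
    out$clipped[i] <- tmax < 1
    tt <- seq(0, tmax, length.out = cfg$n_path)
    P <- cbind(centre[1] + tt * delta[1], centre[2] + tt * delta[2])
    v <- surface_mean(signal_model, P)
    out$gradient[i] <- mean(diff(v) / diff(tt)) # arc length normalised: full radius = 1
  }
  structure(out, class = c("anisotropy_profile", "data.frame"),
            centre = centre, config = cfg)
}

# argmax of a surface/model mean over a dense grid.
predicted_optimum_of <- function(object, space, res = 201) {
  grid <- make_grid(space, res)
  mu <- surface_mean(object, grid)
  i <- which.max(mu)
  list(glucose_pct = grid$glucose_pct[i], nh4cl_mM = grid$nh4cl_mM[i],
       predicted_value = mu[i])
}

#' Asymmetry index of a gradient profile
#'
#' `(max|g| - min|g|) / (mean|g| + eps)` over the profile's defined angles;
#' an all-zero profile has index 0 by convention. A surface whose gradient
#' magnitude is direction-independent (radially symmetric about the centre)
#' scores ~0; a generic tilted surface scores well above the default filter
#' threshold.
#'
#' @param profile an `anisotropy_profile`.
#' @return non-negative scalar.
#' @export
asymmetry_index <- function(profile) {
  g <- abs(profile$gradient[!is.na(profile$gradient)])
  if (length(g) == 0 || max(g) < 1e-12) return(0)
  (max(g) - min(g)) / (mean(g) + 1e-12)
}

#' Filter asymmetric gradient profiles
#'
#' @param profiles named list of `anisotropy_profile`s.
#' @param threshold asymmetry-index threshold (default 0.5).
#' @return data.frame `signal, index, dominant_angle_deg, asymmetric`,
#'   sorted by decreasing index; `dominant_angle_deg` is the direction of
#'   the largest absolute gradient.
#' @export
filter_asymmetric <- function(profiles, threshold = 0.5) {
  stopifnot(length(names(profiles)) == length(profiles))
  rows <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    idx <- asymmetry_index(p)
    ok <- !is.na(p$gradient)
    dom <- if (any(ok)) p$angle_deg[ok][which.max(abs(p$gradient[ok]))] else NA_real_
    data.frame(signal = nm, index = idx, dominant_angle_deg = dom,
               asymmetric = idx > threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$index), , drop = FALSE]
}

#' Export anisotropy profiles
#'
#' Long CSV (`signal, angle_deg, gradient`) and a radar-chart-ready JSON.
#'
#' @param profiles named list of `anisotropy_profile`s.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the long data.frame.
#' @export
write_anisotropy <- function(profiles, csv_path = NULL, json_path = NULL) {
  long <- do.call(rbind, lapply(names(profiles), function(nm) {
    data.frame(signal = nm, angle_deg = profiles[[nm]]$angle_deg,
               gradient = profiles[[nm]]$gradient, stringsAsFactors = FALSE)
  }))
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    radar <- lapply(profiles, function(p) list(angle_deg = p$angle_deg, gradient = p$gradient))
    jsonlite::write_json(radar, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(long)
}
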