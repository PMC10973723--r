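# Synthetic-data generators: ground-truth titre landscapes, correlated
# metabolite panels, noisy flow-injection plate traces and growth curves.
# These emulate every measured input of the wet-lab study so the whole
# pipeline can be exercised and validated without instrument data.

#' Specify a ground-truth titre landscape
#'
#' The landscape is a smooth sum of anisotropic Gaussian bumps plus a
#' constant floor, algebraically anchored so that its value at the M9
#' baseline composition is exactly 1.0 (titres are expressed relative to
#' M9) and its value at the peak equals `peak_relative_height`. The default
#' peak location and height mirror the optimised medium: a 2.6-fold
#' relative titre at 0.8 % glucose / 50 mM NH4Cl (a 160 % improvement).
#'
#' @param peak length-2 numeric: peak composition (glucose_pct, nh4cl_mM).
#' @param peak_relative_height relative titre at the peak (>= 1).
#' @param widths per-axis Gaussian bump scales (glucose %, NH4Cl mM).
#' @param baseline M9 baseline composition anchored to 1.0.
#' @param extra_bumps optional list of `list(location=, height=, widths=)`
#'   secondary bumps (heights relative to the main bump's unit height).
#' @return object of class `surface_spec`.
#' @export
surface_spec <- function(peak = c(0.8, 50), peak_relative_height = 2.6,
                         widths = c(0.35, 30), baseline = c(0.4, 18.7),
                         extra_bumps = NULL) {
  stopifnot(length(peak) == 2L, length(widths) == 2L, length(baseline) == 2L)
  if (any(baseline <= 0)) stop("baseline composition must be strictly positive")
  if (peak_relative_height < 1) stop("peak_relative_height must be >= 1")
  if (any(widths <= 0)) stop("bump widths must be positive")
  structure(list(peak = as.numeric(peak),
                 peak_relative_height = peak_relative_height,
                 widths = as.numeric(widths),
                 baseline = as.numeric(baseline),
                 extra_bumps = extra_bumps),
            class = "surface_spec")
}

# Unit-height anisotropic Gaussian bump at `centre` with per-axis `widths`.
gauss_bump <- function(X, centre, widths) {
  d2 <- ((X[, 1] - centre[1]) / widths[1])^2 + ((X[, 2] - centre[2]) / widths[2])^2
  exp(-0.5 * d2)
}

#' Build a ground-truth relative-titre landscape
#'
#' Returns a deterministic smooth function of media composition. Anchoring
#' is algebraic: with `raw(x)` the sum of unit-height bumps, the surface is
#' `f(x) = b + A * raw(x)` with `A`, `b` solved so `f(baseline) = 1` exactly
#' and `f(peak) = peak_relative_height`. With the default single-bump spec
#' the peak is the exact global maximum; with extra bumps it remains the
#' maximum to within 1 % provided the extra bumps are genuinely secondary.
#'
#' @param spec a [surface_spec()].
#' @param space a [design_space()]; the peak must lie inside it.
#' @param seed kept for interface symmetry with the other generators; the
#'   construction is fully deterministic given `spec`.
#' @return a function (`surface_function`) mapping composition rows to
#'   relative titre.
#' @export
make_landscape <- function(spec = surface_spec(), space = design_space(), seed = 1) {
  stopifnot(inherits(spec, "surface_spec"))
  pk <- spec$peak
  if (!in_space(matrix(pk, 1), space)) {
    bad <- c("glucose_pct", "nh4cl_mM")[pk < space$lo | pk > space$hi]
    stop(sprintf("surface peak outside the design space on axis %s (peak = %g %%, %g mM)",
                 paste(bad, collapse = ","), pk[1], pk[2]))
  }
  bumps <- c(list(list(location = pk, height = 1, widths = spec$widths)),
             spec$extra_bumps)
  raw <- function(X) {
    X <- as_composition_matrix(X)
    v <- 0
    for (bmp in bumps) v <- v + bmp$height * gauss_bump(X, bmp$location, bmp$widths)
    v
  }
  r_base <- raw(matrix(spec$baseline, 1))
  r_peak <- raw(matrix(pk, 1))
  if (abs(r_peak - r_base) < 1e-12) {
    if (spec$peak_relative_height == 1) {
      A <- 0; b <- 1
    } else stop("degenerate spec: peak and baseline coincide")
  } else {
    A <- (spec$peak_relative_height - 1) / (r_peak - r_base)
    b <- 1 - A * r_base
  }
  f <- function(X) as.numeric(b + A * raw(X))
  structure(f, class = c("surface_function", "function"),
            spec = spec, space = space, floor = b, amplitude = A)
}

#' Specify replicate/measurement noise for simulated plates
#'
#' Replicate noise is multiplicative with a coefficient of variation that
#' grows with the surface value (heteroskedastic):
#' `cv_eff = replicate_cv * (1 + heteroskedastic_slope * value)`.
#' Traces additionally receive a linear baseline drift and white noise,
#' and with probability `outlier_prob` a well's area is multiplied by
#' `outlier_scale`.
#'
#' @param replicate_cv baseline coefficient of variation (default 0.15).
#' @param heteroskedastic_slope CV growth per unit surface value.
#' @param outlier_prob per-well gross-outlier probability.
#' @param outlier_scale multiplier applied to outlier areas.
#' @param drift_mag magnitude of the linear baseline drift (intensity units;
#'   intercept ~ U(0, drift_mag), slope ~ U(-drift_mag, drift_mag)).
#' @param white_sd white-noise standard deviation (intensity units).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(replicate_cv = 0.15, heteroskedastic_slope = 0.2,
                       outlier_prob = 0, outlier_scale = 5,
                       drift_mag = 0.3, white_sd = 0.01) {
  stopifnot(replicate_cv >= 0, replicate_cv < 1, heteroskedastic_slope >= 0,
            outlier_prob >= 0, outlier_prob <= 1, outlier_scale >= 0,
            drift_mag >= 0, white_sd >= 0)
  structure(list(replicate_cv = replicate_cv,
                 heteroskedastic_slope = heteroskedastic_slope,
                 outlier_prob = outlier_prob, outlier_scale = outlier_scale,
                 drift_mag = drift_mag, white_sd = white_sd),
            class = "noise_spec")
}

#' Specify the correlated metabolite panel
#'
#' The panel emulates the 22 signals quantified per well (4 lipopeptides +
#' 18 other metabolites) plus their planted correlation structure: four
#' subgroups of sizes 6/7/7/5, with amino-acid-type groups (1, 2)
#' anti-correlated to the lipopeptide and organic-acid groups (3, 4).
#' Exactly `n_asymmetric` panel surfaces receive a directionally biased
#' (anisotropic) component about the titre maximum.
#'
#' @param group_sizes integer group sizes (must sum to the panel size).
#' @param within_group_weight convex weight of the shared group latent in
#'   each member surface (0..1).
#' @param between_group_weight convex weight of the panel-common latent in
#'   each group latent (0..1); controls cross-group correlation strength.
#' @param group_signs per-group sign (+1/-1) controlling the sign of
#'   between-group correlations.
#' @param n_asymmetric number of deliberately anisotropic surfaces.
#' @param asym_strength relative amplitude of the angular modulation
#'   applied to asymmetric members (0..1).
#' @param amplitude overall deviation amplitude about the level 1.0.
#' @param radial_scale per-axis scales (glucose %, NH4Cl mM) that map the
#'   neighbourhood of the titre peak to ellipse-normalised coordinates; the
#'   defaults equal the anisotropy-analysis radii (0.6 %, 24 mM).
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(group_sizes = c(6, 7, 7, 5), within_group_weight = 0.85,
                       between_group_weight = 0.4,
                       group_signs = c(-1, -1, 1, 1),
                       n_asymmetric = 6, asym_strength = 0.6,
                       amplitude = 0.3, radial_scale = c(0.6, 24)) {
  stopifnot(all(group_sizes >= 1), within_group_weight >= 0, within_group_weight <= 1,
            between_group_weight >= 0, between_group_weight <= 1,
            length(group_signs) == length(group_sizes), all(abs(group_signs) == 1),
            n_asymmetric >= 0, n_asymmetric <= sum(group_sizes),
            asym_strength >= 0, asym_strength < 1, amplitude > 0,
            all(radial_scale > 0))
  structure(list(group_sizes = as.integer(group_sizes),
                 within_group_weight = within_group_weight,
                 between_group_weight = between_group_weight,
                 group_signs = group_signs, n_asymmetric = as.integer(n_asymmetric),
                 asym_strength = asym_strength, amplitude = amplitude,
                 radial_scale = as.numeric(radial_scale)),
            class = "panel_spec")
}

# A random smooth 2-D field on the design space: a sum of Gaussian bumps in
# unit-square coordinates, rescaled to unit maximum absolute value.
random_field <- function(seed, space, k = 5) {
  par <- with_seed_(seed, list(a = stats::rnorm(k),
                               mu = matrix(stats::runif(2 * k), ncol = 2),
                               s = stats::runif(k, 0.15, 0.4)))
  f <- function(U) {
    v <- 0
    for (j in seq_len(k)) {
      d2 <- ((U[, 1] - par$mu[j, 1])^2 + (U[, 2] - par$mu[j, 2])^2) / par$s[j]^2
      v <- v + par$a[j] * exp(-0.5 * d2)
    }
    v
  }
  # normalise to zero mean / unit sd over the space so convex mixture
  # weights translate directly into correlation strength
  pr <- as.matrix(expand.grid(seq(0, 1, length.out = 21), seq(0, 1, length.out = 21)))
  v <- f(pr)
  mu <- mean(v)
  s <- stats::sd(v)
  if (s < 1e-9) s <- 1
  function(U) (f(U) - mu) / s
}

#' Generate the correlated metabolite panel surfaces
#'
#' Each panel surface is `1 + amplitude * q_i(x) * w(r)` (plus, for planted
#' anisotropic members, `amplitude * asym_strength * cos(theta - theta0) * v(r)`),
#' where `(r, theta)` are ellipse-normalised polar coordinates about the
#' titre peak (the ellipse with the `radial_scale` half-axes maps to the
#' unit circle), `q_i` is a smooth random 2-D field carrying the planted
#' correlation structure, `w(r)` is a window vanishing at the centre and on
#' the unit ring, and `v(r)` rises from 0 at the centre to 1 on the ring.
#'
#' The correlation structure is planted through convex mixtures:
#' `q_i = w_in * G_g + (1 - w_in) * E_i` with group latents
#' `G_g = sign_g * (w_bg * Q0 + (1 - w_bg) * Q_g)` built from independent
#' random fields, so within-group correlation is controlled by
#' `within_group_weight` and the between-group correlation sign by
#' `group_signs` (amino-acid-type groups negative versus the lipopeptide
#' and organic-acid groups).
#'
#' Because `w(r)` vanishes at the centre and on the ring, every
#' non-planted member has zero net centre-to-ring change in every
#' direction (a direction-symmetric gradient profile), while each planted
#' member's angular term produces a gradient profile proportional to
#' `|cos(theta - theta0)|` regardless of its correlation field, so planted
#' anisotropy is always detectable.
#'
#' @param panel a [panel_spec()].
#' @param titre_spec the titre [surface_spec()] whose peak anchors the
#'   panel's polar coordinates.
#' @param space a [design_space()].
#' @param seed integer seed.
#' @return list with `surfaces` (named list of surface functions), `groups`
#'   (integer labels), `asymmetric` (logical), `asym_direction_deg`
#'   (planted dominant directions, NA for symmetric members).
#' @export
make_metabolite_panel <- function(panel = panel_spec(), titre_spec = surface_spec(),
                                  space = design_space(), seed = 1) {
  stopifnot(inherits(panel, "panel_spec"))
  sizes <- panel$group_sizes
  n <- sum(sizes)
  groups <- rep(seq_along(sizes), sizes)
  centre <- titre_spec$peak
  rs <- panel$radial_scale
  polar <- function(X) {
    X <- as_composition_matrix(X)
    dx <- (X[, 1] - centre[1]) / rs[1]
    dy <- (X[, 2] - centre[2]) / rs[2]
    list(r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx))
  }
  ring_window <- function(r) tanh(3 * (r - 1))^2 * tanh(3 * r)^2
  ring_ramp <- function(r) r * exp(0.5 * (1 - r^2))
  Q0 <- random_field(derive_seed(seed, 99), space)
  c_bg <- panel$between_group_weight
  latents <- lapply(seq_along(sizes), function(g) {
    Qg <- random_field(derive_seed(seed, 100 + g), space)
    s <- panel$group_signs[g]
    function(U) s * (c_bg * Q0(U) + (1 - c_bg) * Qg(U))
  })
  asym_idx <- if (panel$n_asymmetric > 0) {
    sort(with_seed_(derive_seed(seed, 7), sample.int(n, panel$n_asymmetric)))
  } else integer(0)
  theta0 <- rep(NA_real_, n)
  if (length(asym_idx)) {
    theta0[asym_idx] <- with_seed_(derive_seed(seed, 8),
                                   stats::runif(length(asym_idx), 0, 2 * pi))
  }
  w_in <- panel$within_group_weight
  surfaces <- vector("list", n)
  for (i in seq_len(n)) {
    Ei <- random_field(derive_seed(seed, 200 + i), space)
    surfaces[[i]] <- local({
      lat <- latents[[groups[i]]]; Ei <- Ei
      is_asym <- i %in% asym_idx; th0 <- theta0[i]
      beta <- panel$asym_strength; amp <- panel$amplitude
      polar <- polar; space <- space
      ring_window <- ring_window; ring_ramp <- ring_ramp; w_in <- w_in
      function(X) {
        X <- as_composition_matrix(X)
        U <- to_unit(X, space)
        pc <- polar(X)
        q <- w_in * lat(U) + (1 - w_in) * Ei(U)
        v <- 1 + amp * q * ring_window(pc$r)
        if (is_asym) v <- v + amp * beta * cos(pc$theta - th0) * ring_ramp(pc$r)
        pmax(0.02, v)
      }
    })
    class(surfaces[[i]]) <- c("surface_function", "function")
  }
  names(surfaces) <- sprintf("signal_%02d", seq_len(n))
  list(surfaces = surfaces, groups = groups,
       asymmetric = seq_len(n) %in% asym_idx,
       asym_direction_deg = ifelse(is.na(theta0), NA, (theta0 * 180 / pi) %% 360),
       panel = panel, centre = centre)
}

#' Simulate a plate of flow-injection traces
#'
#' For each assigned well and each panel signal, the generated 1-minute
#' trace is a Gaussian injection peak (centre 0.3 min, sd 0.05 min) whose
#' area equals `value * (1 + eps)` with `eps ~ N(0, cv_eff^2)` and
#' `cv_eff = replicate_cv * (1 + heteroskedastic_slope * value)`, plus a
#' linear baseline drift and white noise. Control wells (no added
#' carbon/nitrogen) produce a small residual signal `control_value`.
#'
#' @param layout a `plate_layout`.
#' @param surfaces named list of surface functions (one per signal), or a
#'   single surface function (named via `signal_name`).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param times trace time grid in minutes (default 2 Hz over 1 min).
#' @param control_value surface value assigned to control wells.
#' @param signal_name name used when `surfaces` is a single function.
#' @return long data.frame `well, metabolite, time_min, intensity`, with a
#'   `truth` attribute (per well/signal true surface value and drawn area).
#' @export
simulate_plate <- function(layout, surfaces, noise = noise_spec(), seed = 1,
                           times = seq(0, 1, length.out = 121),
                           control_value = 0.1, signal_name = "surfactin_C") {
  stopifnot(inherits(layout, "plate_layout") || is.data.frame(layout))
  if (is.function(surfaces)) {
    surfaces <- stats::setNames(list(surfaces), signal_name)
  }
  stopifnot(length(names(surfaces)) == length(surfaces))
  nt <- length(times)
  peak_shape <- stats::dnorm(times, 0.3, 0.05)
  nw <- nrow(layout)
  out <- vector("list", nw * length(surfaces))
  truth <- vector("list", nw * length(surfaces))
  k <- 0
  for (j in seq_along(surfaces)) {
    f <- surfaces[[j]]
    met <- names(surfaces)[j]
    vals <- numeric(nw)
    is_ctrl <- layout$treatment == "control" | is.na(layout$glucose_pct)
    if (any(!is_ctrl)) {
      vals[!is_ctrl] <- f(cbind(layout$glucose_pct[!is_ctrl], layout$nh4cl_mM[!is_ctrl]))
    }
    vals[is_ctrl] <- control_value
    for (i in seq_len(nw)) {
      s_ij <- derive_seed(seed, j, i)
      draws <- with_seed_(s_ij, {
        list(eps = stats::rnorm(1), drift = stats::runif(2), out = stats::runif(1),
             white = stats::rnorm(nt))
      })
      v <- vals[i]
      cv_eff <- noise$replicate_cv * (1 + noise$heteroskedastic_slope * v)
      area <- v * (1 + draws$eps * cv_eff)
      if (noise$outlier_prob > 0 && draws$out < noise$outlier_prob) {
        area <- area * noise$outlier_scale
      }
      a0 <- draws$drift[1] * noise$drift_mag
      b0 <- (2 * draws$drift[2] - 1) * noise$drift_mag
      intensity <- area * peak_shape + a0 + b0 * times + draws$white * noise$white_sd
      k <- k + 1
      out[[k]] <- data.frame(well = layout$well[i], metabolite = met,
                             time_min = times, intensity = intensity,
                             stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(well = layout$well[i], metabolite = met,
                               value = v, area = area, cv_eff = cv_eff,
                               stringsAsFactors = FALSE)
    }
  }
  traces <- do.call(rbind, out)
  rownames(traces) <- NULL
  attr(traces, "truth") <- do.call(rbind, truth)
  traces
}

#' @rdname simulate_plate
#' @param traces long trace data.frame to write.
#' @param path file path.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces[, c("well", "metabolite", "time_min", "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname simulate_plate
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Growth-curve parameters
#'
#' Logistic growth `OD(t) = od0 + (K - od0) / (1 + exp(-r (t - t_mid)))`
#' measured every 10 min for 36 h, starting from an initial OD600 of 0.1.
#' The carrying capacity `K` is a smooth (Monod-type) function of the
#' glucose and ammonium concentrations; the coupling between growth and
#' titre surfaces is exposed explicitly through `K_fun` rather than assumed.
#'
#' @param od0 initial OD600 (default 0.1).
#' @param r logistic growth rate per minute.
#' @param t_mid inflection time in minutes.
#' @param K_fun function (glucose_pct, nh4cl_mM) -> carrying capacity.
#' @param noise_sd additive OD measurement noise.
#' @param times measurement times in minutes.
#' @return object of class `growth_spec`.
#' @export
growth_spec <- function(od0 = 0.1, r = 0.012, t_mid = 600,
                        K_fun = function(g, n) 0.25 + 1.15 * (g / (g + 0.25)) * (n / (n + 12)),
                        noise_sd = 0.005, times = seq(0, 36 * 60, by = 10)) {
  stopifnot(od0 >= 0, r > 0, t_mid >= 0, noise_sd >= 0, all(diff(times) > 0))
  structure(list(od0 = od0, r = r, t_mid = t_mid, K_fun = K_fun,
                 noise_sd = noise_sd, times = times),
            class = "growth_spec")
}

#' Simulate a growth curve for one media composition
#'
#' @param composition length-2 numeric (glucose_pct, nh4cl_mM).
#' @param seed integer seed for the measurement noise.
#' @param growth a [growth_spec()].
#' @return object of class `growth_curve`: list with `times` (min) and `od`.
#' @export
simulate_growth <- function(composition, seed = 1, growth = growth_spec()) {
  composition <- as.numeric(as_composition_matrix(composition))
  K <- growth$K_fun(composition[1], composition[2])
  t <- growth$times
  od <- growth$od0 + (K - growth$od0) / (1 + exp(-growth$r * (t - growth$t_mid)))
  if (growth$noise_sd > 0) {
    od <- od + with_seed_(seed, stats::rnorm(length(t), 0, growth$noise_sd))
  }
  od <- pmax(od, 0)
  structure(list(times = t, od = od, composition = composition, K = K),
            class = "growth_curve")
}

#' Extract growth features (maximum and final OD)
#'
#' @param curve a `growth_curve`.
#' @param smooth apply a running-median smoother before feature extraction.
#' @return named numeric `c(max_od=, final_od=)`.
#' @export
growth_features <- function(curve, smooth = TRUE) {
  od <- curve$od
  if (smooth && length(od) >= 5) od <- stats::runmed(od, 5)
  c(max_od = max(od), final_od = od[length(od)])
}
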