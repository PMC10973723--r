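# Flow-injection MS signal processing: AsLS baseline correction, trapezoid
# peak integration, IQR outlier filtering and per-batch M9 normalisation.

#' Asymmetric least-squares (AsLS) baseline configuration
#'
#' @param lam second-difference smoothness penalty (default 1e6; appropriate
#'   for ~100-200 point traces, where it makes the baseline near-linear).
#' @param p asymmetry weight given to points above the baseline (default 0.01).
#' @param max_iter maximum reweighting iterations.
#' @param tol convergence threshold on the maximum weight change.
#' @return object of class `asls_config`.
#' @export
asls_config <- function(lam = 1e6, p = 0.01, max_iter = 50, tol = 1e-6) {
  stopifnot(lam > 0, p > 0, p < 1, max_iter >= 1, tol >= 0)
  structure(list(lam = lam, p = p, max_iter = max_iter, tol = tol),
            class = "asls_config")
}

#' IQR outlier-filter configuration
#'
#' Values outside `median - k*IQR` to `median + k*IQR` are flagged as
#' outliers. Groups smaller than `min_n` bypass filtering: quartiles on very
#' few points are too unstable to reject observations from.
#'
#' @param k IQR multiplier (default 1.5).
#' @param min_n minimum group size to apply the filter (default 4).
#' @return object of class `outlier_config`.
#' @export
outlier_config <- function(k = 1.5, min_n = 4) {
  stopifnot(k > 0, min_n >= 0)
  structure(list(k = k, min_n = min_n), class = "outlier_config")
}

#' AsLS baseline estimation
#'
#' Iteratively solves `(W + lam * D'D) z = W y` with `D` the second-difference
#' operator and asymmetric weights `w_i = p` if `y_i > z_i`, else `1 - p`,
#' until the weights stabilise. The second-difference penalty leaves linear
#' trends unpenalised, so linear drifts are recovered essentially exactly
#' away from the peak.
#'
#' @param y numeric intensity vector (length >= 3, finite).
#' @param cfg an [asls_config()].
#' @return the estimated baseline, same length as `y`.
#' @export
asls_baseline <- function(y, cfg = asls_config()) {
  if (any(!is.finite(y))) stop("asls_baseline: non-finite intensities")
  m <- length(y)
  if (m < 3) stop("asls_baseline: need at least 3 samples")
  D <- diff(diag(m), differences = 2)
  P <- cfg$lam * crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(cfg$max_iter)) {
    A <- P
    diag(A) <- diag(A) + w
    z <- solve(A, w * y)
    w_new <- ifelse(y > z, cfg$p, 1 - cfg$p)
    if (max(abs(w_new - w)) < cfg$tol) break
    w <- w_new
  }
  as.numeric(z)
}

#' Trapezoid peak integration
#'
#' Integrates `intensity - baseline` over the time grid by the trapezoid
#' rule. Negative baseline-corrected residuals are not clipped (clipping
#' would bias low-abundance wells upward).
#'
#' @param time time grid in minutes (length >= 2, strictly increasing).
#' @param intensity intensity vector, same length.
#' @param baseline baseline vector (or scalar 0).
#' @return integrated area in intensity * min.
#' @export
integrate_area <- function(time, intensity, baseline = 0) {
  if (length(time) < 2) stop("integrate_area: need at least 2 samples")
  stopifnot(length(intensity) == length(time),
            length(baseline) %in% c(1L, length(time)))
  pracma::trapz(time, intensity - baseline)
}

#' IQR outlier filter
#'
#' @param values numeric vector of replicate measurements (finite).
#' @param cfg an [outlier_config()].
#' @return logical keep-mask; `TRUE` iff the value lies within
#'   `median +- k*IQR` (quartiles by linear interpolation) or the group is
#'   smaller than `min_n`.
#' @export
iqr_filter <- function(values, cfg = outlier_config()) {
  stopifnot(all(is.finite(values)))
  n <- length(values)
  if (n < cfg$min_n) return(rep(TRUE, n))
  qs <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  med <- stats::median(values)
  iqr <- qs[2] - qs[1]
  values >= med - cfg$k * iqr & values <= med + cfg$k * iqr
}

# Decide whether a trace needs baseline correction: robust linear fit on the
# trailing (peak-free) window; triggered when the fitted offset or the drift
# over the run exceeds `rel_tol` of the trace's maximum absolute intensity.
needs_baseline <- function(time, intensity, rel_tol = 0.005, trailing_frac = 0.4) {
  m <- length(time)
  idx <- seq.int(max(1L, floor((1 - trailing_frac) * m)), m)
  tt <- time[idx]; yy <- intensity[idx]
  b <- if (length(idx) >= 3 && stats::sd(tt) > 0) {
    stats::coef(stats::lm.fit(cbind(1, tt), yy))
  } else c(stats::median(yy), 0)
  scale <- max(abs(intensity))
  if (scale == 0) return(FALSE)
  span <- diff(range(time))
  abs(stats::median(yy)) > rel_tol * scale || abs(b[2]) * span > rel_tol * scale
}

#' Build the per-well abundance table from traces
#'
#' Baseline-corrects (where a drift statistic triggers it, or for an explicit
#' metabolite list), integrates each (well, metabolite) trace, and attaches
#' the plate-layout metadata.
#'
#' @param traces long data.frame `well, metabolite, time_min, intensity`.
#' @param layout the `plate_layout` of the plate.
#' @param asls_cfg an [asls_config()].
#' @param baseline_metabolites `NULL` for automatic drift detection, `"all"`,
#'   `"none"`, or a character vector of metabolite names to always correct.
#' @param drift_rel_tol trigger threshold for the automatic drift statistic,
#'   relative to the trace's maximum absolute intensity.
#' @return an `abundance_table`: long data.frame `well, metabolite, area`
#'   plus layout columns; with attribute `baseline_corrected` (count).
#' @export
integrate_plate <- function(traces, layout, asls_cfg = asls_config(),
                            baseline_metabolites = NULL, drift_rel_tol = 0.005) {
  if (nrow(traces) == 0) {
    out <- data.frame(well = character(), metabolite = character(), area = numeric())
    class(out) <- c("abundance_table", "data.frame")
    return(out)
  }
  key <- interaction(traces$well, traces$metabolite, drop = TRUE)
  pieces <- split(seq_len(nrow(traces)), key)
  rows <- lapply(pieces, function(ix) {
    tt <- traces$time_min[ix]; yy <- traces$intensity[ix]
    o <- order(tt); tt <- tt[o]; yy <- yy[o]
    met <- traces$metabolite[ix[1]]
    correct <- if (is.null(baseline_metabolites)) {
      needs_baseline(tt, yy, rel_tol = drift_rel_tol)
    } else if (identical(baseline_metabolites, "all")) TRUE
    else if (identical(baseline_metabolites, "none")) FALSE
    else met %in% baseline_metabolites
    bl <- if (correct) asls_baseline(yy, asls_cfg) else 0
    data.frame(well = traces$well[ix[1]], metabolite = met,
               area = integrate_area(tt, yy, bl),
               baseline_corrected = correct, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  meta <- as.data.frame(layout)[, c("well", "treatment", "block", "batch",
                                    "glucose_pct", "nh4cl_mM")]
  tab <- merge(tab, meta, by = "well", sort = FALSE)
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' Apply IQR outlier filtering per replicate group
#'
#' Filtering is applied within each treatment x metabolite x batch replicate
#' group (the natural replication unit of the block design).
#'
#' @param tab an `abundance_table` (from [integrate_plate()]).
#' @param cfg an [outlier_config()].
#' @return the table with a logical `kept` column.
#' @export
filter_outliers <- function(tab, cfg = outlier_config()) {
  if (nrow(tab) == 0) { tab$kept <- logical(0); return(tab) }
  tab$kept <- TRUE
  key <- interaction(tab$treatment, tab$metabolite, tab$batch, drop = TRUE)
  for (ix in split(seq_len(nrow(tab)), key)) {
    tab$kept[ix] <- iqr_filter(tab$area[ix], cfg)
  }
  tab
}

#' Normalise abundances to the per-batch M9 reference
#'
#' Divides every kept area by the mean kept area of the `M9_reference`
#' wells of the same batch and metabolite, so the M9 wells of each batch
#' average to a relative abundance of exactly 1.
#'
#' @param tab an `abundance_table` with a `kept` column (see
#'   [filter_outliers()]); a missing `kept` column keeps everything.
#' @return a `rel_abundance_table` with a `rel_abundance` column.
#' @export
normalise_to_m9 <- function(tab) {
  if (nrow(tab) == 0) {
    tab$rel_abundance <- numeric(0)
    class(tab) <- c("rel_abundance_table", class(tab))
    return(tab)
  }
  if (is.null(tab$kept)) tab$kept <- TRUE
  tab$rel_abundance <- NA_real_
  key <- interaction(tab$metabolite, tab$batch, drop = TRUE)
  for (ix in split(seq_len(nrow(tab)), key)) {
    m9 <- ix[tab$treatment[ix] == "M9_reference" & tab$kept[ix]]
    if (length(m9) == 0) {
      stop(sprintf("no surviving M9_reference wells for metabolite '%s', batch %s",
                   tab$metabolite[ix[1]], tab$batch[ix[1]]))
    }
    tab$rel_abundance[ix] <- tab$area[ix] / mean(tab$area[m9])
  }
  class(tab) <- unique(c("rel_abundance_table", class(tab)))
  tab
}

#' Process a full plate of traces into relative abundances
#'
#' Chains baseline correction, trapezoid integration, per-group IQR outlier
#' filtering and per-batch M9 normalisation.
#'
#' @inheritParams integrate_plate
#' @param outlier_cfg an [outlier_config()].
#' @return a `rel_abundance_table`; attribute `qc` records per-group removal
#'   counts and the quartile convention.
#' @export
process_plate <- function(traces, layout, asls_cfg = asls_config(),
                          outlier_cfg = outlier_config(),
                          baseline_metabolites = NULL, drift_rel_tol = 0.005) {
  tab <- integrate_plate(traces, layout, asls_cfg, baseline_metabolites, drift_rel_tol)
  if (nrow(tab) == 0) {
    tab$kept <- logical(0); tab$rel_abundance <- numeric(0)
    class(tab) <- unique(c("rel_abundance_table", class(tab)))
    return(tab)
  }
  tab <- filter_outliers(tab, outlier_cfg)
  rel <- normalise_to_m9(tab)
  qc <- stats::aggregate(list(n = !rel$kept),
                         by = list(treatment = rel$treatment, metabolite = rel$metabolite),
                         FUN = sum)
  names(qc)[3] <- "n_removed"
  attr(rel, "qc") <- list(removed = qc[qc$n_removed > 0, , drop = FALSE],
                          n_removed_total = sum(!rel$kept),
                          quartile_convention = "linear interpolation (type 7)")
  rel
}

#' Summarise relative abundances per condition
#'
#' Collapses kept wells to per-treatment replicate means with squared
#' standard errors (SEM^2), the observation-noise variances consumed by the
#' heteroskedastic surrogate.
#'
#' @param rel a `rel_abundance_table`.
#' @param metabolite signal to summarise (default `"surfactin_C"`).
#' @param include_control keep the control treatment row (default FALSE).
#' @return data.frame `treatment, glucose_pct, nh4cl_mM, mean_rel, sem2, n`.
#' @export
condition_summary <- function(rel, metabolite = "surfactin_C", include_control = FALSE) {
  d <- rel[rel$metabolite == metabolite & rel$kept, , drop = FALSE]
  if (!include_control) d <- d[d$treatment != "control", , drop = FALSE]
  out <- lapply(split(d, d$treatment, drop = TRUE), function(g) {
    n <- nrow(g)
    data.frame(treatment = g$treatment[1],
               glucose_pct = g$glucose_pct[1], nh4cl_mM = g$nh4cl_mM[1],
               mean_rel = mean(g$rel_abundance),
               sem2 = if (n > 1) stats::var(g$rel_abundance) / n else 0,
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname process_plate
#' @param rel table to write.
#' @param path file path.
#' @export
write_rel_abundance_csv <- function(rel, path) {
  utils::write.csv(as.data.frame(rel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname process_plate
#' @export
read_rel_abundance_csv <- function(path) {
  rel <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(rel) <- c("rel_abundance_table", "abundance_table", "data.frame")
  rel
}
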