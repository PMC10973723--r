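# DBTL loop orchestration: Design (LHD / qNEI batches) -> Build (simulated
# plates) -> Test (trace processing) -> Learn (GP refit), with uncertainty
# maps, best-observed tracking and the performance cliff.

#' Loop configuration
#'
#' @param n_iterations number of DBTL iterations (default 3, labelled 0..2).
#' @param batch_q combinations proposed per iteration (default 7).
#' @param n_blocks plate blocks / biological replicates (default 6).
#' @param grid_res landscape/uncertainty grid resolution (default 101).
#' @param seed root seed; all stage streams derive from it.
#' @param space the [design_space()].
#' @param titre_spec ground-truth [surface_spec()] for the simulator.
#' @param noise a [noise_spec()].
#' @param acq an [acq_config()] for iterations >= 1. The loop default uses a
#'   512-point pool with 2048 MC samples: ample for a 2-D space and sized so
#'   that replicated multi-seed studies stay quick.
#' @param fit a [gp_fit_config()].
#' @param include_m9_point include the M9 reference condition (relative
#'   titre 1 with its replicate SEM) as a GP training point.
#' @return object of class `loop_config`.
#' @export
loop_config <- function(n_iterations = 3, batch_q = 7, n_blocks = 6,
                        grid_res = 101, seed = 1, space = design_space(),
                        titre_spec = surface_spec(), noise = noise_spec(),
                        acq = acq_config(pool_size = 512, mc_samples = 2048),
                        fit = gp_fit_config(), include_m9_point = TRUE) {
  stopifnot(n_iterations >= 1, batch_q >= 1, n_blocks >= 1, grid_res >= 2)
  structure(list(n_iterations = as.integer(n_iterations),
                 batch_q = as.integer(batch_q), n_blocks = as.integer(n_blocks),
                 grid_res = as.integer(grid_res), seed = as.integer(seed),
                 space = space, titre_spec = titre_spec, noise = noise,
                 acq = acq, fit = fit, include_m9_point = include_m9_point),
            class = "loop_config")
}

#' Performance-cliff configuration
#'
#' @param threshold relative titre below which the landscape is considered
#'   to have fallen off the performance cliff (default 0.5, i.e. half the M9
#'   baseline titre).
#' @return object of class `cliff_config`.
#' @export
cliff_config <- function(threshold = 0.5) {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold), class = "cliff_config")
}

#' Regular prediction grid over the design space
#'
#' @param space a [design_space()].
#' @param res points per axis.
#' @return data.frame of `res^2` compositions (glucose varying fastest).
#' @export
make_grid <- function(space = design_space(), res = 101) {
  g <- seq(space$lo[1], space$hi[1], length.out = res)
  n <- seq(space$lo[2], space$hi[2], length.out = res)
  out <- expand.grid(glucose_pct = g, nh4cl_mM = n, KEEP.OUT.ATTRS = FALSE)
  attr(out, "res") <- res
  out
}

#' Posterior landscape and uncertainty map on a grid
#'
#' @param model a fitted `gp_model`.
#' @param grid a grid from [make_grid()].
#' @return a `landscape_grid`: the grid with `mean` and `sd` (posterior sd
#'   of the latent mean) columns.
#' @export
uncertainty_map <- function(model, grid) {
  pr <- stats::predict(model, grid, se = TRUE)
  out <- cbind(as.data.frame(grid), mean = pr$mean, sd = pr$sd)
  attr(out, "res") <- attr(grid, "res")
  class(out) <- c("landscape_grid", "data.frame")
  out
}

#' @rdname uncertainty_map
#' @param landscape a `landscape_grid`.
#' @return `mean_uncertainty`: the arithmetic mean posterior sd over the grid.
#' @export
mean_uncertainty <- function(landscape) {
  mean(landscape$sd)
}

#' Compare model uncertainty on a shared grid
#'
#' @param models list of fitted `gp_model`s.
#' @param grid the shared prediction grid.
#' @return named numeric vector of mean grid uncertainties.
#' @export
compare_uncertainty <- function(models, grid) {
  vapply(models, function(m) mean_uncertainty(uncertainty_map(m, grid)), numeric(1))
}

#' Performance-cliff extraction
#'
#' @param landscape a `landscape_grid` (with a `mean` column).
#' @param cfg a [cliff_config()].
#' @return list with `mask` (logical, mean < threshold), `area_fraction`
#'   (masked cells / total), and `boundary` (list of contour polylines at
#'   the threshold, marching-squares style).
#' @export
performance_cliff <- function(landscape, cfg = cliff_config()) {
  stopifnot(!is.null(landscape$mean))
  mask <- landscape$mean < cfg$threshold
  res_x <- length(unique(landscape$glucose_pct))
  res_y <- length(unique(landscape$nh4cl_mM))
  boundary <- list()
  if (res_x >= 2 && res_y >= 2 && res_x * res_y == nrow(landscape)) {
    z <- matrix(landscape$mean, nrow = res_x)
    cl <- grDevices::contourLines(sort(unique(landscape$glucose_pct)),
                                  sort(unique(landscape$nh4cl_mM)),
                                  z, levels = cfg$threshold)
    boundary <- lapply(cl, function(s) data.frame(glucose_pct = s$x, nh4cl_mM = s$y))
  }
  list(mask = mask, area_fraction = mean(mask), boundary = boundary)
}

#' Run the full active-learning loop on the simulator
#'
#' Iteration 0 designs by centred Latin hypercube; later iterations by
#' greedy qNEI batches from the current surrogate. Every iteration builds a
#' block-randomised plate, simulates its injection traces, processes them to
#' a relative-abundance table, refits the heteroskedastic GP on all
#' condition summaries so far, and records the landscape and mean grid
#' uncertainty. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [loop_config()].
#' @param surface optional ground-truth titre surface (defaults to
#'   `make_landscape(cfg$titre_spec, cfg$space)`).
#' @param state_dir optional directory; per-iteration artefacts (design,
#'   relative abundances, model JSON, grid CSV, manifest) are persisted
#'   there, including on stage failure.
#' @return a `loop_state`: list with per-iteration records, the accumulated
#'   condition table, the final model, and the cumulative best observed
#'   condition.
#' @export
run_loop <- function(cfg = loop_config(), surface = NULL, state_dir = NULL) {
  stopifnot(inherits(cfg, "loop_config"))
  surface <- surface %||% make_landscape(cfg$titre_spec, cfg$space)
  grid <- make_grid(cfg$space, cfg$grid_res)
  iterations <- list()
  conditions <- NULL
  model <- NULL
  persist <- function() {
    if (is.null(state_dir)) return(invisible(NULL))
    save_loop_state(list(iterations = iterations, conditions = conditions,
                         config_seed = cfg$seed), state_dir)
  }
  stage <- function(it, name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop(sprintf("DBTL loop failed at iteration %d, stage '%s': %s",
                   it, name, conditionMessage(e)), call. = FALSE)
    })
  }
  for (it in seq_len(cfg$n_iterations) - 1L) {
    design <- stage(it, "design", {
      if (it == 0L) {
        latin_hypercube(cfg$batch_q, cfg$space, derive_seed(cfg$seed, it, 1))
      } else {
        acq <- cfg$acq
        acq$seed <- derive_seed(cfg$seed, it, 1)
        acq$q <- cfg$batch_q
        as.data.frame(propose_batch(model, cfg$space, acq))
      }
    })
    treatments <- media_treatments(design, baseline = cfg$titre_spec$baseline)
    layout <- stage(it, "build", {
      block_randomised_layout(treatments, cfg$n_blocks,
                              seed = derive_seed(cfg$seed, it, 2), batch = it)
    })
    rel <- stage(it, "test", {
      traces <- simulate_plate(layout, surface, cfg$noise,
                               seed = derive_seed(cfg$seed, it, 3))
      process_plate(traces, layout)
    })
    cond <- condition_summary(rel, metabolite = "surfactin_C")
    cond$iteration <- it
    if (!cfg$include_m9_point) cond <- cond[cond$treatment != "M9_reference", ]
    conditions <- rbind(conditions, cond)
    model <- stage(it, "learn", {
      ds <- gp_dataset(conditions[, c("glucose_pct", "nh4cl_mM")],
                       conditions$mean_rel, conditions$sem2, cfg$space)
      fitc <- cfg$fit
      fitc$seed <- derive_seed(cfg$seed, it, 4)
      fit_gp(ds, fitc)
    })
    landscape <- uncertainty_map(model, grid)
    best_idx <- which.max(conditions$mean_rel)
    iterations[[it + 1L]] <- list(
      iteration = it, design = design, layout = layout, rel_table = rel,
      model = model, landscape = landscape,
      mean_sd = mean_uncertainty(landscape),
      best_so_far = list(value = conditions$mean_rel[best_idx],
                         glucose_pct = conditions$glucose_pct[best_idx],
                         nh4cl_mM = conditions$nh4cl_mM[best_idx]))
  }
  best_idx <- which.max(conditions$mean_rel)
  state <- structure(list(
    iterations = iterations, conditions = conditions, model = model,
    grid = grid, config = cfg, surface = surface,
    best = list(value = conditions$mean_rel[best_idx],
                glucose_pct = conditions$glucose_pct[best_idx],
                nh4cl_mM = conditions$nh4cl_mM[best_idx])),
    class = "loop_state")
  if (!is.null(state_dir)) persist()
  state
}

#' Best observed titre improvement over the M9 baseline
#'
#' `100 * (best observed replicate-mean relative titre - 1)`, reported with
#' the composition achieving it. A relative titre of 2.6 corresponds to a
#' 160 % improvement.
#'
#' @param state a `loop_state` (or a persisted-state list from
#'   [load_loop_state()]).
#' @return list with `improvement_pct`, `best_value`, `glucose_pct`,
#'   `nh4cl_mM`.
#' @export
best_improvement <- function(state) {
  best <- state$best
  if (is.null(best)) {
    idx <- which.max(state$conditions$mean_rel)
    best <- list(value = state$conditions$mean_rel[idx],
                 glucose_pct = state$conditions$glucose_pct[idx],
                 nh4cl_mM = state$conditions$nh4cl_mM[idx])
  }
  list(improvement_pct = 100 * (best$value - 1), best_value = best$value,
       glucose_pct = best$glucose_pct, nh4cl_mM = best$nh4cl_mM)
}

#' Model-predicted optimal composition
#'
#' The argmax of the posterior mean over a dense grid (the cross marked on
#' the final landscape), as opposed to the best *observed* condition used by
#' [best_improvement()].
#'
#' @param model a fitted `gp_model`.
#' @param space the [design_space()].
#' @param res grid resolution.
#' @return list with `glucose_pct`, `nh4cl_mM`, `predicted_titre`.
#' @export
predicted_optimum <- function(model, space = design_space(), res = 201) {
  grid <- make_grid(space, res)
  mu <- stats::predict(model, grid, se = FALSE)$mean
  i <- which.max(mu)
  list(glucose_pct = grid$glucose_pct[i], nh4cl_mM = grid$nh4cl_mM[i],
       predicted_titre = mu[i])
}

#' Persist / reload loop state
#'
#' Writes per-iteration subfolders (design and relative-abundance CSVs,
#' model JSON, landscape CSV) plus a manifest JSON with seeds and summary
#' quantities. Only plain-text artefacts are written.
#'
#' @param state a `loop_state` (or partial-state list).
#' @param dir output directory.
#' @return `load_loop_state` returns a list with the manifest, the condition
#'   table and the refitted final model.
#' @export
save_loop_state <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in state$iterations) {
    sub <- file.path(dir, sprintf("iteration_%d", rec$iteration))
    dir.create(sub, showWarnings = FALSE)
    utils::write.csv(rec$design, file.path(sub, "design.csv"), row.names = FALSE)
    write_rel_abundance_csv(rec$rel_table, file.path(sub, "rel_abundance.csv"))
    gp_to_json(rec$model, file.path(sub, "model.json"))
    utils::write.csv(as.data.frame(rec$landscape), file.path(sub, "landscape.csv"),
                     row.names = FALSE)
  }
  if (!is.null(state$conditions)) {
    utils::write.csv(state$conditions, file.path(dir, "conditions.csv"), row.names = FALSE)
  }
  manifest <- list(
    seed = if (!is.null(state$config)) state$config$seed else state$config_seed,
    n_iterations = length(state$iterations),
    mean_sd = vapply(state$iterations, function(r) r$mean_sd, numeric(1)),
    best = state$best, package_version = as.character(utils::packageVersion("mediaopt")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_loop_state
#' @param dir state directory written by [save_loop_state()].
#' @export
load_loop_state <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  conditions <- utils::read.csv(file.path(dir, "conditions.csv"), stringsAsFactors = FALSE)
  last <- file.path(dir, sprintf("iteration_%d", manifest$n_iterations - 1))
  model <- if (file.exists(file.path(last, "model.json"))) {
    gp_from_json(file.path(last, "model.json"))
  } else NULL
  list(manifest = manifest, conditions = conditions, model = model)
}
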