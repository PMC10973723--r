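# Experimental design: design space, centred Latin hypercube, and
# block-randomised 96-well plate layouts.

#' Define the 2-D media design space
#'
#' The design space spans glucose (% w/v) and ammonium chloride (mM)
#' concentrations. Defaults contain both the optimum found by the active
#' learning study (0.8 % / 50 mM) and the literature optimum (0.8 % / 100 mM).
#'
#' @param glucose length-2 numeric, lower/upper glucose bound in % w/v.
#' @param nh4cl length-2 numeric, lower/upper NH4Cl bound in mM.
#' @return an object of class `design_space` with `lo` and `hi` vectors.
#' @export
design_space <- function(glucose = c(0.1, 2.0), nh4cl = c(5, 120)) {
  stopifnot(length(glucose) == 2L, length(nh4cl) == 2L)
  lo <- c(glucose_pct = glucose[1], nh4cl_mM = nh4cl[1])
  hi <- c(glucose_pct = glucose[2], nh4cl_mM = nh4cl[2])
  if (any(lo >= hi)) stop("design_space requires lo < hi on both axes")
  structure(list(lo = lo, hi = hi), class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("design space: glucose [%g, %g] %% w/v; NH4Cl [%g, %g] mM\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2]))
  invisible(x)
}

# Map compositions to/from the unit square.
to_unit <- function(X, space) {
  X <- as_composition_matrix(X)
  sweep(sweep(X, 2, space$lo, "-"), 2, space$hi - space$lo, "/")
}
from_unit <- function(U, space) {
  U <- as.matrix(U)
  X <- sweep(sweep(U, 2, space$hi - space$lo, "*"), 2, space$lo, "+")
  colnames(X) <- c("glucose_pct", "nh4cl_mM")
  X
}

in_space <- function(X, space, tol = 1e-9) {
  U <- to_unit(X, space)
  apply(U >= -tol & U <= 1 + tol, 1, all)
}

#' Centred Latin hypercube design
#'
#' Each axis is split into `n` equal bins; the design places one point per
#' bin per axis at the bin centre, with the bin-to-bin pairing given by
#' seeded uniform permutations. Every axis projection therefore occupies
#' each of the `n` bins exactly once.
#'
#' @param n number of design points (>= 1).
#' @param space a [design_space()].
#' @param seed integer seed fixing the permutations.
#' @return data.frame with columns `glucose_pct`, `nh4cl_mM`.
#' @export
latin_hypercube <- function(n, space = design_space(), seed = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  perms <- with_seed_(seed, list(sample.int(n), sample.int(n)))
  centres <- function(p) (p - 0.5) / n
  U <- cbind(centres(perms[[1]]), centres(perms[[2]]))
  as.data.frame(from_unit(U, space))
}

#' Build the treatment table for one loop iteration
#'
#' Combines the proposed media combinations with the two reference
#' treatments used on every plate: `M9_reference` (complete M9: baseline
#' glucose/NH4Cl) and `control` (M9 salts with no added carbon/nitrogen
#' source; it carries no composition in the design space).
#'
#' @param combinations data.frame of compositions (glucose_pct, nh4cl_mM).
#' @param baseline length-2 numeric, the M9 baseline composition.
#' @return data.frame with columns `treatment`, `glucose_pct`, `nh4cl_mM`.
#' @export
media_treatments <- function(combinations, baseline = c(0.4, 18.7)) {
  X <- as_composition_matrix(combinations)
  data.frame(
    treatment = c(sprintf("combination_%d", seq_len(nrow(X))), "control", "M9_reference"),
    glucose_pct = c(X[, 1], NA_real_, baseline[1]),
    nh4cl_mM = c(X[, 2], NA_real_, baseline[2]),
    stringsAsFactors = FALSE
  )
}

#' Block-randomised 96-well plate layout
#'
#' Randomised complete block design: wells of an 8 x 12 plate are taken in
#' row-major (or column-major) order and partitioned into `n_blocks`
#' contiguous runs of one well per treatment; within each block the
#' treatment order is an independent seeded permutation. Blocks correspond
#' to biological replicates.
#'
#' @param treatments data.frame as from [media_treatments()] (columns
#'   `treatment`, `glucose_pct`, `nh4cl_mM`).
#' @param n_blocks number of blocks/replicates (default 6).
#' @param seed integer root seed; per-block streams are derived from it so
#'   layouts are stable under block-count changes.
#' @param batch batch identifier stored with every well (default 1).
#' @param order well-filling order, `"row"` or `"column"` major.
#' @return a `plate_layout`: data.frame with columns
#'   `well,row,col,treatment,block,glucose_pct,nh4cl_mM,batch`.
#' @export
block_randomised_layout <- function(treatments, n_blocks = 6, seed = 1,
                                    batch = 1, order = c("row", "column")) {
  order <- match.arg(order)
  stopifnot(is.data.frame(treatments), "treatment" %in% names(treatments))
  q <- nrow(treatments)
  need <- q * n_blocks
  if (need > 96) {
    stop(sprintf("plate capacity exceeded: %d treatments x %d blocks = %d wells needed, 96 available",
                 q, n_blocks, need))
  }
  rows <- LETTERS[1:8]
  if (order == "row") {
    rr <- rep(rows, each = 12); cc <- rep(1:12, times = 8)
  } else {
    rr <- rep(rows, times = 12); cc <- rep(1:12, each = 8)
  }
  wells <- paste0(rr, cc)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    perm <- with_seed_(derive_seed(seed, b), sample.int(q))
    idx <- (b - 1L) * q + seq_len(q)
    out[[b]] <- data.frame(
      well = wells[idx], row = rr[idx], col = cc[idx],
      treatment = treatments$treatment[perm],
      block = b,
      glucose_pct = treatments$glucose_pct[perm],
      nh4cl_mM = treatments$nh4cl_mM[perm],
      batch = batch, stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Audit a plate layout's block structure
#'
#' @param layout a `plate_layout`.
#' @return the treatment x block incidence matrix (counts).
#' @export
layout_incidence <- function(layout) {
  table(layout$treatment, layout$block)
}

#' @rdname block_randomised_layout
#' @param layout a `plate_layout` to write.
#' @param path file path.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname block_randomised_layout
#' @export
read_layout_csv <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}
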