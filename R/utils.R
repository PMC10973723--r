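#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed
#'
#' Mixes a root seed with an arbitrary sequence of integer tags (iteration
#' number, stage index, block id, ...) into a new seed below 2^31, so that
#' every stochastic stage of the pipeline draws from its own stream while
#' remaining fully determined by one root seed.
#'
#' @param root integer root seed.
#' @param ... integer tags identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, ...) {
  ks <- c(root, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 12345) %% 2147483647
  as.integer(h)
}

# Run code with a local RNG state (never disturbs the caller's stream).
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Halton radical-inverse sequence with a seeded random shift (mod 1):
# deterministic low-discrepancy candidate pools.
halton_seq <- function(n, base, shift = 0) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; r <- 0; k <- i
    while (k > 0) {
      f <- f / base
      r <- r + f * (k %% base)
      k <- k %/% base
    }
    out[i] <- r
  }
  (out + shift) %% 1
}

# 2-D space-filling pool on [0,1]^2, seeded via the shift.
halton_pool <- function(n, seed) {
  sh <- with_seed_(seed, stats::runif(2))
  cbind(halton_seq(n, 2, sh[1]), halton_seq(n, 3, sh[2]))
}

# Coerce compositions to a 2-column matrix (glucose_pct, nh4cl_mM).
as_composition_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("glucose_pct", "nh4cl_mM") %in% names(x)))
    x <- cbind(x$glucose_pct, x$nh4cl_mM)
  } else if (is.null(dim(x))) {
    stopifnot(length(x) == 2L)
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L)
  colnames(x) <- c("glucose_pct", "nh4cl_mM")
  x
}

# Evaluate the posterior/true mean of a "surface" at compositions X.
# Accepts a plain function (rows of X -> values), a surface_function,
# or a fitted gp_model.
surface_mean <- function(object, X) {
  X <- as_composition_matrix(X)
  if (inherits(object, "gp_model")) {
    stats::predict(object, X, se = FALSE)$mean
  } else if (is.function(object)) {
    object(X)
  } else {
    stop("cannot evaluate object of class ", paste(class(object), collapse = "/"))
  }
}
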