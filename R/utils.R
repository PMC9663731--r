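# Internal helpers shared across modules.

sigmoid <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

# Deterministic per-stage seed derived from a single global seed. Kept
# strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

# Predictor column names of an encoded table (everything that is not the
# outcome or a bookkeeping column).
predictor_cols <- function(data, outcome = attr(data, "outcome") %||% "outcome") {
  setdiff(names(data), c(outcome, ".imp", ".id"))
}

as_numeric_matrix <- function(data, cols) {
  m <- as.matrix(as.data.frame(data)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Piecewise-linear interpolation with linear extrapolation from the two
# terminal grid points on each side. `grid` must be strictly increasing.
interp_linear <- function(grid, values, x) {
  n <- length(grid)
  if (n == 1L) return(rep(values, length(x)))
  i <- findInterval(x, grid, all.inside = TRUE)
  x0 <- grid[i]; x1 <- grid[i + 1L]
  y0 <- values[i]; y1 <- values[i + 1L]
  y0 + (x - x0) * (y1 - y0) / (x1 - x0)
}

check_binary <- function(x, name = "outcome") {
  x <- x[!is.na(x)]
  if (!all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 values.", name))
  }
  invisible(TRUE)
}
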