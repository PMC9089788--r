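#' @keywords internal
"_PACKAGE"

## Condition helpers -------------------------------------------------------

stop_atriakit <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "atriakit_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

config_error <- function(msg, ...) stop_atriakit("atriakit_config_error", msg, ...)
format_error <- function(msg, ...) stop_atriakit("atriakit_format_error", msg, ...)

## Randomness --------------------------------------------------------------

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Every stochastic generator funnels
# through this so that identical (preset, seed) calls are bit-identical and
# no global RNG state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for sub-streams, kept below 2^31.
child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647
}

## Numeric helpers ---------------------------------------------------------

# Vertex of the parabola through (-1, y0), (0, y1), (1, y2); returns
# c(offset, value).  Degenerate (non-concave) fits fall back to the centre
# sample; offsets are clamped to half a sample so flat-topped profiles under
# noise cannot throw the estimate outside the bracketing samples.
parabolic_vertex <- function(y0, y1, y2) {
  a <- (y0 - 2 * y1 + y2) / 2
  b <- (y2 - y0) / 2
  if (!is.finite(a) || a >= -1e-12) {
    return(c(0, y1))
  }
  x <- -b / (2 * a)
  x <- max(-0.5, min(0.5, x))
  c(x, y1 + b * x + a * x^2)
}

# Index of the maximum with plateau-centre tie-breaking: exact ties (to
# within `tol` of the max) are resolved to the middle of the leading
# plateau, so a sampled flat-topped derivative is dated at its centre.
which_max_plateau <- function(x, tol = 1e-12) {
  m <- max(x)
  idx <- which(x >= m - tol * max(1, abs(m)))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  first <- runs[[1L]]
  first[ceiling(length(first) / 2)]
}

# First index at which `x` drops below `level` at or after `from`; linear
# interpolation between the bracketing samples.  NA when never crossed.
first_crossing_below <- function(x, level, from) {
  n <- length(x)
  if (from >= n) return(NA_real_)
  below <- which(x[(from + 1L):n] < level)
  if (!length(below)) return(NA_real_)
  i <- from + below[1L]          # first sample below level
  x0 <- x[i - 1L]; x1 <- x[i]
  if (!is.finite(x0) || !is.finite(x1) || x0 == x1) return(i - 1)
  (i - 1) + (x0 - level) / (x0 - x1) * 1  # 1-based fractional index
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
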