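# Internal helpers shared across modules.

# round-half-up: coherent/majority counts use commercial rounding so that
# e.g. 0.625 * 8 -> 5, independent of IEEE round-half-even. With the standard
# grids (multiples of 5% at n = 100) the products are exact integers anyway.
round_half_up <- function(x) floor(x + 0.5)

# Wrap a coordinate into [0, side).
wrap_coord <- function(x, side) x %% side

# Smallest signed displacement on a circle of circumference `side`
# (maps raw differences into (-side/2, side/2]).
wrap_delta <- function(dx, side) {
  ((dx + side / 2) %% side) - side / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Draw a seed for a sub-stream from a parent seed, keeping within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 11 * k) %% 2147483587L) + 1L
}

# Longest run of identical values in a vector.
max_run_length <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(as.character(x))$lengths)
}
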