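# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-frame child seed from a base seed; stays within 32-bit range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + as.numeric(k) * 7919) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# smallest odd integer >= x
odd_ceiling <- function(x) {
  n <- ceiling(x)
  if (n %% 2 == 0) n + 1 else n
}

is_gray_image <- function(x) is.matrix(x) && is.numeric(x) && all(dim(x) > 0)

assert_gray_image <- function(x, arg = "image") {
  if (!is_gray_image(x)) abort(sprintf("`%s` must be a non-empty numeric matrix", arg))
  invisible(x)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
bilinear_at <- function(m, row, col) {
  H <- nrow(m); W <- ncol(m)
  r <- clamp(row, 1, H); c <- clamp(col, 1, W)
  r0 <- clamp(floor(r), 1, H - 1L); c0 <- clamp(floor(c), 1, W - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
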