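# Internal grid helpers shared by the filtering and level-set code.
# All fields are plain numeric matrices indexed [row, col], row 1 at the top.

# Shift a matrix by (dr, dc) with replicate (Neumann) padding: the value at
# [i, j] of the result is x[i + dr, j + dc] clamped to the frame.
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x)
  nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

# Central differences on the unit grid, replicate boundaries.
grad_x <- function(x) (shift_mat(x, 0L, 1L) - shift_mat(x, 0L, -1L)) / 2
grad_y <- function(x) (shift_mat(x, 1L, 0L) - shift_mat(x, -1L, 0L)) / 2

# 5-point discrete Laplacian, Neumann boundaries.
laplacian5 <- function(x) {
  shift_mat(x, 1L, 0L) + shift_mat(x, -1L, 0L) +
    shift_mat(x, 0L, 1L) + shift_mat(x, 0L, -1L) - 4 * x
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  t <- seq.int(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate padding; kernel sums to one so
# flat fields are exact fixed points.
gaussian_blur <- function(x, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma, radius)
  offs <- seq.int(-radius, radius)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(offs)) out <- out + k[i] * shift_mat(x, offs[i], 0L)
  x <- out
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(offs)) out <- out + k[i] * shift_mat(x, 0L, offs[i])
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Binary morphology on logical matrices. Dilation uses the 8-neighbourhood
# (3x3 structuring element), erosion the 4-neighbourhood.
dilate8 <- function(m) {
  m <- m != 0
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | shift_mat_logical(m, dr, dc)
  }
  out
}

erode4 <- function(m) {
  m <- m != 0
  m &
    shift_mat_logical(m, 1L, 0L) & shift_mat_logical(m, -1L, 0L) &
    shift_mat_logical(m, 0L, 1L) & shift_mat_logical(m, 0L, -1L)
}

# Replicate padding is wrong for morphology at the frame edge (a pixel outside
# the frame counts as background), so pad logically with FALSE.
shift_mat_logical <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  keep_r <- rs >= 1L & rs <= nr
  keep_c <- cs >= 1L & cs <= nc
  out[keep_r, keep_c] <- m[rs[keep_r], cs[keep_c]]
  out
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}
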