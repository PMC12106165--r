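#  Internal helpers: validation, seeded RNG scoping, quadrature, geometry.

abort <- function(...) stop(..., call. = FALSE)

is_point <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))

#' Derive a per-item seed from a master seed
#'
#' Deterministic linear-congruential mix, kept below 2^31 so the result is a
#' valid R integer seed.
#'
#' @param master integer master seed.
#' @param i item index (1-based).
#' @return integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + i * 1009) %% 2147483629)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Composite Simpson quadrature of a vectorised function on [a, b].
simpson <- function(f, a, b, n = 2000L) {
  if (b <= a) return(0)
  n <- if (n %% 2L == 1L) n + 1L else n
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

# Arc length of y(x) with derivative dy on [a, b].
arc_length <- function(dy, a, b, n = 2000L) {
  simpson(function(x) sqrt(1 + dy(x)^2), a, b, n)
}

logistic_score <- function(margin, slope) plogis(margin / slope)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Clamp a half-open box c(x0,y0,x1,y1) to an image of dim c(h, w).
clamp_box <- function(box, dim_hw) {
  c(clamp(box[1], 0, dim_hw[2]), clamp(box[2], 0, dim_hw[1]),
    clamp(box[3], 0, dim_hw[2]), clamp(box[4], 0, dim_hw[1]))
}

box_area <- function(box) max(0, box[3] - box[1]) * max(0, box[4] - box[2])

# Crop a matrix (or H x W x 3 array) by a half-open 0-based box.
crop_box <- function(m, box) {
  rows <- (box[2] + 1L):box[4]
  cols <- (box[1] + 1L):box[3]
  if (length(dim(m)) == 3L) m[rows, cols, , drop = FALSE] else m[rows, cols, drop = FALSE]
}

# Stable 32-bit FNV-1a hash of a character scalar, as hex (config digests).
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# round() in R is already round-half-to-even (IEEE 754); alias for clarity
# where the rounding rule is part of a documented contract.
round_half_even <- function(x) round(x)
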