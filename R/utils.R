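# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

DEG <- 180 / pi

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap to [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# wrap to (-180, 180]
wrap180 <- function(x) {
  x <- wrap360(x)
  ifelse(x > 180, x - 360, x)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

# unsigned angle between two vectors, degrees
angle_between <- function(a, b) {
  rad2deg(atan2(abs(cross2(a, b)), sum(a * b)))
}

# round half away from zero at d decimals (the convention used when
# comparing against the printed tables, which round 0.5 up)
round_half_up <- function(x, d = 2) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_missing_num <- function(x) is.null(x) || length(x) == 0L || is.na(x)

# run expr with a local RNG state seeded from `seed` (NULL = use current
# stream); restores the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

num_or_na <- function(x) {
  if (is_missing_num(x)) NA_real_ else as.numeric(x)
}
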