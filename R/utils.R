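# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a reproducible child seed; double arithmetic stays exact below
# 2^53 and the modulus keeps the result inside R's 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483629)
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

# rows of `m` normalized to unit length
unit_rows <- function(m) m / sqrt(rowSums(m^2))

# rotation matrix for angle `ang` about unit axis `ax` (Rodrigues)
rotation_about <- function(ax, ang) {
  ax <- unit(ax)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

stop_megshield <- function(...) stop(..., call. = FALSE)
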