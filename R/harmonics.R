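#' Vector spherical harmonic machinery
#'
#' The SSS family of methods expands the measured field in two truncated
#' series of multipole fields `B = -grad(psi)`, with interior potentials
#' `psi_in(l,m) = Y_lm(theta, phi) / r^(l+1)` (sources inside the helmet,
#' valid outside them) and exterior potentials `psi_out(l,m) = r^l *
#' Y_lm(theta, phi)` (sources outside, valid inside). The degree-0 term is
#' omitted since it vanishes for magnetic fields. `Y_lm` here are *real*
#' spherical harmonics, orthonormal over the sphere, without the
#' Condon-Shortley phase:
#' `Y_lm = N_lm P_l^|m|(cos theta) * {sqrt(2) cos(m phi), 1, sqrt(2)
#' sin(|m| phi)}` for `m > 0`, `m = 0`, `m < 0`. Any fixed self-consistent
#' convention spans the same signal subspaces; this one is verified against
#' numerical quadrature in the test suite. Field values carry an arbitrary
#' fixed multiplicative constant (set to 1); column normalization of the
#' basis makes all downstream quantities independent of it.
#'
#' @name harmonics
NULL

# associated Legendre P_l^m(x) (no Condon-Shortley phase) and theta
# derivative dP/dtheta for all l = 0..L, m = 0..l; vectorized over x.
# Returns arrays [n, l+1, m+1].
legendre_tables <- function(x, s, L) {
  n <- length(x)
  P <- array(0, c(n, L + 1, L + 1))
  P[, 1, 1] <- 1
  if (L >= 1) {
    dfact <- 1
    for (m in 0:L) {
      if (m > 0) {
        dfact <- dfact * (2 * m - 1)
        P[, m + 1, m + 1] <- dfact * s^m
      }
      if (m < L) P[, m + 2, m + 1] <- (2 * m + 1) * x * P[, m + 1, m + 1]
      if (m + 2 <= L) {
        for (l in (m + 2):L) {
          P[, l + 1, m + 1] <- ((2 * l - 1) * x * P[, l, m + 1] -
                                  (l + m - 1) * P[, l - 1, m + 1]) / (l - m)
        }
      }
    }
  }
  s_safe <- pmax(s, 1e-300)
  dP <- array(0, c(n, L + 1, L + 1))
  for (l in 1:max(1, L)) {
    if (l > L) break
    for (m in 0:l) {
      Plm1 <- if (l - 1 >= m) P[, l, m + 1] else rep(0, n)
      dP[, l + 1, m + 1] <- (l * x * P[, l + 1, m + 1] -
                               (l + m) * Plm1) / s_safe
    }
  }
  list(P = P, dP = dP)
}

sph_norm_const <- function(l, m) {
  am <- abs(m)
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
}

#' Real orthonormal spherical harmonic
#'
#' Evaluates the real spherical harmonic `Y_lm(theta, phi)` in the package's
#' convention (orthonormal over the sphere, no Condon-Shortley phase).
#' Vectorized over `theta` and `phi`.
#'
#' @param l degree, integer `>= 0`.
#' @param m order, `-l <= m <= l`.
#' @param theta colatitude in radians, `0 <= theta <= pi`.
#' @param phi azimuth in radians.
#' @return numeric vector of harmonic values.
#' @examples
#' real_spherical_harmonic(0, 0, 1, 2)   # 1 / (2 sqrt(pi))
#' @export
real_spherical_harmonic <- function(l, m, theta, phi) {
  if (abs(m) > l) stop_megshield("|m| = ", abs(m), " exceeds l = ", l)
  if (any(theta < -1e-12 | theta > pi + 1e-12)) {
    stop_megshield("theta must lie in [0, pi]")
  }
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  tab <- legendre_tables(cos(theta), sin(theta), l)
  am <- abs(m)
  azim <- if (m > 0) sqrt(2) * cos(m * phi)
          else if (m == 0) rep(1, n)
          else sqrt(2) * sin(am * phi)
  sph_norm_const(l, m) * tab$P[, l + 1, am + 1] * azim
}

# canonical (l, m) ordering of basis columns for one domain
harmonic_index <- function(L, domain) {
  l <- rep(seq_len(L), times = 2 * seq_len(L) + 1)
  m <- unlist(lapply(seq_len(L), function(k) seq(-k, k)))
  data.frame(l = l, m = m, domain = domain)
}

# multipole field B = -grad(psi) at `points` (n x 3, relative to origin
# already subtracted) for all degrees 1..L of one domain.
# Returns an array [n, 3, L(L+2)].
multipole_field_matrix <- function(points, L, domain = c("in", "out")) {
  domain <- match.arg(domain)
  n <- nrow(points)
  r <- sqrt(rowSums(points^2))
  if (domain == "in" && any(r < 1e-12)) {
    stop_megshield("interior multipole field is singular at the origin")
  }
  r_safe <- pmax(r, 1e-300)
  theta <- acos(pmin(1, pmax(-1, points[, 3] / r_safe)))
  theta <- pmin(pmax(theta, 1e-10), pi - 1e-10)  # pole guard
  phi <- atan2(points[, 2], points[, 1])
  x <- cos(theta); s <- sin(theta)
  tab <- legendre_tables(x, s, L)

  cphi <- cos(phi); sphi <- sin(phi)
  rhat <- cbind(s * cphi, s * sphi, x)
  that <- cbind(x * cphi, x * sphi, -s)
  phat <- cbind(-sphi, cphi, 0)

  D <- L * (L + 2)
  out <- array(0, c(n, 3, D))
  for (l in seq_len(L)) {
    rad <- if (domain == "in") r_safe^(-(l + 2)) else r_safe^(l - 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      N <- sph_norm_const(l, m)
      if (m > 0) {
        azim <- sqrt(2) * cos(m * phi); dazim <- -m * sqrt(2) * sin(m * phi)
      } else if (m == 0) {
        azim <- rep(1, n); dazim <- rep(0, n)
      } else {
        azim <- sqrt(2) * sin(am * phi); dazim <- am * sqrt(2) * cos(am * phi)
      }
      Y <- N * tab$P[, l + 1, am + 1] * azim
      dYdt <- N * tab$dP[, l + 1, am + 1] * azim
      dYdp_over_s <- N * tab$P[, l + 1, am + 1] * dazim / s

      if (domain == "in") {
        Br <- (l + 1) * Y * rad; Bt <- -dYdt * rad; Bp <- -dYdp_over_s * rad
      } else {
        Br <- -l * Y * rad; Bt <- -dYdt * rad; Bp <- -dYdp_over_s * rad
      }
      col <- l^2 + l + m
      out[, , col] <- Br * rhat + Bt * that + Bp * phat
    }
  }
  out
}

#' Multipole magnetic field of a single harmonic
#'
#' Field `B = -grad(psi)` of one interior (`domain = "in"`, potential
#' `Y_lm / r^(l+1)`, valid outside the sources) or exterior (`domain =
#' "out"`, potential `r^l Y_lm`, valid inside the source-free region)
#' harmonic, evaluated at a point relative to the expansion origin. The
#' field is curl- and divergence-free in its valid region; values carry a
#' fixed arbitrary constant (documented under [harmonics]).
#'
#' @param l degree `>= 1`; @param m order, `|m| <= l`.
#' @param domain `"in"` or `"out"`.
#' @param point 3-vector (or n x 3 matrix) of positions, meters, relative to
#'   the expansion origin.
#' @return 3-vector (or n x 3 matrix) of field values.
#' @export
multipole_field <- function(l, m, domain, point) {
  if (l < 1) stop_megshield("degree l must be >= 1")
  if (abs(m) > l) stop_megshield("|m| = ", abs(m), " exceeds l = ", l)
  pts <- if (is.matrix(point)) point else matrix(point, 1, 3)
  F <- multipole_field_matrix(pts, l, domain)
  res <- F[, , l^2 + l + m, drop = FALSE]
  dim(res) <- dim(F)[1:2]
  if (is.matrix(point)) res else as.numeric(res)
}

# couple a [n_ip, 3, D] field array to the array's channels:
# channel j, column c: gain_j * sum_i w_i B(r_i, c) . n_j
couple_to_array <- function(array, field) {
  n_ip <- dim(field)[1]; D <- dim(field)[3]
  n_ip_or <- array$orientation[array$ip_channel, , drop = FALSE]
  S_ip <- matrix(0, n_ip, D)
  for (k in 1:3) S_ip <- S_ip + field[, k, ] * n_ip_or[, k]
  S <- rowsum(S_ip * array$ip_w, array$ip_channel)
  dimnames(S) <- NULL
  S * array$gain
}

# per-channel scale making magnetometers (T) and planar gradiometers (T/m)
# numerically commensurate: magnetometer rows divided by a length scale.
channel_scale <- function(array, mag_scale_length) {
  ifelse(is_magnetometer(array), 1 / mag_scale_length, 1)
}

#' Build the SSS basis for a sensor array
#'
#' Assembles the internal (`S_in`, degrees `1..L_in`) and external (`S_out`,
#' degrees `1..L_out`) multipole basis matrices coupled to a sensor array.
#' Element `(j, c)` is the channel-j output for unit-amplitude harmonic `c`:
#' `gain_j * sum_i w_ji B_c(r_ji) . n_j` over the channel's integration
#' points. Before any decomposition the magnetometer rows are divided by
#' `mag_scale_length` so both channel types have commensurate magnitude, and
#' every column is normalized to unit Euclidean norm (normalization factors
#' are retained so multipole moments can be mapped back to physical units).
#'
#' The default truncation orders `L_in = 8`, `L_out = 3` give `80 + 15 = 95`
#' basis vectors, sufficient for SQUID arrays a few centimeters from the
#' scalp.
#'
#' @param array a [meg_sensor_array] (the basis uses its gains: build from
#'   the *nominal* array to emulate imperfect knowledge of a perturbed
#'   device).
#' @param L_in,L_out interior/exterior truncation degrees.
#' @param mag_scale_length length scale (m) dividing magnetometer rows;
#'   default 0.0168 (the planar-gradiometer baseline).
#' @return an object of class `sss_basis` with fields `S_in`, `S_out`
#'   (scaled, column-normalized), `index` (column -> (l, m, domain) map),
#'   `scale`, `col_norms`, and the SVD of the full basis used for
#'   pseudoinversion.
#' @export
build_sss_basis <- function(array, L_in = 8, L_out = 3,
                            mag_scale_length = 0.0168) {
  validate_array(array)
  N <- n_channels(array)
  D_in <- L_in * (L_in + 2); D_out <- L_out * (L_out + 2)
  if (D_in + D_out >= N) {
    stop_megshield("basis dimension ", D_in + D_out,
                   " must be smaller than the channel count ", N)
  }
  pts <- array$ip_pos - matrix(array$origin, nrow(array$ip_pos), 3,
                               byrow = TRUE)
  S_in <- couple_to_array(array, multipole_field_matrix(pts, L_in, "in"))
  S_out <- couple_to_array(array, multipole_field_matrix(pts, L_out, "out"))

  scale <- channel_scale(array, mag_scale_length)
  S_in <- S_in * scale; S_out <- S_out * scale
  norms_in <- sqrt(colSums(S_in^2)); norms_out <- sqrt(colSums(S_out^2))
  S_in <- sweep(S_in, 2, norms_in, "/")
  S_out <- sweep(S_out, 2, norms_out, "/")

  sv <- svd(cbind(S_in, S_out))
  rank <- sum(sv$d > 1e-8 * sv$d[1])
  if (rank < D_in + D_out) {
    stop_megshield("SSS basis is rank deficient: numerical rank ", rank,
                   " < ", D_in + D_out, " columns")
  }
  structure(list(
    S_in = S_in, S_out = S_out,
    L_in = L_in, L_out = L_out, D_in = D_in, D_out = D_out,
    origin = array$origin, scale = scale,
    mag_scale_length = mag_scale_length,
    col_norms = c(norms_in, norms_out),
    index = rbind(harmonic_index(L_in, "in"), harmonic_index(L_out, "out")),
    channel_names = array$name,
    svd = sv,
    cond = sv$d[1] / sv$d[length(sv$d)]
  ), class = "sss_basis")
}

#' @export
print.sss_basis <- function(x, ...) {
  cat("<sss_basis> L_in =", x$L_in, "(", x$D_in, "vectors ), L_out =",
      x$L_out, "(", x$D_out, "vectors );", length(x$channel_names),
      "channels\n  condition number:", signif(x$cond, 4), "\n")
  invisible(x)
}
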