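# independent oracles, written against the closed forms directly and kept
# free of the package's vectorized implementation paths

# current dipole in a spherically symmetric conductor: scalar, step-by-step
# evaluation of the closed-form field at a single field point
oracle_sphere_dipole_field <- function(r, r0, Q) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  rn <- sqrt(sum(r^2))
  F <- a * (rn * a + rn^2 - sum(r0 * r))
  gradF_c1 <- a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn
  gradF_c2 <- a + 2 * rn + sum(a_vec * r) / a
  gradF <- gradF_c1 * r - gradF_c2 * r0
  Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  1e-7 / F^2 * (F * Qxr0 - sum(Qxr0 * r) * gradF)
}

# free-space field of the primary current element (Biot-Savart); its radial
# component must match the conductor model (volume currents are tangential)
oracle_free_dipole_field <- function(r, r0, Q) {
  a_vec <- r - r0
  a3 <- sum(a_vec^2)^1.5
  1e-7 * c(Q[2] * a_vec[3] - Q[3] * a_vec[2],
           Q[3] * a_vec[1] - Q[1] * a_vec[3],
           Q[1] * a_vec[2] - Q[2] * a_vec[1]) / a3
}

# channel outputs of a whole array computed independently point by point
oracle_array_dipole_signal <- function(array, r0, Q, origin = c(0, 0, 0)) {
  out <- numeric(length(array$name))
  for (i in seq_along(array$ip_w)) {
    ch <- array$ip_channel[i]
    B <- oracle_sphere_dipole_field(array$ip_pos[i, ] - origin, r0 - origin, Q)
    out[ch] <- out[ch] + array$ip_w[i] * sum(B * array$orientation[ch, ])
  }
  out * array$gain
}

# Gauss-Legendre nodes/weights on [-1, 1] by Newton iteration on Legendre
# polynomials (kept self-contained so the quadrature oracle is independent)
oracle_gauss_legendre <- function(n) {
  x <- cos(pi * (seq_len(n) - 0.25) / (n + 0.5))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    dx <- p1 / dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  list(x = x, w = 2 / ((1 - x^2) * dp^2))
}
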