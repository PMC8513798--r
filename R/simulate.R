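#' Current dipole sources
#'
#' A `dipole_source` is a current dipole inside a spherically symmetric
#' volume conductor: position (m, device coordinates; its distance from the
#' conductor origin is the "depth" used in the simulation sweeps),
#' tangential unit orientation (radial dipoles are magnetically silent in a
#' spherical conductor), and peak amplitude in A*m.
#'
#' @param position 3-vector, m.
#' @param orientation unit 3-vector, tangential: `orientation . position`
#'   must vanish (relative to the conductor origin).
#' @param peak_amplitude scalar, A*m (e.g. `1000e-9` for 1000 nAm).
#' @param conductor_origin origin of the spherical conductor (default 0).
#' @return a `dipole_source`.
#' @export
dipole_source <- function(position, orientation, peak_amplitude = 1000e-9,
                          conductor_origin = c(0, 0, 0)) {
  position <- as.numeric(position); orientation <- unit(orientation)
  rel <- position - conductor_origin
  if (abs(sum(orientation * rel)) > 1e-10 * max(vnorm(rel), 1e-12)) {
    stop_megshield("dipole orientation must be tangential ",
                   "(orthogonal to the position vector)")
  }
  structure(list(position = position, orientation = orientation,
                 peak_amplitude = peak_amplitude,
                 conductor_origin = as.numeric(conductor_origin)),
            class = "dipole_source")
}

# seeded random tangential dipoles in the upper hemisphere (z > 0)
# at a given radius from the conductor origin
random_tangential_dipoles <- function(radius, n, seed,
                                      conductor_origin = c(0, 0, 0),
                                      peak_amplitude = 1000e-9) {
  run_seeded(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        u <- stats::rnorm(3)
        if (vnorm(u) > 1e-6 && u[3] > 0) break
      }
      u <- unit(u)
      v <- stats::rnorm(3); v <- v - sum(v * u) * u
      dipole_source(conductor_origin + radius * u, unit(v),
                    peak_amplitude, conductor_origin)
    })
  })
}

#' Lead field of a dipole position in a spherical conductor
#'
#' Magnetic field of a current dipole in a spherically symmetric conductor
#' (Sarvas closed form, including volume currents), coupled to every
#' channel of the array through its integration points and gains. The
#' radial field component equals that of the primary current alone; volume
#' currents contribute only tangentially.
#'
#' @param position dipole location (3-vector, m).
#' @param array a [meg_sensor_array].
#' @param conductor_origin conductor center (3-vector, m).
#' @return `leadfield_sphere`: N x 3 matrix, channel output per unit dipole
#'   moment along x, y, z (T or T/m per A*m).
#' @export
leadfield_sphere <- function(position, array, conductor_origin = c(0, 0, 0)) {
  r0 <- as.numeric(position) - conductor_origin
  r0n <- vnorm(r0)
  if (r0n < 1e-9) stop_megshield("dipole at the conductor origin is silent")
  if (r0n >= array$inner_radius) {
    stop_megshield("dipole at radius ", signif(r0n, 4),
                   " m lies outside the source region (inner radius ",
                   array$inner_radius, " m)")
  }
  pts <- array$ip_pos - matrix(conductor_origin, nrow(array$ip_pos), 3,
                               byrow = TRUE)
  a <- pts - matrix(r0, nrow(pts), 3, byrow = TRUE)
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(pts^2))
  r0_dot_r <- as.numeric(pts %*% r0)
  a_dot_r <- rowSums(a * pts)
  F <- an * (rn * an + rn^2 - r0_dot_r)
  cF_r <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn
  cF_r0 <- an + 2 * rn + a_dot_r / an
  # gradF rows: cF_r * r - cF_r0 * r0
  gF <- cF_r * pts - outer(cF_r0, r0)

  n_ip <- array$orientation[array$ip_channel, , drop = FALSE]
  L <- matrix(0, n_channels(array), 3)
  for (k in 1:3) {
    Q <- c(0, 0, 0); Q[k] <- 1
    Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
              Q[3] * r0[1] - Q[1] * r0[3],
              Q[1] * r0[2] - Q[2] * r0[1])
    B <- 1e-7 * (F * matrix(Qxr0, nrow(pts), 3, byrow = TRUE) -
                   as.numeric(pts %*% Qxr0) * gF) / F^2
    sig <- rowSums(B * n_ip)
    L[, k] <- as.numeric(rowsum(sig * array$ip_w, array$ip_channel)) *
      array$gain
  }
  L
}

#' @rdname leadfield_sphere
#' @param dipole a [dipole_source()].
#' @return `dipole_forward_sphere`: length-N signal vector for the dipole
#'   moment `peak_amplitude * orientation`; linear in the moment.
#' @export
dipole_forward_sphere <- function(dipole, array,
                                  conductor_origin = dipole$conductor_origin) {
  L <- leadfield_sphere(dipole$position, array, conductor_origin)
  as.numeric(L %*% (dipole$peak_amplitude * dipole$orientation))
}

#' Simulate dipole trials
#'
#' Activates a dipole with one cycle of a 10-Hz sinusoid (100 ms) followed
#' by 100 ms of zero signal, repeated for `n_trials` identical 200-ms
#' trials (the default 100 trials at 1 kHz give 20 s of data). The signal
#' peaks at 25 ms into each trial.
#'
#' @param dipole a [dipole_source()]; @param array a [meg_sensor_array].
#' @param n_trials number of trials; @param sfreq sampling rate, Hz.
#' @param f_source source frequency, Hz (one cycle per trial).
#' @return a `meg_recording` of `n_trials * 0.2 * sfreq` samples.
#' @export
simulate_dipole_trials <- function(dipole, array, n_trials = 100,
                                   sfreq = 1000, f_source = 10) {
  pattern <- dipole_forward_sphere(dipole, array)
  n_on <- round(sfreq / f_source)
  wave <- c(sin(2 * pi * f_source * (0:(n_on - 1)) / sfreq), rep(0, n_on))
  data <- pattern %o% rep(wave, n_trials)
  new_recording(data, sfreq, array$name, provenance = list(list(
    step = "simulate_dipole_trials", n_trials = n_trials,
    f_source = f_source, position_m = dipole$position,
    orientation = dipole$orientation,
    peak_amplitude_Am = dipole$peak_amplitude)))
}

#' External interference components
#'
#' `interference_spec()` describes one external multipole component: degree
#' `l` (1 = homogeneous field, 2 = first-order gradient), order `m`, a
#' sinusoidal frequency, and a peak amplitude defined as the peak value (T)
#' on the magnetometer that couples most strongly to the component's
#' spatial pattern.
#'
#' `interference_preset()` returns the component sets used by the
#' simulation study:
#' * `"empty_room"`: homogeneous fields below 2 Hz (m = 0 at 1.0 Hz,
#'   18 nT; m = +1 at 0.6 Hz, 4 nT) plus first-order gradient components
#'   around 20 Hz at about 10% relative amplitude (0.4 nT each) -- the
#'   environment characterized by the empty-room recording.
#' * `"known"`: the same multipole components (same spatial directions)
#'   at shifted frequencies (homogeneous 0.5 / 0.9 Hz, gradients
#'   22.2-23.8 Hz), emulating stationary interference sources between the
#'   empty-room and subject sessions.
#' * `"unknown"`: the `"known"` set plus a *novel* homogeneous component
#'   (m = -1, 1.3 Hz, 18 nT) absent from the empty room, emulating a new
#'   interference source appearing.
#'
#' The empty-room set deliberately leaves the whole `sin(phi)` azimuthal
#' sector unexcited -- both the homogeneous `(l=1, m=-1)` and the gradient
#' `(l=2, m=-1)` degree of freedom -- so that a genuinely novel field
#' direction exists: on a cap-shaped helmet (where `cos(theta)` does not
#' change sign) those two patterns are strongly collinear in sensor space,
#' and an empty room containing the gradient component would make the
#' "novel" homogeneous field partially known to SSP and eSSS.
#'
#' @param l degree (1 or 2); @param m order; @param freq Hz;
#' @param amplitude peak tesla on the best-coupled magnetometer.
#' @export
interference_spec <- function(l, m, freq, amplitude) {
  if (!l %in% 1:2) stop_megshield("interference degree l must be 1 or 2")
  if (abs(m) > l) stop_megshield("|m| must not exceed l")
  if (amplitude <= 0) stop_megshield("amplitude must be positive")
  structure(list(l = l, m = m, freq = freq, amplitude = amplitude),
            class = "interference_spec")
}

#' @rdname interference_spec
#' @param which preset name.
#' @export
interference_preset <- function(which = c("empty_room", "known", "unknown")) {
  which <- match.arg(which)
  l2 <- function(freqs) Map(function(m, f) interference_spec(2, m, f, 0.4e-9),
                            c(-2, 0, 1, 2), freqs)
  base <- switch(which,
    empty_room = c(list(interference_spec(1, 0, 1.0, 18e-9),
                        interference_spec(1, 1, 0.6, 4e-9)),
                   l2(c(19.2, 20.0, 20.4, 20.8))),
    known = ,
    unknown = c(list(interference_spec(1, 0, 0.5, 18e-9),
                     interference_spec(1, 1, 0.9, 4e-9)),
                l2(c(22.2, 23.0, 23.4, 23.8)))
  )
  if (which == "unknown") {
    base <- c(base, list(interference_spec(1, -1, 1.3, 18e-9)))
  }
  base
}

# sensor-space pattern of one external component, normalized so the
# best-coupled magnetometer reads 1
interference_pattern <- function(array, spec) {
  pts <- array$ip_pos - matrix(array$origin, nrow(array$ip_pos), 3,
                               byrow = TRUE)
  S <- couple_to_array(array, multipole_field_matrix(pts, spec$l, "out"))
  p <- S[, spec$l^2 + spec$l + spec$m]
  p / max(abs(p[is_magnetometer(array)]))
}

#' Simulate external interference
#'
#' Generates the sensor-space time series of a set of external multipole
#' components coupled to the array: each component's spatial pattern is the
#' corresponding exterior harmonic field seen through the array's
#' integration points and gains (so calibration errors in the array
#' propagate into the data, as on a real device), and its time course is a
#' sinusoid at the component frequency with a seeded random phase.
#'
#' @param array a [meg_sensor_array] (use the *perturbed* truth array to
#'   emulate an imperfectly calibrated device).
#' @param specs list of [interference_spec()]; default the `"empty_room"`
#'   preset.
#' @param duration seconds; @param sfreq Hz; @param seed integer seed for
#'   the phases.
#' @return a `meg_recording`.
#' @export
simulate_interference <- function(array, specs = interference_preset(),
                                  duration = 60, sfreq = 1000, seed = 1L) {
  nyq <- sfreq / 2
  for (s in specs) {
    if (s$freq >= nyq) stop_megshield("interference frequency ", s$freq,
                                      " Hz exceeds Nyquist ", nyq, " Hz")
  }
  Tn <- round(duration * sfreq)
  t <- (0:(Tn - 1)) / sfreq
  data <- matrix(0, n_channels(array), Tn)
  run_seeded(seed, {
    for (s in specs) {
      phase <- stats::runif(1, 0, 2 * pi)
      p <- interference_pattern(array, s) * s$amplitude
      data <- data + p %o% sin(2 * pi * s$freq * t + phase)
    }
  })
  new_recording(data, sfreq, array$name, provenance = list(list(
    step = "simulate_interference", seed = seed,
    components = lapply(specs, unclass))))
}

#' Add sensor noise to a recording
#'
#' Adds white Gaussian noise per channel at spectral density `mag_level`
#' (T/sqrt(Hz)) or `grad_level` ((T/m)/sqrt(Hz)) -- the per-sample standard
#' deviation is `level * sqrt(sfreq / 2)` -- plus a rank-5 spatially
#' correlated Gaussian component carrying `correlated_fraction` of the
#' total noise power. Defaults emulate typical SQUID sensor noise
#' (3 fT/sqrt(Hz) magnetometers, 3 fT/cm/sqrt(Hz) gradiometers, 10%
#' correlated).
#'
#' @param recording input `meg_recording`.
#' @param mag_level,grad_level noise amplitude spectral densities.
#' @param correlated_fraction fraction of noise power in the rank-5
#'   spatially correlated part.
#' @param seed integer seed.
#' @param array optional array for channel-type lookup (name prefix `MAG`
#'   is used otherwise).
#' @return `meg_recording` with noise added.
#' @export
add_sensor_noise <- function(recording, mag_level = 3e-15,
                             grad_level = 3e-13, correlated_fraction = 0.1,
                             seed = 1L, array = NULL) {
  if (correlated_fraction < 0 || correlated_fraction > 1) {
    stop_megshield("correlated_fraction must be in [0, 1]")
  }
  mags <- if (!is.null(array)) is_magnetometer(array) else
    grepl("^MAG", recording$channel_names)
  N <- nrow(recording$data); Tn <- ncol(recording$data)
  target <- ifelse(mags, mag_level, grad_level) * sqrt(recording$sfreq / 2)
  if (all(target == 0)) return(recording)
  out <- recording
  run_seeded(seed, {
    white <- matrix(stats::rnorm(N * Tn), N, Tn) *
      (target * sqrt(1 - correlated_fraction))
    noise <- white
    if (correlated_fraction > 0) {
      M <- matrix(stats::rnorm(N * 5), N, 5)
      M <- unit_rows(M) * (target * sqrt(correlated_fraction))
      noise <- noise + M %*% matrix(stats::rnorm(5 * Tn), 5, Tn)
    }
    out$data <- recording$data + noise
  })
  add_provenance(out, "add_sensor_noise", mag_level = mag_level,
                 grad_level = grad_level,
                 correlated_fraction = correlated_fraction, seed = seed)
}

#' Simulate an empty-room recording
#'
#' Interference preset (`"empty_room"`) plus sensor noise, no internal
#' source: the fixture from which SSP and eSSS estimate their interference
#' principal components. Default 60 s at 1 kHz.
#'
#' @inheritParams simulate_interference
#' @inheritParams add_sensor_noise
#' @export
simulate_empty_room <- function(array, duration = 60, sfreq = 1000,
                                seed = 1L, mag_level = 3e-15,
                                grad_level = 3e-13,
                                correlated_fraction = 0.1) {
  rec <- simulate_interference(array, interference_preset("empty_room"),
                               duration, sfreq, seed = child_seed(seed, 1))
  rec <- add_sensor_noise(rec, mag_level, grad_level, correlated_fraction,
                          seed = child_seed(seed, 2), array = array)
  add_provenance(rec, "simulate_empty_room", duration_s = duration,
                 seed = seed)
}
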