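make_rec <- function(data, sfreq = 1000, prefix = c("MAG", "GRAD")) {
  N <- nrow(data)
  nm <- sprintf("%s%03d", rep(prefix, length.out = N), seq_len(N))
  new_recording(data, sfreq, nm)
}

test_that("norm-based shielding factor follows its definition", {
  set.seed(1)
  X <- matrix(stats::rnorm(20 * 4000), 20, 4000)
  raw <- make_rec(X, prefix = "MAG")
  expect_equal(shielding_factor_norm(raw, raw), 1, tolerance = 1e-12)
  tenth <- raw; tenth$data <- raw$data / 10
  expect_equal(shielding_factor_norm(raw, tenth), 10, tolerance = 1e-10)

  # invariant under common rescaling
  r2 <- raw; r2$data <- raw$data * 3.7
  t2 <- tenth; t2$data <- tenth$data * 3.7
  expect_equal(shielding_factor_norm(r2, t2),
               shielding_factor_norm(raw, tenth), tolerance = 1e-12)

  # zero processed signal flags +Inf instead of erroring
  zero <- raw; zero$data[] <- 0
  expect_identical(shielding_factor_norm(raw, zero), Inf)

  # the window locks onto the largest raw swing
  X2 <- matrix(1e-12, 4, 10000)
  X2[, 5000:6999] <- 1e-9
  raw2 <- make_rec(X2, prefix = "MAG")
  proc2 <- raw2
  proc2$data[, 5000:6999] <- 1e-11   # suppression only during the swing
  expect_equal(shielding_factor_norm(raw2, proc2), 100, tolerance = 0.01)
})

test_that("FFT shielding factor isolates the target frequency", {
  t <- (0:19999) / 1000
  base <- 1e-12 * sin(2 * pi * 7 * t)
  tone <- 1e-10 * sin(2 * pi * 1.3 * t)
  raw <- make_rec(rbind(base + tone, 2 * base + tone), prefix = "MAG")
  proc <- make_rec(rbind(base + tone / 100, 2 * base + tone / 100),
                   prefix = "MAG")
  expect_equal(shielding_factor_fft(raw, raw, 1.3), 1, tolerance = 1e-12)
  # processed attenuated 100x only at the target frequency
  expect_equal(shielding_factor_fft(raw, proc, 1.3), 100, tolerance = 0.02)
  # the untouched 7 Hz signal does not register
  expect_equal(shielding_factor_fft(raw, proc, 7), 1, tolerance = 0.02)

  # norm- and FFT-based factors agree within a factor 2 on single-tone data
  raw1 <- make_rec(matrix(tone, 1), prefix = "MAG")
  proc1 <- make_rec(matrix(tone / 25, 1), prefix = "MAG")
  sf_t <- shielding_factor_norm(raw1, proc1)
  sf_f <- shielding_factor_fft(raw1, proc1, 1.3)
  expect_lt(max(sf_t / sf_f, sf_f / sf_t), 2)
})

test_that("Welch spectra match closed-form window responses", {
  sfreq <- 1000; n_fft <- 4096
  A <- 3e-12
  f0 <- 40 * sfreq / n_fft   # exact bin frequency
  t <- (0:65535) / sfreq
  rec <- make_rec(matrix(A * sin(2 * pi * f0 * t), 1), sfreq, "MAG")
  sp <- welch_spectrum(rec, n_fft = n_fft)
  # closed-form Hann response at an exact bin: one-sided PSD peak
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_fft - 1)) / (n_fft - 1)))
  peak_psd <- 2 * (A * sum(w) / 2)^2 / (sfreq * sum(w^2))
  i0 <- which.min(abs(sp$freq - f0))
  expect_equal(sp$asd[1, i0], sqrt(peak_psd), tolerance = 0.05)

  # white noise: flat ASD at the generating level
  level <- 5e-15
  zero <- make_rec(matrix(0, 1, 60000), sfreq, "MAG")
  noisy <- add_sensor_noise(zero, mag_level = level,
                            correlated_fraction = 0, seed = 8)
  spn <- welch_spectrum(noisy, n_fft = n_fft)
  band <- spn$freq > 10 & spn$freq < 400
  expect_equal(mean(spn$asd[1, band]), level, tolerance = 0.1)

  # Parseval: integrated PSD equals the time-domain variance
  df <- sfreq / n_fft
  expect_equal(sum(spn$asd[1, ]^2) * df, stats::var(noisy$data[1, ]),
               tolerance = 0.02)
})

test_that("noise covariance estimation yields a calibrated whitener", {
  set.seed(3)
  N <- 40
  X <- matrix(stats::rnorm(N * 20000), N, 20000)
  rec <- make_rec(X)
  nc <- estimate_noise_covariance(rec)
  offdiag <- nc$cov - diag(diag(nc$cov))
  expect_lt(max(abs(offdiag)), 0.05)
  expect_equal(mean(diag(nc$cov)), 1, tolerance = 0.05)

  # whitened data have identity covariance
  W <- nc$whitener
  Cw <- W %*% nc$cov %*% t(W)
  expect_lt(max(abs(Cw - diag(N))), 0.01)

  # rank-deficient input stays positive semi-definite with full-rank
  # whitening confined to the data subspace
  Xr <- matrix(stats::rnorm(N * 10), N, 10)
  ncr <- estimate_noise_covariance(make_rec(Xr))
  expect_lte(ncr$rank, 10)
  ev <- eigen(ncr$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_true(all(is.finite(ncr$whitener)))

  # chi-square consistency: whitened residual power of pure noise matches
  # its degrees of freedom
  Y <- matrix(stats::rnorm(N * 5000), N, 5000)
  nc2 <- estimate_noise_covariance(make_rec(Y))
  wss <- colSums((nc2$whitener %*% Y[, 1:200])^2)
  expect_equal(mean(wss), N, tolerance = 0.1)
})

test_that("dipole fitting is self-consistent and rotation-equivariant", {
  helmet <- full_helmet()
  dip <- make_dipole(radius = 0.05, dir = c(1, 0.5, 1.5), mom = c(1, 1, -1))
  ev <- dipole_forward_sphere(dip, helmet)
  fit <- fit_dipole(ev, helmet)
  expect_lt(vnorm <- sqrt(sum((fit$position - dip$position)^2)), 1e-4)
  expect_lt(abs(fit$amplitude - dip$peak_amplitude) / dip$peak_amplitude,
            2e-3)
  expect_gt(fit$goodness_of_fit, 1 - 1e-6)

  # rotating array and source about the origin rotates the fit
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- helmet
  rot$position <- helmet$position %*% t(R)
  rot$orientation <- helmet$orientation %*% t(R)
  rot$baseline_dir <- helmet$baseline_dir %*% t(R)
  rot$ip_pos <- helmet$ip_pos %*% t(R)
  dip_r <- dipole_source(as.numeric(R %*% dip$position),
                         as.numeric(R %*% dip$orientation),
                         dip$peak_amplitude)
  ev_r <- dipole_forward_sphere(dip_r, rot)
  expect_equal(ev_r, ev, tolerance = 1e-10)
  fit_r <- fit_dipole(ev_r, rot)
  expect_equal(fit_r$position, as.numeric(R %*% fit$position),
               tolerance = 1e-3)
})

test_that("source error summaries implement the stated definitions", {
  dips <- list(make_dipole(0.03), make_dipole(0.05, dir = c(1, 2, 1)))
  perfect <- lapply(dips, function(d) {
    structure(list(position = d$position, moment = d$peak_amplitude *
                     d$orientation, amplitude = d$peak_amplitude,
                   goodness_of_fit = 1, converged = TRUE),
              class = "dipole_fit")
  })
  z <- source_errors(perfect, dips)
  expect_equal(z$localization_error_m, 0)
  expect_equal(z$amplitude_error, 0)

  shifted <- perfect
  shifted[[1]]$position <- shifted[[1]]$position + c(0.003, 0, 0)
  s <- source_errors(shifted[1], dips[1])
  expect_equal(s$localization_error_m, 0.003, tolerance = 1e-12)
  expect_equal(nrow(z$per_depth), 2)
  expect_equal(z$per_depth$n, c(1, 1))
})
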