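test_that("the spherical-conductor dipole forward matches independent oracles", {
  helmet <- small_helmet()
  dip <- make_dipole(radius = 0.045, dir = c(1, 2, 2), mom = c(3, -1, 1))
  Q <- dip$peak_amplitude * dip$orientation

  # independent scalar evaluation at 5 hand-placed field points
  pts <- rbind(c(0.11, 0, 0.03), c(0, 0.12, 0.01), c(-0.08, 0.05, 0.09),
               c(0.03, -0.09, 0.1), c(0.06, 0.06, 0.11))
  for (i in 1:5) {
    ora <- oracle_sphere_dipole_field(pts[i, ], dip$position, Q)
    # package path: a single-point magnetometer probe via the lead field
    probe <- megshield:::new_sensor_array(
      name = "P1", kind = "magnetometer",
      position = matrix(pts[i, ], 1), orientation = matrix(c(1, 0, 0), 1),
      baseline_dir = matrix(NA_real_, 1, 3), gain = 1,
      ip_pos = matrix(pts[i, ], 1), ip_w = 1, ip_channel = 1L,
      origin = c(0, 0, 0), inner_radius = 0.07)
    for (k in 1:3) {
      probe$orientation[1, ] <- c(0, 0, 0); probe$orientation[1, k] <- 1
      got <- dipole_forward_sphere(dip, probe)
      expect_equal(got, ora[k], tolerance = 1e-10)
    }
    # radial field equals the free-space primary-current field
    rhat <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    expect_lt(abs(sum(ora * rhat) -
                    sum(oracle_free_dipole_field(pts[i, ], dip$position, Q) *
                          rhat)),
               1e-10 * max(abs(ora)))
  }

  # whole-array agreement including integration weights and gains
  pert <- perturb_calibration(helmet, 0.01, seed = 3)
  expect_equal(dipole_forward_sphere(dip, pert),
               oracle_array_dipole_signal(pert, dip$position, Q),
               tolerance = 1e-12)

  # radial dipoles are silent; the forward is linear in the moment
  u <- dip$position / sqrt(sum(dip$position^2))
  L <- leadfield_sphere(dip$position, helmet)
  expect_lt(sqrt(sum((L %*% u)^2)),
            1e-12 * sqrt(sum((L %*% dip$orientation)^2)))
  d2 <- dipole_source(dip$position, dip$orientation,
                      2 * dip$peak_amplitude)
  expect_equal(dipole_forward_sphere(d2, helmet),
               2 * dipole_forward_sphere(dip, helmet), tolerance = 1e-15)

  # error conditions
  expect_error(leadfield_sphere(c(0, 0, 0), helmet), "origin")
  expect_error(leadfield_sphere(c(0, 0, 0.11), helmet), "outside")
  expect_error(dipole_source(c(0, 0, 0.05), c(0, 0, 1)), "tangential")
})

test_that("dipole trials have the stated waveform and duration", {
  helmet <- small_helmet()
  dip <- make_dipole()
  rec <- simulate_dipole_trials(dip, helmet)  # defaults: 100 trials, 1 kHz
  expect_equal(ncol(rec$data), 20000)
  expect_equal(rec$sfreq, 1000)
  # second half of every trial is exactly zero
  idx0 <- as.vector(outer(101:200, (0:99) * 200, "+"))
  expect_true(all(rec$data[, idx0] == 0))
  # identical trials: trial-averaged peak equals single-trial peak
  avg <- matrix(rowMeans(array(rec$data, c(120, 200, 100)), dims = 2),
                120, 200)
  expect_equal(avg, rec$data[, 1:200], tolerance = 1e-15)
  # waveform peaks at 25 ms
  expect_equal(which.max(abs(avg[which.max(abs(avg[, 26])), 1:100])), 26)
})

test_that("interference presets have the stated amplitude and structure", {
  helmet <- full_helmet()
  rec <- simulate_interference(helmet, duration = 3, sfreq = 500, seed = 1)
  mags <- helmet$kind == "magnetometer"
  peak <- max(abs(rec$data[mags, ]))
  expect_gt(peak, 15e-9)
  expect_lt(peak, 25e-9)

  # exact-gain interference lies in span(S_out)
  basis <- full_basis()
  X <- rec$data * basis$scale
  resid <- X - basis$S_out %*% qr.solve(basis$S_out, X)
  expect_lt(norm(resid, "F") / norm(X, "F"), 1e-10)

  # seeded determinism
  rec2 <- simulate_interference(helmet, duration = 3, sfreq = 500, seed = 1)
  expect_identical(rec$data, rec2$data)

  # "known" reuses empty-room directions at shifted frequencies; "unknown"
  # adds one homogeneous component absent from the empty room
  er <- interference_preset("empty_room")
  kn <- interference_preset("known")
  un <- interference_preset("unknown")
  expect_identical(lapply(er, function(s) c(s$l, s$m)),
                   lapply(kn, function(s) c(s$l, s$m)))
  expect_false(any(vapply(er, function(s) s$freq, 1) %in%
                     vapply(kn, function(s) s$freq, 1)))
  extra <- setdiff(vapply(un, function(s) paste(s$l, s$m), ""),
                   vapply(kn, function(s) paste(s$l, s$m), ""))
  expect_identical(extra, "1 -1")
})

test_that("sensor noise has calibrated level and rank-5 correlated part", {
  helmet <- small_helmet()
  zero <- new_recording(matrix(0, 120, 20000), 1000, helmet$name)

  # uncorrelated noise: per-channel SD within 5% of level * sqrt(sfreq/2)
  rec <- add_sensor_noise(zero, correlated_fraction = 0, seed = 2,
                          array = helmet)
  sds <- apply(rec$data, 1, stats::sd)
  target <- ifelse(helmet$kind == "magnetometer", 3e-15, 3e-13) * sqrt(500)
  expect_true(all(abs(sds / target - 1) < 0.05))

  # zero levels leave the recording untouched
  expect_identical(add_sensor_noise(zero, mag_level = 0, grad_level = 0,
                                    seed = 3, array = helmet), zero)

  # the correlated component has spatial rank 5
  corr <- add_sensor_noise(zero, mag_level = 1e-12, grad_level = 1e-12,
                           correlated_fraction = 1, seed = 4,
                           array = helmet)
  sv <- svd(corr$data, nu = 0, nv = 0)$d
  expect_gt(sv[5] / sv[1], 1e-6)
  expect_lt(sv[6] / sv[1], 1e-10)
})

test_that("empty-room fixtures are reproducible with a stable subspace", {
  helmet <- small_helmet()
  er <- simulate_empty_room(helmet, duration = 60, sfreq = 1000, seed = 5)
  expect_equal(ncol(er$data), 60000)

  er_a <- simulate_empty_room(helmet, duration = 5, sfreq = 500, seed = 6)
  er_b <- simulate_empty_room(helmet, duration = 5, sfreq = 500, seed = 7)
  expect_false(identical(er_a$data, er_b$data))

  # top-8 PCs capture nearly all variance (interference >> sensor noise)
  sv <- svd(er_a$data - rowMeans(er_a$data), nu = 0, nv = 0)$d
  expect_gt(sum(sv[1:8]^2) / sum(sv^2), 0.99)

  # the interference subspace is seed-independent: principal angles between
  # the 6-component subspaces of two seeds stay small at high SNR
  sub_a <- estimate_interference_subspace(er_a, 6, mode = "joint",
                                          mag_scale = 100, array = helmet)
  sub_b <- estimate_interference_subspace(er_b, 6, mode = "joint",
                                          mag_scale = 100, array = helmet)
  s <- svd(crossprod(sub_a$U, sub_b$U), nu = 0, nv = 0)$d
  expect_lt(max(acos(pmin(1, s))), 1e-3)
})
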