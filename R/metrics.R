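#' Shielding factors
#'
#' The shielding factor (SF) quantifies interference suppression as the
#' ratio of interference amplitude before vs after processing.
#'
#' `shielding_factor_norm()` is the time-domain definition: the ratio of
#' the time-averaged norms of the raw and processed magnetometer signal
#' vectors, `SF = <||phi_raw||> / <||phi_proc||>`, evaluated over the 2-s
#' window in which the raw norm is largest (the "largest swing" of the
#' data). The average is the ratio of time-averaged norms (not the average
#' of instantaneous ratios).
#'
#' `shielding_factor_fft()` is the frequency-domain definition used for
#' simulations, where an internal source at a different frequency must not
#' contaminate the estimate: the ratio of FFT amplitude peaks at a specific
#' frequency (peak searched within +-1 bin), per channel, combined across
#' the channel subset by the Euclidean norm. The two definitions agree to
#' within a small factor on single-tone interference.
#'
#' @param raw,processed `meg_recording`s of equal shape.
#' @param window_s averaging window length in seconds (default 2).
#' @param channel_subset `"magnetometer"`, `"planar_gradiometer"`, or
#'   `"all"`; the published definition uses magnetometers.
#' @param array optional [meg_sensor_array] for channel-type lookup.
#' @return a scalar SF; `+Inf` when the processed signal is numerically
#'   zero (flagged, not an error).
#' @export
shielding_factor_norm <- function(raw, processed, window_s = 2,
                                  channel_subset = "magnetometer",
                                  array = NULL) {
  stopifnot(all(dim(raw$data) == dim(processed$data)))
  sel <- subset_channels(raw, channel_subset, array)
  w <- round(window_s * raw$sfreq)
  if (w > n_samples(raw)) stop_megshield("window longer than the recording")
  nr <- sqrt(colSums(raw$data[sel, , drop = FALSE]^2))
  np <- sqrt(colSums(processed$data[sel, , drop = FALSE]^2))
  cr <- cumsum(c(0, nr)); cp <- cumsum(c(0, np))
  starts <- seq_len(length(nr) - w + 1)
  sums <- cr[starts + w] - cr[starts]
  i <- which.max(sums)
  denom <- cp[i + w] - cp[i]
  if (denom < .Machine$double.xmin * w) return(Inf)
  sums[i] / denom
}

subset_channels <- function(rec, channel_subset, array = NULL) {
  if (identical(channel_subset, "all")) return(seq_along(rec$channel_names))
  kinds <- if (!is.null(array)) array$kind else
    ifelse(grepl("^MAG", rec$channel_names), "magnetometer",
           "planar_gradiometer")
  which(kinds == channel_subset)
}

#' @rdname shielding_factor_norm
#' @param freq target frequency, Hz.
#' @export
shielding_factor_fft <- function(raw, processed, freq,
                                 channel_subset = "magnetometer",
                                 array = NULL) {
  stopifnot(all(dim(raw$data) == dim(processed$data)))
  sel <- subset_channels(raw, channel_subset, array)
  peak_amps <- function(rec) {
    X <- rec$data[sel, , drop = FALSE]
    X <- X - rowMeans(X)
    Tn <- ncol(X)
    sp <- Mod(stats::mvfft(t(X)))
    bin <- round(freq * Tn / rec$sfreq) + 1
    bins <- pmax(1, bin - 1):pmin(floor(Tn / 2) + 1, bin + 1)
    apply(sp[bins, , drop = FALSE], 2, max)
  }
  a_raw <- peak_amps(raw); a_proc <- peak_amps(processed)
  denom <- sqrt(sum(a_proc^2))
  if (denom < .Machine$double.xmin) return(Inf)
  sqrt(sum(a_raw^2)) / denom
}

#' Welch amplitude spectral density
#'
#' Per-channel one-sided amplitude spectral density by Welch's method with
#' a 4096-point Hann window and 50% overlap (shorter recordings fall back
#' to the largest power-of-two window that fits). Units are
#' `unit/sqrt(Hz)` (T/sqrt(Hz) for magnetometers). The underlying PSD is
#' normalized by the window power (`sum(w^2)`), so the integrated PSD
#' matches the time-domain variance (Parseval).
#'
#' @param recording a `meg_recording`.
#' @param n_fft window length (default 4096).
#' @return list with `freq` (Hz) and `asd` (channels x frequencies matrix).
#' @export
welch_spectrum <- function(recording, n_fft = 4096) {
  X <- recording$data
  Tn <- ncol(X)
  if (Tn < n_fft) n_fft <- 2^floor(log2(Tn))
  if (n_fft < 8) stop_megshield("recording too short for a spectrum")
  step <- n_fft / 2
  starts <- seq(1, Tn - n_fft + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_fft - 1)) / (n_fft - 1)))  # Hann
  U <- sum(w^2)
  sf <- recording$sfreq
  n_keep <- floor(n_fft / 2) + 1
  acc <- matrix(0, nrow(X), n_keep)
  for (s in starts) {
    seg <- X[, s:(s + n_fft - 1), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(w, each = nrow(X))
    sp <- Mod(stats::mvfft(t(seg)))^2
    acc <- acc + t(sp[seq_len(n_keep), , drop = FALSE])
  }
  psd <- acc / (length(starts) * sf * U)
  psd[, 2:(n_keep - 1)] <- 2 * psd[, 2:(n_keep - 1)]  # one-sided
  list(freq = (0:(n_keep - 1)) * sf / n_fft, asd = sqrt(psd))
}

#' Noise covariance and whitener from baseline data
#'
#' Sample covariance over concatenated baseline segments, with relative
#' diagonal loading (default 1e-3 of the mean retained eigenvalue) for
#' invertibility, and *rank-aware* whitening: data processed by SSS, eSSS
#' or SSP live in a low-dimensional subspace (e.g. the 80-dimensional
#' internal reconstruction span), so the noise covariance is
#' rank-deficient, and a naive inverse square root would give enormous
#' weight to the empty directions -- exactly where the unprocessed
#' forward model's truncation mismatch lives. The whitener is therefore
#' the inverse symmetric square root restricted to the covariance's
#' numerical rank (eigenvalues above `rank_tol` times the largest); data
#' components outside that subspace get zero weight. Whitened baseline
#' data have (approximately) identity covariance on the retained
#' subspace, which is what makes full-covariance dipole fitting
#' downweight residual interference directions.
#'
#' @param recording a `meg_recording`.
#' @param baseline_idx integer vector of sample indices forming the
#'   baseline (e.g. the zero-signal halves of simulation trials); default
#'   all samples.
#' @param loading relative diagonal loading factor.
#' @param rank_tol relative eigenvalue threshold defining the numerical
#'   rank.
#' @return list with `cov` (N x N), `whitener` (N x N), `rank`, `n`
#'   (samples used).
#' @export
estimate_noise_covariance <- function(recording, baseline_idx = NULL,
                                      loading = 1e-3, rank_tol = 1e-8) {
  X <- recording$data
  if (!is.null(baseline_idx)) X <- X[, baseline_idx, drop = FALSE]
  X <- X - rowMeans(X)
  n <- ncol(X)
  C <- tcrossprod(X) / max(1, n - 1)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] <= 0) {
    # noiseless baseline: unweighted least squares
    return(list(cov = C, whitener = diag(nrow(C)), rank = 0L, n = n))
  }
  r <- sum(e$values > rank_tol * e$values[1])
  vals <- e$values[seq_len(r)] + loading * mean(e$values[seq_len(r)])
  V <- e$vectors[, seq_len(r), drop = FALSE]
  W <- V %*% (t(V) / sqrt(vals))
  list(cov = C, whitener = W, rank = r, n = n)
}

#' Least-squares dipole fit in a spherical conductor
#'
#' Fits a single current dipole to an evoked field vector by nonlinear
#' search over position with the moment solved linearly in whitened
#' space. Channels are weighted by the full noise covariance (its inverse
#' matrix square root whitens both data and forward model). The search is
#' multi-start: a coarse grid of >= 27 seed positions inside the conductor
#' followed by Nelder-Mead refinement from the best seed. With
#' SSP-processed data, pass the projector so both the evoked vector and
#' the forward model are projected before whitening (forward
#' compensation), which removes the amplitude bias that SSP's signal
#' distortion would otherwise cause.
#'
#' @param evoked length-N numeric vector (one latency, e.g. the peak of
#'   the trial-averaged response).
#' @param array a [meg_sensor_array] (nominal calibration: the fit does not
#'   know the true gains).
#' @param conductor_origin sphere center, m.
#' @param noise_cov result of [estimate_noise_covariance()] (or a list
#'   with a `whitener`).
#' @param projector optional `ssp_projector` for forward compensation.
#' @param max_radius search bound on the source radius (default 90% of the
#'   array's inner radius).
#' @return a `dipole_fit`: `position` (m), `moment` (A*m vector),
#'   `amplitude` (|moment|), `goodness_of_fit` (whitened variance
#'   explained), `converged`.
#' @export
fit_dipole <- function(evoked, array, conductor_origin = c(0, 0, 0),
                       noise_cov = NULL, projector = NULL,
                       max_radius = 0.9 * array$inner_radius) {
  N <- n_channels(array)
  stopifnot(length(evoked) == N)
  W <- if (is.null(noise_cov)) diag(N) else noise_cov$whitener
  e <- as.numeric(evoked)
  if (!is.null(projector)) e <- as.numeric(project_matrix(projector,
                                                          matrix(e)))
  ew <- as.numeric(W %*% e)
  ss_tot <- sum(ew^2)

  solve_moment <- function(pos) {
    L <- leadfield_sphere(pos, array, conductor_origin)
    if (!is.null(projector)) L <- project_forward(projector, L)
    Lw <- W %*% L
    sv <- svd(Lw)
    dinv <- ifelse(sv$d > 1e-10 * sv$d[1], 1 / sv$d, 0)
    q <- sv$v %*% (dinv * crossprod(sv$u, ew))
    resid <- ew - Lw %*% q
    list(q = as.numeric(q), ss_res = sum(resid^2))
  }
  cost <- function(pos) {
    r <- vnorm(pos - conductor_origin)
    if (r >= max_radius) return(ss_tot * (1 + 10 * (r - max_radius)))
    solve_moment(pos)$ss_res
  }

  # multi-start grid: coarse directions at inner radii, finer at the outer
  # radius where superficial-source fields decorrelate over a few cm
  sph <- function(th, ph) c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  dirs9 <- rbind(c(0, 0, 1))
  for (th in c(pi / 5, 2 * pi / 5)) {
    for (ph in seq(0, 2 * pi, length.out = 5)[1:4]) {
      dirs9 <- rbind(dirs9, sph(th, ph))
    }
  }
  dirs_fine <- rbind(c(0, 0, 1))
  for (th in pi / 180 * c(18, 36, 54, 72, 88)) {
    for (ph in seq(0, 2 * pi, length.out = 9)[1:8]) {
      dirs_fine <- rbind(dirs_fine, sph(th, ph))
    }
  }
  grid <- rbind(
    do.call(rbind, lapply(max_radius * c(0.25, 0.55), function(r) {
      t(apply(dirs9, 1, function(d) conductor_origin + r * d))
    })),
    t(apply(dirs_fine, 1, function(d) conductor_origin + 0.8 * max_radius * d))
  )
  costs <- apply(grid, 1, cost)
  refine <- function(p0) {
    opt <- stats::optim(p0, cost, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    stats::optim(opt$par, cost, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
  }
  # refine from the three best well-separated seeds, keep the best optimum
  ord <- order(costs)
  seeds <- list(grid[ord[1], ])
  for (i in ord[-1]) {
    if (length(seeds) >= 3) break
    if (all(vapply(seeds, function(s) vnorm(s - grid[i, ]) > 0.015,
                   logical(1)))) {
      seeds <- c(seeds, list(grid[i, ]))
    }
  }
  opts <- lapply(seeds, refine)
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  converged <- opt$convergence == 0
  if (!converged) {
    warning("dipole fit did not fully converge; returning best candidate",
            call. = FALSE)
  }
  sol <- solve_moment(opt$par)
  structure(list(position = as.numeric(opt$par), moment = sol$q,
                 amplitude = vnorm(sol$q),
                 goodness_of_fit = 1 - sol$ss_res / ss_tot,
                 converged = converged),
            class = "dipole_fit")
}

#' Source-estimation error summary
#'
#' Localization error is the mean Euclidean distance between true and
#' estimated dipole locations; amplitude error is the mean absolute
#' difference between true and estimated amplitudes relative to the true
#' amplitude. A per-depth breakdown (grouped by the true source radius) is
#' included.
#'
#' @param fits list of `dipole_fit`s; @param truths list of matching
#'   [dipole_source()]s.
#' @return an `error_summary`: `localization_error_m`,
#'   `amplitude_error` (fraction), `n`, and `per_depth` data frame with
#'   columns `radius_m`, `loc_err_m`, `amp_err`, `n`.
#' @export
source_errors <- function(fits, truths) {
  stopifnot(length(fits) == length(truths))
  loc <- mapply(function(f, t) vnorm(f$position - t$position), fits, truths)
  amp <- mapply(function(f, t) {
    abs(f$amplitude - t$peak_amplitude) / t$peak_amplitude
  }, fits, truths)
  radius <- vapply(truths, function(t) {
    vnorm(t$position - t$conductor_origin)
  }, numeric(1))
  key <- round(radius, 6)
  per_depth <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    data.frame(radius_m = radius[i[1]], loc_err_m = mean(loc[i]),
               amp_err = mean(amp[i]), n = length(i))
  }))
  rownames(per_depth) <- NULL
  structure(list(localization_error_m = mean(loc),
                 amplitude_error = mean(amp), n = length(fits),
                 per_depth = per_depth[order(per_depth$radius_m), ]),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary> n =", x$n, "\n  mean localization error:",
      signif(x$localization_error_m * 1e3, 3), "mm\n",
      " mean amplitude error:", signif(x$amplitude_error * 100, 3), "%\n")
  invisible(x)
}
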