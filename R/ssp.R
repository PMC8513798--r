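#' Interference subspace estimation (SSP / eSSS input)
#'
#' Estimates the dominant interference signal-space directions from an
#' empty-room recording by PCA: the per-channel temporal mean is removed
#' and the left singular vectors of the demeaned (and, in joint mode,
#' channel-type scaled) data matrix are taken. Two modes are supported:
#'
#' * `per_type` (classic SSP): PCA run separately on the magnetometer and
#'   gradiometer blocks in native units, `k` components per type, stacked
#'   with zero padding (default `k = 5`, i.e. 5 + 5 directions).
#' * `joint` (eSSS input): one PCA over all channels after multiplying
#'   magnetometer rows by `mag_scale` (default 100) so both sensor types
#'   have similar numerical range; `k` components total (default 8,
#'   motivated by the homogeneous + first-order-gradient fields occupying
#'   3 + 5 degrees of freedom).
#'
#' Component signs are fixed deterministically (largest-magnitude element
#' positive) so results are reproducible.
#'
#' @param empty_room a [new_recording] measured/simulated without a subject.
#' @param k number of components (per sensor type in `per_type` mode).
#' @param mode `"per_type"` or `"joint"`.
#' @param mag_scale magnetometer scaling used in `joint` mode.
#' @param array optional [meg_sensor_array] used to classify channel types;
#'   if omitted, channels named `MAG*` are treated as magnetometers.
#' @return an `interference_subspace` with orthonormal `U` (N x k or
#'   N x 2k), singular values, the scale vector used, and provenance.
#' @export
estimate_interference_subspace <- function(empty_room, k,
                                           mode = c("per_type", "joint"),
                                           mag_scale = 100, array = NULL) {
  mode <- match.arg(mode)
  if (k < 1) stop_megshield("k must be >= 1")
  X <- empty_room$data
  N <- nrow(X)
  if (k >= N) stop_megshield("k = ", k, " must be smaller than the channel ",
                             "count ", N)
  if (ncol(X) < k) stop_megshield("empty-room duration too short: ",
                                  ncol(X), " samples < k = ", k)
  X <- X - rowMeans(X)
  if (max(abs(X)) < 1e-30) stop_megshield("degenerate empty-room recording")
  mags <- if (!is.null(array)) {
    check_channels_match(array$name, empty_room$channel_names, "empty room")
    is_magnetometer(array)
  } else grepl("^MAG", empty_room$channel_names)

  fix_signs <- function(U) {
    for (j in seq_len(ncol(U))) {
      if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
    }
    U
  }

  if (mode == "joint") {
    scale <- ifelse(mags, mag_scale, 1)
    sv <- svd(X * scale, nu = k, nv = 0)
    U <- fix_signs(sv$u)
    d <- sv$d[seq_len(k)]
  } else {
    scale <- rep(1, N)
    U <- matrix(0, N, 2 * k); d <- numeric(2 * k)
    for (block in list(which(mags), which(!mags))) {
      if (length(block) <= k) {
        stop_megshield("k = ", k, " too large for a sensor-type block of ",
                       length(block), " channels")
      }
      sv <- svd(X[block, , drop = FALSE], nu = k, nv = 0)
      cols <- if (identical(block, which(mags))) seq_len(k) else k + seq_len(k)
      U[block, cols] <- sv$u
      d[cols] <- sv$d[seq_len(k)]
    }
    U <- fix_signs(U)
  }
  structure(list(
    U = U, singular_values = d, scale = scale, mode = mode,
    channel_names = empty_room$channel_names,
    source_meta = list(duration_s = ncol(empty_room$data) / empty_room$sfreq,
                       k = k, mode = mode, mag_scale = mag_scale)
  ), class = "interference_subspace")
}

# a subspace with zero components (projector = identity; eSSS = SSS)
empty_subspace <- function(channel_names) {
  structure(list(U = matrix(0, length(channel_names), 0),
                 singular_values = numeric(0),
                 scale = rep(1, length(channel_names)), mode = "joint",
                 channel_names = channel_names,
                 source_meta = list(k = 0)),
            class = "interference_subspace")
}

#' Orthogonal SSP projector
#'
#' Builds the projector `P = I - U U'` onto the orthogonal complement of an
#' interference subspace. For a subspace estimated in scaled channel units
#' (joint mode) the projector acts in that scaled space; with the default
#' per-type SSP subspace the scale is 1 and `P` is symmetric and idempotent
#' in native sensor units.
#'
#' @param subspace an `interference_subspace`.
#' @return an `ssp_projector`; use [apply_projector()] on recordings,
#'   [project_forward()] on lead fields, and [projector_matrix()] for the
#'   explicit N x N matrix.
#' @export
make_projector <- function(subspace) {
  stopifnot(inherits(subspace, "interference_subspace"))
  structure(list(U = subspace$U, scale = subspace$scale,
                 k = ncol(subspace$U),
                 channel_names = subspace$channel_names),
            class = "ssp_projector")
}

#' @rdname make_projector
#' @param projector an `ssp_projector`.
#' @export
projector_matrix <- function(projector) {
  N <- nrow(projector$U)
  P <- diag(N) - tcrossprod(projector$U)
  # conjugate back to native units when the subspace was scaled
  (P / projector$scale) * rep(projector$scale, each = N)
}

# apply P to an N x T matrix in native units
project_matrix <- function(projector, M) {
  Ms <- M * projector$scale
  (Ms - projector$U %*% crossprod(projector$U, Ms)) / projector$scale
}

#' Apply an SSP projector to a recording
#'
#' Projects every sample onto the orthogonal complement of the interference
#' subspace, `phi -> P phi`. Energy never increases; signals orthogonal to
#' the subspace pass unchanged, while internal signals with a component in
#' the subspace are distorted, which is why dipole fitting of SSP-processed
#' data must use a projector-compensated forward model
#' ([project_forward()]).
#'
#' @param projector an `ssp_projector`; @param recording a `meg_recording`.
#' @return processed `meg_recording` with `k` and provenance recorded.
#' @export
apply_projector <- function(projector, recording) {
  check_channels_match(projector$channel_names, recording$channel_names)
  out <- recording
  out$data <- project_matrix(projector, recording$data)
  add_provenance(out, "apply_projector", k = projector$k)
}

#' @rdname apply_projector
#' @param leadfield numeric matrix N x n_sources (native sensor units).
#' @return `project_forward` returns the compensated lead field `P L`.
#' @export
project_forward <- function(projector, leadfield) {
  if (nrow(leadfield) != nrow(projector$U)) {
    stop_megshield("leadfield has ", nrow(leadfield), " rows, projector ",
                   "expects ", nrow(projector$U))
  }
  project_matrix(projector, leadfield)
}
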