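#' Extend the external SSS basis with empirical interference components
#'
#' The heart of eSSS: the computational external basis `S_out` is augmented
#' with the empirically determined interference principal components and
#' the concatenation is orthogonalized by SVD,
#' `S_out_e = orth([S_out  PC_out])`, to prevent a singular extended basis
#' (computational and measured interference patterns can be arbitrarily
#' close in signal space). After orthogonalization `S_out_e` spans
#' `span(S_out)` plus the interference features that the physical model
#' misses, notably calibration- and geometry-error leakage of real
#' interference fields. The full extended basis `S_e = [S_in  S_out_e]` is
#' then used exactly as in conventional SSS.
#'
#' Orthogonalization is carried out in the basis's scaled channel units
#' (consistent with joint PC estimation); the subspace's own scaling is
#' undone first. Left singular vectors with singular value below
#' `rank_tol` times the largest are dropped with a warning, so merging PCs
#' already contained in `span(S_out)` does not grow the basis.
#'
#' @param basis an `sss_basis` from [build_sss_basis()].
#' @param subspace an `interference_subspace` (joint mode recommended), or
#'   `NULL` / zero-component subspace, in which case eSSS reduces to SSS.
#' @param rank_tol relative singular-value tolerance of `orth()`.
#' @param extra_components optional matrix of additional (scaled-unit)
#'   column patterns merged after the PCs (used for band-limited artifact
#'   components, see [extend_with_band_components()]).
#' @return an `esss_basis` (inherits `sss_basis`); its `S_out` slot holds
#'   the orthonormal `S_out_e`, and `condition_number` the ratio of largest
#'   to smallest singular value of `S_e`.
#' @export
extend_external_basis <- function(basis, subspace, rank_tol = 1e-8,
                                  extra_components = NULL) {
  stopifnot(inherits(basis, "sss_basis"))
  if (is.null(subspace)) subspace <- empty_subspace(basis$channel_names)
  stopifnot(inherits(subspace, "interference_subspace"))
  check_channels_match(basis$channel_names, subspace$channel_names,
                       "interference subspace")
  # PCs back to native units, then into the basis's scaled units
  U <- subspace$U
  if (ncol(U)) {
    U <- (U / subspace$scale) * basis$scale
    U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  }
  C <- cbind(basis$S_out, U, extra_components)
  sv <- svd(C)
  keep <- sv$d > rank_tol * sv$d[1]
  if (!all(keep)) {
    warning(sum(!keep), " merged component(s) linearly dependent on the ",
            "external basis were dropped", call. = FALSE)
  }
  S_out_e <- sv$u[, keep, drop = FALSE]
  D_e <- ncol(S_out_e)
  N <- length(basis$channel_names)
  if (basis$D_in + D_e >= N) {
    stop_megshield("extended basis (", basis$D_in + D_e, " vectors) ",
                   "exceeds the oversampling margin of ", N, " channels")
  }
  sv_full <- svd(cbind(basis$S_in, S_out_e))
  ext <- basis
  ext$S_out <- S_out_e
  ext$D_out <- D_e
  ext$col_norms <- c(basis$col_norms[seq_len(basis$D_in)], rep(1, D_e))
  ext$index <- rbind(basis$index[seq_len(basis$D_in), ],
                     data.frame(l = NA, m = NA,
                                domain = rep("out_e", D_e)))
  ext$svd <- sv_full
  ext$cond <- sv_full$d[1] / sv_full$d[length(sv_full$d)]
  ext$provenance <- list(
    n_pcs_merged = ncol(U), n_extra = ncol(extra_components) %||% 0L,
    n_dropped = sum(!keep), rank_tol = rank_tol,
    pc_meta = subspace$source_meta)
  class(ext) <- c("esss_basis", "sss_basis")
  ext
}

#' Extend the basis with band-limited artifact components (eSSS')
#'
#' For artifacts whose spatial pattern lies outside both the computational
#' external basis and the broadband empty-room PCs (e.g. mechanical
#' vibration of the shielded room in a narrow frequency band), additional
#' components can be estimated from band-pass-filtered data:
#' `S_out_e' = orth([S_out  PC_out  PC_out_f])`. The artifact recording is
#' filtered with a zero-phase FFT band-pass (exact stopband, cosine-tapered
#' edges of `taper_hz`): strong interference lines just outside the band
#' must not leak into the band PCA, which rules out low-order IIR designs.
#' The top `n_components` joint PCs of the filtered data are extracted and
#' all components are orthogonalized together.
#'
#' @inheritParams extend_external_basis
#' @param artifact_recording recording containing the artifact (often the
#'   same empty-room data).
#' @param band `c(f_lo, f_hi)` in Hz, inside `(0, sfreq/2)`.
#' @param n_components number of band-limited PCs (often fewer than the
#'   broadband PCs suffice); 0 reduces to [extend_external_basis()].
#' @param mag_scale magnetometer scaling for the joint band-PC estimation.
#' @param taper_hz width of the raised-cosine band edges, Hz.
#' @return an `esss_basis`.
#' @export
extend_with_band_components <- function(basis, subspace, artifact_recording,
                                        band, n_components = 3,
                                        mag_scale = 100, rank_tol = 1e-8,
                                        taper_hz = 0.5) {
  if (n_components == 0) return(extend_external_basis(basis, subspace,
                                                      rank_tol))
  sf <- artifact_recording$sfreq
  if (band[1] <= 0 || band[2] >= sf / 2 || band[1] >= band[2]) {
    stop_megshield("band must satisfy 0 < f_lo < f_hi < sfreq/2")
  }
  check_channels_match(basis$channel_names,
                       artifact_recording$channel_names, "artifact recording")
  X <- artifact_recording$data
  Xf <- fft_bandpass(X - rowMeans(X), sf, band, taper_hz)
  band_power <- sum(Xf^2) / sum((X - rowMeans(X))^2)
  if (band_power < 1e-12) {
    warning("band [", band[1], ", ", band[2], "] Hz contains almost no ",
            "energy; proceeding", call. = FALSE)
  }
  filt_rec <- new_recording(Xf, sf, artifact_recording$channel_names)
  band_sub <- estimate_interference_subspace(filt_rec, n_components,
                                             mode = "joint",
                                             mag_scale = mag_scale)
  Uf <- (band_sub$U / band_sub$scale) * basis$scale
  Uf <- sweep(Uf, 2, sqrt(colSums(Uf^2)), "/")
  ext <- extend_external_basis(basis, subspace, rank_tol,
                               extra_components = Uf)
  ext$provenance$band_hz <- band
  ext$provenance$n_band_pcs <- n_components
  ext
}

# zero-phase FFT band-pass of an N x T matrix: exact stopband with
# raised-cosine edges; real part of the masked inverse transform
fft_bandpass <- function(X, sfreq, band, taper_hz = 0.5) {
  Tn <- ncol(X)
  f <- c(seq(0, floor(Tn / 2)), seq(-ceiling(Tn / 2) + 1, -1)) * sfreq / Tn
  af <- abs(f)
  mask <- numeric(Tn)
  core <- af >= band[1] & af <= band[2]
  mask[core] <- 1
  if (taper_hz > 0) {
    lo <- af > band[1] - taper_hz & af < band[1]
    mask[lo] <- 0.5 * (1 + cos(pi * (band[1] - af[lo]) / taper_hz))
    hi <- af > band[2] & af < band[2] + taper_hz
    mask[hi] <- 0.5 * (1 + cos(pi * (af[hi] - band[2]) / taper_hz))
  }
  sp <- stats::mvfft(t(X)) * mask
  t(Re(stats::mvfft(sp, inverse = TRUE))) / Tn
}

#' Apply eSSS interference suppression
#'
#' Full eSSS pipeline: build the SSS basis on the (nominal) array, estimate
#' `n_pcs` joint principal components from an unprocessed empty-room
#' recording (magnetometers scaled by `mag_scale`), merge them into the
#' external basis with SVD orthogonalization, decompose the recording in
#' the extended basis, and reconstruct the internal part. Like SSS this is
#' a linear, idempotent oblique projection, so brain signals in
#' `span(S_in)` are neither projected out nor biased; unlike SSS, external
#' interference whose empirical pattern was captured in the empty room is
#' suppressed even under imperfect calibration.
#'
#' @inheritParams apply_sss
#' @param empty_room empty-room `meg_recording` (same channel order).
#' @param n_pcs number of empty-room PCs merged (default 8: homogeneous +
#'   first-order-gradient fields occupy 3 + 5 degrees of freedom).
#' @param mag_scale magnetometer scaling for joint PC estimation.
#' @param basis optional prebuilt `esss_basis` (skips estimation; `array`,
#'   `empty_room` ignored).
#' @return processed `meg_recording` with a condition report in provenance.
#' @export
apply_esss <- function(recording, array = NULL, empty_room = NULL,
                       n_pcs = 8, L_in = 8, L_out = 3, mag_scale = 100,
                       basis = NULL) {
  if (is.null(basis)) {
    sss <- build_sss_basis(array, L_in, L_out)
    check_channels_match(sss$channel_names, empty_room$channel_names,
                         "empty room")
    sub <- estimate_interference_subspace(empty_room, n_pcs, mode = "joint",
                                          mag_scale = mag_scale,
                                          array = array)
    basis <- extend_external_basis(sss, sub)
  }
  moments <- sss_decompose(basis, recording)
  out <- reconstruct_internal(basis, moments)
  out$provenance <- c(recording$provenance, out$provenance)
  rep <- condition_report(basis)
  add_provenance(out, "apply_esss", n_vectors = rep$n_vectors,
                 condition_number = rep$condition_number)
}

#' Basis size and condition report
#'
#' Reports the number of basis vectors and the condition number (ratio of
#' largest to smallest singular value) of a basis. Adding empirical
#' components to the SSS basis can increase the condition number and hence
#' the reconstruction noise; a well-chosen extension leaves it nearly
#' unchanged, which this report makes auditable.
#'
#' @param basis an `sss_basis`, `esss_basis`, or plain numeric matrix.
#' @return list with `n_vectors` and `condition_number`.
#' @export
condition_report <- function(basis) {
  if (is.matrix(basis)) {
    d <- svd(basis, nu = 0, nv = 0)$d
    return(list(n_vectors = ncol(basis),
                condition_number = d[1] / d[length(d)]))
  }
  stopifnot(inherits(basis, "sss_basis"))
  list(n_vectors = basis$D_in + ncol(basis$S_out),
       condition_number = basis$cond)
}
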