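#' SSS decomposition and internal reconstruction
#'
#' `sss_decompose()` estimates the magnetostatic multipole moments
#' `x = [x_in; x_out]` of a recording as the least-squares solution
#' `x = pinv(S) phi` per time sample, with the pseudoinverse computed by
#' truncated SVD (relative singular-value cutoff, default 1e-10) rather
#' than normal equations: the joint basis has a condition number of order
#' 100, where `(S'S)^-1 S'` is numerically fragile. Channel-type scaling is
#' applied consistently with basis construction. The moments are
#' coordinates in the *normalized* basis; `col_norms` in the basis maps
#' them back to physical multipole units.
#'
#' `reconstruct_internal()` maps the internal moments back to sensor space,
#' `phi_in = S_in x_in`, in native sensor units; the external expansion is
#' discarded, which is what suppresses external interference.
#'
#' @param basis an `sss_basis` or `esss_basis`.
#' @param recording a [new_recording] whose channel order matches the basis.
#' @param sv_tol relative singular value cutoff of the pseudoinverse.
#' @return `sss_decompose` returns a `multipole_moments` object with
#'   matrices `x_in` (D_in x T) and `x_out` (D_out x T).
#' @export
sss_decompose <- function(basis, recording, sv_tol = 1e-10) {
  stopifnot(inherits(basis, "sss_basis"))
  check_channels_match(basis$channel_names, recording$channel_names)
  sv <- basis$svd
  keep <- sv$d > sv_tol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  phi_s <- recording$data * basis$scale
  x <- sv$v %*% (dinv * crossprod(sv$u, phi_s))
  D_in <- basis$D_in
  structure(list(
    x_in = x[seq_len(D_in), , drop = FALSE],
    x_out = x[-seq_len(D_in), , drop = FALSE],
    D_in = D_in, D_out = nrow(x) - D_in,
    index = basis$index, col_norms = basis$col_norms,
    sfreq = recording$sfreq, channel_names = basis$channel_names
  ), class = "multipole_moments")
}

#' @rdname sss_decompose
#' @param moments a `multipole_moments` object produced from the same basis.
#' @export
reconstruct_internal <- function(basis, moments) {
  stopifnot(inherits(basis, "sss_basis"),
            inherits(moments, "multipole_moments"))
  if (nrow(moments$x_in) != basis$D_in) {
    stop_megshield("moments have ", nrow(moments$x_in),
                   " internal components, basis expects ", basis$D_in)
  }
  data <- (basis$S_in %*% moments$x_in) / basis$scale
  new_recording(data, moments$sfreq, basis$channel_names,
                provenance = list(list(step = "reconstruct_internal",
                                       D_in = basis$D_in)))
}

#' Apply SSS interference suppression
#'
#' Convenience composition of [build_sss_basis()], [sss_decompose()] and
#' [reconstruct_internal()] with the default expansion orders `L_in = 8`,
#' `L_out = 3` and the expansion origin of the array (the middle of the
#' sensor helmet). The operation is linear and idempotent: an oblique
#' projection onto `span(S_in)` along `span(S_out)` that leaves signals
#' already in `span(S_in)` untouched.
#'
#' @inheritParams build_sss_basis
#' @param recording recording to process.
#' @param basis optionally a prebuilt basis (skips rebuilding; `array` is
#'   then ignored).
#' @return the processed `meg_recording`, with the basis size and condition
#'   number recorded in its provenance.
#' @export
apply_sss <- function(recording, array = NULL, L_in = 8, L_out = 3,
                      basis = NULL) {
  if (is.null(basis)) basis <- build_sss_basis(array, L_in, L_out)
  moments <- sss_decompose(basis, recording)
  out <- reconstruct_internal(basis, moments)
  out$provenance <- c(recording$provenance, out$provenance)
  add_provenance(out, "apply_sss", L_in = basis$L_in, L_out = basis$L_out,
                 n_vectors = basis$D_in + ncol(basis$S_out),
                 condition_number = basis$cond)
}
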