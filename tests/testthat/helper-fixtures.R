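# shared fixtures, built lazily and cached for the whole test run

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

small_helmet <- function() {
  # 40 sites = 120 channels: smallest array that oversamples the default
  # 95-vector basis and its 103-vector extension
  fixture("small_helmet", function() build_synthetic_helmet(40))
}

small_basis <- function() {
  fixture("small_basis", function() build_sss_basis(small_helmet()))
}

full_helmet <- function() {
  fixture("full_helmet", function() build_synthetic_helmet(102))
}

full_basis <- function() {
  fixture("full_basis", function() build_sss_basis(full_helmet()))
}

# a tangential dipole with deterministic geometry
make_dipole <- function(radius = 0.05, dir = c(2, 1, 3), mom = c(1, -2, 0.5),
                        amplitude = 1000e-9) {
  u <- dir / sqrt(sum(dir^2))
  p <- radius * u
  v <- mom - sum(mom * u) * u
  dipole_source(p, v / sqrt(sum(v^2)), amplitude)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
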