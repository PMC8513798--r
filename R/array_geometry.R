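#' Sensor arrays for MEG interference modeling
#'
#' A `meg_sensor_array` describes the geometry and calibration of a
#' multichannel MEG sensor helmet in right-handed device coordinates (origin
#' at the helmet center, z toward the vertex, SI units: m, T, T/m). Each
#' channel is either a magnetometer (area-averaged normal field, tesla) or a
#' planar gradiometer (balanced two-loop difference along a tangential
#' baseline, tesla/meter). Pick-up coils are discretized into integration
#' points `(r_i, w_i)` such that `gain * sum_i w_i B(r_i) . n` is the channel
#' output; magnetometer weights sum to 1 and gradiometer weights to 0.
#'
#' The flat in-memory layout (channel-level vectors plus pooled
#' integration-point matrices indexed by channel) is the single source of
#' truth for channel ordering: every matrix in the package uses this row
#' order.
#'
#' @param origin expansion origin (3-vector, m), the reference point of the
#'   harmonic expansions ("middle of the sensor helmet").
#' @param inner_radius radius (m) of the sphere around `origin` guaranteed to
#'   be source-free; all integration points must lie outside it.
#' @name meg_sensor_array
NULL

new_sensor_array <- function(name, kind, position, orientation, baseline_dir,
                             gain, ip_pos, ip_w, ip_channel, origin,
                             inner_radius, version = "1.0") {
  arr <- list(
    version = version,
    origin = as.numeric(origin),
    inner_radius = as.numeric(inner_radius),
    name = as.character(name),
    kind = as.character(kind),
    position = position,
    orientation = orientation,
    baseline_dir = baseline_dir,
    gain = as.numeric(gain),
    ip_pos = ip_pos,
    ip_w = as.numeric(ip_w),
    ip_channel = as.integer(ip_channel)
  )
  class(arr) <- "meg_sensor_array"
  arr
}

n_channels <- function(array) length(array$name)

is_magnetometer <- function(array) array$kind == "magnetometer"

#' Validate a sensor array
#'
#' Checks the structural invariants of a [meg_sensor_array]: unique channel
#' names, unit coil normals, magnetometer integration weights summing to 1
#' and gradiometer weights to 0, at least one integration point per channel,
#' and all integration points outside the source-free `inner_radius`.
#'
#' @param array a `meg_sensor_array`.
#' @return `array`, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_array <- function(array) {
  if (!inherits(array, "meg_sensor_array")) {
    stop_megshield("not a 'meg_sensor_array' object")
  }
  N <- n_channels(array)
  if (anyDuplicated(array$name)) {
    stop_megshield("duplicate channel names: ",
                   array$name[anyDuplicated(array$name)])
  }
  if (!all(array$kind %in% c("magnetometer", "planar_gradiometer"))) {
    stop_megshield("invalid channel kind; must be 'magnetometer' or ",
                   "'planar_gradiometer'")
  }
  onorm <- sqrt(rowSums(array$orientation^2))
  if (any(abs(onorm - 1) > 1e-12)) {
    stop_megshield("orientation of channel '",
                   array$name[which.max(abs(onorm - 1))],
                   "' is not a unit vector")
  }
  tab <- tabulate(array$ip_channel, nbins = N)
  if (any(tab < 1L)) {
    stop_megshield("channel '", array$name[which(tab < 1L)[1]],
                   "' has no integration points")
  }
  wsum <- as.numeric(rowsum(array$ip_w, array$ip_channel))
  wabs <- as.numeric(rowsum(abs(array$ip_w), array$ip_channel))
  mags <- is_magnetometer(array)
  if (any(abs(wsum[mags] - 1) > 1e-12)) {
    stop_megshield("magnetometer integration weights must sum to 1")
  }
  # relative loop imbalance; exact balance at construction, small nonzero
  # values arise from calibration-error injection, >10% flags corruption
  if (any(abs(wsum[!mags]) * 2 / wabs[!mags] > 0.1)) {
    stop_megshield("gradiometer integration weights are grossly unbalanced")
  }
  d <- sqrt(rowSums((array$ip_pos -
                       matrix(array$origin, nrow(array$ip_pos), 3,
                              byrow = TRUE))^2))
  if (any(d <= array$inner_radius)) {
    stop_megshield("integration points inside inner_radius (",
                   array$inner_radius, " m); source-free shell violated")
  }
  invisible(array)
}

# local tangent frame (e_theta, e_phi) at unit radial direction u
tangent_frame <- function(u) {
  if (abs(u[3]) > 1 - 1e-9) {
    # vertex: spherical frame degenerates; pick fixed tangentials
    return(list(e_th = c(1, 0, 0), e_ph = c(0, 1, 0)))
  }
  e_ph <- unit(c(-u[2], u[1], 0))
  e_th <- unit(c(u[3] * u[1], u[3] * u[2], -(u[1]^2 + u[2]^2)) /
                 sqrt(u[1]^2 + u[2]^2))
  list(e_th = e_th, e_ph = e_ph)
}

#' Build a synthetic MEG helmet array
#'
#' Generates a deterministic, quasi-uniform helmet of sensor sites on the
#' spherical cap `z > -0.1 * helmet_radius` (Fibonacci lattice restricted to
#' the cap). Each site carries one magnetometer with radial normal and two
#' orthogonal planar gradiometers with tangential baselines, mimicking the
#' triple-sensor layout of 306-channel MEG systems: `n_sites = 102` yields
#' 306 channels.
#'
#' Coil discretization: magnetometers average the normal field over a square
#' coil (side 21 mm) with a 2x2 Gauss rule (4 points, weights 1/4);
#' gradiometers use two square loops (side 12 mm) separated by a 16.8 mm
#' baseline, 4 Gauss points per loop with weights `+-1/(4 * baseline)`, so
#' that the output approximates the tangential derivative of the normal
#' field in T/m. All gains are 1.
#'
#' @param n_sites number of sensor sites (>= 32 so the 306-channel-like array
#'   oversamples the default L_in=8, L_out=3 harmonic basis).
#' @param helmet_radius helmet radius in meters (default 0.12).
#' @param origin expansion origin, defaults to the helmet center `c(0,0,0)`.
#' @return a [meg_sensor_array] with `3 * n_sites` channels.
#' @examples
#' helmet <- build_synthetic_helmet(102)
#' sum(helmet$kind == "magnetometer")  # 102
#' @export
build_synthetic_helmet <- function(n_sites, helmet_radius = 0.12,
                                   origin = c(0, 0, 0)) {
  if (n_sites < 32) {
    stop_megshield("n_sites = ", n_sites, " is too small to span the ",
                   "default SSS basis (95 vectors); need n_sites >= 32 ",
                   "(96 channels)")
  }
  if (helmet_radius <= 0) stop_megshield("helmet_radius must be positive")
  origin <- as.numeric(origin)

  baseline <- 0.0168           # planar-gradiometer baseline, m
  mag_side <- 0.021            # magnetometer coil side, m
  loop_side <- 0.012           # gradiometer loop side, m
  g2 <- 1 / (2 * sqrt(3))      # 2x2 Gauss offset factor for a unit square

  # Fibonacci lattice on the cap z/R in (-0.1, 1]
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_sites)
  zf <- 1 - (i - 0.5) / n_sites * 1.1   # from ~1 down to ~-0.1
  phi <- golden * (i - 1)

  nm <- character(0); kd <- character(0)
  pos <- NULL; ori <- NULL; bdir <- NULL
  ipp <- NULL; ipw <- numeric(0); ipc <- integer(0)
  ch <- 0L

  for (s in seq_len(n_sites)) {
    u <- c(sqrt(max(0, 1 - zf[s]^2)) * cos(phi[s]),
           sqrt(max(0, 1 - zf[s]^2)) * sin(phi[s]),
           zf[s])
    u <- unit(u)
    p <- origin + helmet_radius * u
    fr <- tangent_frame(u)

    # magnetometer
    ch <- ch + 1L
    nm <- c(nm, sprintf("MAG%03d", s)); kd <- c(kd, "magnetometer")
    pos <- rbind(pos, p); ori <- rbind(ori, u); bdir <- rbind(bdir, c(NA, NA, NA))
    off <- mag_side * g2
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
      ipp <- rbind(ipp, p + sx * off * fr$e_th + sy * off * fr$e_ph)
      ipw <- c(ipw, 0.25); ipc <- c(ipc, ch)
    }

    # two planar gradiometers, baselines along e_th and e_ph
    for (b in 1:2) {
      ch <- ch + 1L
      bd <- if (b == 1) fr$e_th else fr$e_ph
      td <- if (b == 1) fr$e_ph else fr$e_th
      nm <- c(nm, sprintf("GRAD%03d%s", s, c("A", "B")[b]))
      kd <- c(kd, "planar_gradiometer")
      pos <- rbind(pos, p); ori <- rbind(ori, u); bdir <- rbind(bdir, bd)
      for (sgn in c(1, -1)) {
        cen <- p + sgn * (baseline / 2) * bd
        for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
          ipp <- rbind(ipp, cen + sx * loop_side * g2 * bd +
                         sy * loop_side * g2 * td)
          ipw <- c(ipw, sgn / (4 * baseline)); ipc <- c(ipc, ch)
        }
      }
    }
  }
  dimnames(pos) <- NULL; dimnames(ori) <- NULL; dimnames(bdir) <- NULL
  dimnames(ipp) <- NULL

  arr <- new_sensor_array(nm, kd, pos, ori, bdir, gain = rep(1, ch),
                          ip_pos = ipp, ip_w = ipw, ip_channel = ipc,
                          origin = origin,
                          inner_radius = 0.8 * helmet_radius)
  validate_array(arr)
}

#' Inject calibration errors into a sensor array
#'
#' Returns a copy of the array with per-channel gains multiplied by
#' `1 + e`, `e ~ N(0, gain_sd^2)` i.i.d.; gradiometer loop imbalance drawn
#' as `d ~ N(0, imbalance_sd^2)` and applied as `(1 + d/2)` / `(1 - d/2)`
#' area scalings of the two pick-up loops; and (optionally) each pick-up
#' coil rotated about its center by a random axis through an angle
#' `|N(0, orient_sd^2)|`. This models the calibration uncertainty of a real
#' device (~1% without fine calibration, ~0.1% with it), which comprises
#' electronic gain, pick-up coil areas and the imbalance between
#' gradiometer loops. The imbalance term matters: it is what makes planar
#' gradiometers respond to homogeneous fields, the dominant leakage path
#' that limits the SSS shielding factor under imperfect calibration; a
#' perfectly balanced gradiometer would stay exactly blind to them. The
#' default `imbalance_sd = sqrt(2) * gain_sd` is the differential of two
#' independent loop-area errors of size `gain_sd`. The input array is
#' untouched and the result is reproducible by `seed`.
#'
#' @param array a [meg_sensor_array].
#' @param gain_sd standard deviation of the relative per-channel gain error
#'   (dimensionless, e.g. 0.01 for 1%).
#' @param orient_sd standard deviation of the coil rotation angle (radians);
#'   default 0.
#' @param seed integer seed.
#' @param imbalance_sd standard deviation of the relative area imbalance
#'   between the two loops of each planar gradiometer.
#' @return a perturbed `meg_sensor_array`.
#' @export
perturb_calibration <- function(array, gain_sd, orient_sd = 0, seed = 1L,
                                imbalance_sd = sqrt(2) * gain_sd) {
  validate_array(array)
  if (gain_sd < 0 || orient_sd < 0 || imbalance_sd < 0) {
    stop_megshield("gain_sd, orient_sd and imbalance_sd must be non-negative")
  }
  N <- n_channels(array)
  run_seeded(seed, {
    out <- array
    out$gain <- array$gain * (1 + stats::rnorm(N, 0, gain_sd))
    if (imbalance_sd > 0) {
      grads <- which(!is_magnetometer(array))
      d <- stats::rnorm(length(grads), 0, imbalance_sd)
      for (gi in seq_along(grads)) {
        rows <- which(array$ip_channel == grads[gi])
        # loops are identified by weight sign (+/- 1/(4 * baseline))
        pos_loop <- array$ip_w[rows] > 0
        out$ip_w[rows[pos_loop]] <- array$ip_w[rows[pos_loop]] *
          (1 + d[gi] / 2)
        out$ip_w[rows[!pos_loop]] <- array$ip_w[rows[!pos_loop]] *
          (1 - d[gi] / 2)
      }
    }
    if (orient_sd > 0) {
      for (j in seq_len(N)) {
        ax <- stats::rnorm(3)
        ang <- abs(stats::rnorm(1, 0, orient_sd))
        R <- rotation_about(ax, ang)
        out$orientation[j, ] <- as.numeric(R %*% array$orientation[j, ])
        if (!any(is.na(array$baseline_dir[j, ]))) {
          out$baseline_dir[j, ] <- as.numeric(R %*% array$baseline_dir[j, ])
        }
        rows <- which(array$ip_channel == j)
        offs <- array$ip_pos[rows, , drop = FALSE] -
          matrix(array$position[j, ], length(rows), 3, byrow = TRUE)
        out$ip_pos[rows, ] <- matrix(array$position[j, ], length(rows), 3,
                                     byrow = TRUE) + offs %*% t(R)
      }
    }
    out
  })
}

#' Save or load a sensor array as JSON
#'
#' Lossless round trip of all array fields through a versioned JSON schema
#' with SI units stated in the field names:
#' `{version, origin_m, inner_radius_m, channels: [{name, kind, position_m,
#' orientation, baseline_dir?, integration_points: [{r_m, w}], gain}]}`.
#'
#' @param array a [meg_sensor_array].
#' @param path file path.
#' @return `load_array` returns a validated `meg_sensor_array`; `save_array`
#'   returns `path` invisibly.
#' @export
save_array <- function(array, path) {
  validate_array(array)
  chans <- lapply(seq_len(n_channels(array)), function(j) {
    rows <- which(array$ip_channel == j)
    ch <- list(
      name = array$name[j],
      kind = array$kind[j],
      position_m = array$position[j, ],
      orientation = array$orientation[j, ],
      integration_points = lapply(rows, function(r) {
        list(r_m = array$ip_pos[r, ], w = array$ip_w[r])
      }),
      gain = array$gain[j]
    )
    if (!any(is.na(array$baseline_dir[j, ]))) {
      ch$baseline_dir <- array$baseline_dir[j, ]
    }
    ch
  })
  obj <- list(version = array$version, origin_m = array$origin,
              inner_radius_m = array$inner_radius, channels = chans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_array
#' @export
load_array <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("version", "origin_m", "inner_radius_m", "channels")) {
    if (is.null(obj[[f]])) stop_megshield("array file missing field '", f, "'")
  }
  nm <- character(0); kd <- character(0); gain <- numeric(0)
  pos <- NULL; ori <- NULL; bdir <- NULL
  ipp <- NULL; ipw <- numeric(0); ipc <- integer(0)
  for (j in seq_along(obj$channels)) {
    ch <- obj$channels[[j]]
    for (f in c("name", "kind", "position_m", "orientation",
                "integration_points", "gain")) {
      if (is.null(ch[[f]])) {
        stop_megshield("channel ", j, " missing field '", f, "'")
      }
    }
    nm <- c(nm, ch$name); kd <- c(kd, ch$kind); gain <- c(gain, ch$gain)
    pos <- rbind(pos, unlist(ch$position_m))
    ori <- rbind(ori, unlist(ch$orientation))
    bdir <- rbind(bdir, if (is.null(ch$baseline_dir)) c(NA, NA, NA) else
      unlist(ch$baseline_dir))
    for (ip in ch$integration_points) {
      if (is.null(ip$r_m) || is.null(ip$w)) {
        stop_megshield("channel '", ch$name,
                       "': integration point missing 'r_m' or 'w'")
      }
      ipp <- rbind(ipp, unlist(ip$r_m)); ipw <- c(ipw, ip$w)
      ipc <- c(ipc, j)
    }
  }
  dimnames(pos) <- NULL; dimnames(ori) <- NULL; dimnames(bdir) <- NULL
  dimnames(ipp) <- NULL
  arr <- new_sensor_array(nm, kd, pos, ori, bdir, gain, ipp, ipw, ipc,
                          origin = unlist(obj$origin_m),
                          inner_radius = obj$inner_radius_m,
                          version = obj$version)
  validate_array(arr)
}

#' @export
print.meg_sensor_array <- function(x, ...) {
  cat("<meg_sensor_array> ", n_channels(x), " channels (",
      sum(is_magnetometer(x)), " magnetometers, ",
      sum(!is_magnetometer(x)), " planar gradiometers)\n", sep = "")
  cat("  origin:", paste(signif(x$origin, 4), collapse = " "),
      "m; inner radius:", signif(x$inner_radius, 4), "m\n")
  invisible(x)
}
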