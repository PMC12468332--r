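#' Circular probe array geometry
#'
#' Builds the geometry of the scanner's horizontal circular probe array. The
#' array carries `n_probes` wideband probes equally spaced on a ring of radius
#' `ring_radius` and is stepped vertically in `z_step` increments. The
#' coordinate convention is right-handed with the z axis vertical, z = 0 at
#' the examination-table plane and negative values below it; the uppermost
#' scan position lies `top_offset` mm below the table.
#'
#' @param ring_radius ring radius in mm (must exceed the phantom radius).
#' @param z_min,z_max vertical scan extent in mm (both negative, `z_max >
#'   z_min`); the scan positions run from `z_max` downwards in `z_step` steps.
#' @param n_probes number of probes on the ring (default 21).
#' @param z_step vertical step in mm (default 2).
#' @param top_offset distance of the uppermost admissible scan position below
#'   the table plane, in mm (default 24).
#' @return an object of class `probe_array` with fields `n_probes`,
#'   `ring_radius`, `azimuth` (radians), `z_positions` (mm, ordered from the
#'   table downwards), `z_step`, `top_offset`.
#' @export
probe_array <- function(ring_radius, z_min, z_max = -24, n_probes = 21,
                        z_step = 2, top_offset = 24) {
  if (!is.finite(ring_radius) || ring_radius <= 0)
    stop("invalid geometry: ring_radius must be positive")
  if (z_max <= z_min) stop("invalid geometry: z_max must exceed z_min")
  if (z_max > -top_offset + 1e-9)
    stop("invalid geometry: uppermost scan position cannot be above the ",
         top_offset, " mm table offset")
  structure(list(
    n_probes    = as.integer(n_probes),
    ring_radius = ring_radius,
    azimuth     = 2 * pi * (seq_len(n_probes) - 1L) / n_probes,
    z_positions = seq(z_max, z_min, by = -z_step),
    z_step      = z_step,
    top_offset  = top_offset
  ), class = "probe_array")
}

#' @export
print.probe_array <- function(x, ...) {
  cat(sprintf("<probe_array> %d probes on a %g mm ring, %d scan heights (%g to %g mm, step %g mm)\n",
              x$n_probes, x$ring_radius, length(x$z_positions),
              max(x$z_positions), min(x$z_positions), x$z_step))
  invisible(x)
}

#' Cartesian probe positions at one scan height
#'
#' @param array a [probe_array()].
#' @param z scan height in mm.
#' @return `n_probes` x 3 matrix of xyz coordinates in mm.
#' @export
probe_positions <- function(array, z) {
  cbind(array$ring_radius * cos(array$azimuth),
        array$ring_radius * sin(array$azimuth),
        rep(z, array$n_probes))
}

#' Pendulous breast envelope as a radius function
#'
#' The breast surface is represented as a radius function rho(theta, z)
#' sampled on a regular azimuthal x vertical grid with bilinear interpolation
#' (periodic in theta). The surface is closed at the top by the table plane
#' (z = `z_top`), so the envelope is watertight by construction.
#'
#' @param rho matrix of radii in mm, `length(theta)` x `length(z)`.
#' @param theta azimuthal grid in radians, regular over `[0, 2*pi)`.
#' @param z vertical grid in mm, increasing, with `max(z)` at the chest-wall
#'   (table) plane.
#' @return object of class `breast_envelope`.
#' @export
breast_envelope <- function(rho, theta, z) {
  stopifnot(is.matrix(rho), nrow(rho) == length(theta), ncol(rho) == length(z))
  if (any(rho < 0)) stop("envelope radii must be nonnegative")
  structure(list(rho = rho, theta = theta, z = z,
                 z_top = max(z), z_bottom = min(z)),
            class = "breast_envelope")
}

#' Teardrop pendulous envelope
#'
#' Convenience constructor for a smooth pendulous envelope: widest near the
#' chest wall, tapering to a tip at depth `depth` below it. The optional
#' azimuthal modulation breaks rotational symmetry.
#'
#' @param r_max maximal radius in mm.
#' @param depth vertical extent below the chest-wall plane, in mm.
#' @param z_top chest-wall plane height (default 0 = table plane).
#' @param taper_power shape exponent; 2 gives a hemispherical profile.
#' @param azim_mod relative amplitude of a 2nd-harmonic azimuthal modulation.
#' @param n_theta,n_z grid resolution.
#' @export
pendulous_envelope <- function(r_max, depth, z_top = 0, taper_power = 2,
                               azim_mod = 0, n_theta = 90, n_z = 61) {
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  z <- seq(z_top - depth, z_top, length.out = n_z)
  zeta <- (z_top - z) / depth                      # 0 at chest, 1 at tip
  prof <- r_max * (pmax(0, 1 - zeta^taper_power))^(1 / taper_power)
  rho <- outer(1 + azim_mod * cos(2 * theta), prof)
  breast_envelope(rho, theta, z)
}

#' @export
print.breast_envelope <- function(x, ...) {
  cat(sprintf("<breast_envelope> max radius %.1f mm, depth %.1f mm (z in [%.1f, %.1f])\n",
              max(x$rho), x$z_top - x$z_bottom, x$z_bottom, x$z_top))
  invisible(x)
}

# Bilinear interpolation of rho(theta, z); periodic in theta.
envelope_radius <- function(env, theta, z) {
  nt <- length(env$theta); nz <- length(env$z)
  dth <- 2 * pi / nt
  th <- theta %% (2 * pi)
  it <- floor(th / dth)                      # 0-based lower theta index
  ft <- th / dth - it
  i0 <- (it %% nt) + 1L
  i1 <- ((it + 1L) %% nt) + 1L
  dz <- env$z[2] - env$z[1]
  zc <- pmin(pmax(z, env$z[1]), env$z[nz])
  jz <- pmin(floor((zc - env$z[1]) / dz), nz - 2)
  fz <- (zc - env$z[1]) / dz - jz
  j0 <- jz + 1L; j1 <- jz + 2L
  env$rho[cbind(i0, j0)] * (1 - ft) * (1 - fz) +
    env$rho[cbind(i1, j0)] * ft * (1 - fz) +
    env$rho[cbind(i0, j1)] * (1 - ft) * fz +
    env$rho[cbind(i1, j1)] * ft * fz
}

#' Inside/outside predicate of a breast envelope
#'
#' @param env a [breast_envelope()].
#' @param pts numeric vector (length 3) or N x 3 matrix of points in mm.
#' @return logical vector; `TRUE` for points inside or on the surface.
#' @export
env_inside <- function(env, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  ok_z <- pts[, 3] >= env$z_bottom & pts[, 3] <= env$z_top
  out <- rep(FALSE, nrow(pts))
  if (any(ok_z))
    out[ok_z] <- r[ok_z] <= envelope_radius(env, th[ok_z], pts[ok_z, 3]) + 1e-9
  out
}

# First-entry fractions along rays source -> targets (targets inside).
# Vectorized bisection on the outside/inside indicator; envelopes used here
# are star-shaped about the axis, so the inside set along each ray is a
# single interval ending at the target.
ray_entry_fraction <- function(env, source, targets, iters = 48L) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3)
  n <- nrow(targets)
  lo <- rep(0, n); hi <- rep(1, n)
  src <- matrix(source, n, 3, byrow = TRUE)
  dvec <- targets - src
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    p <- src + dvec * mid
    ins <- env_inside(env, p)
    hi[ins] <- mid[ins]
    lo[!ins] <- mid[!ins]
  }
  (lo + hi) / 2
}

#' Split a straight ray into out-of-breast and in-breast path lengths
#'
#' For a transmit/receive probe outside the breast and a focal point inside
#' (or on) the envelope, splits the Euclidean source-target distance into the
#' leg travelled through the transition liquid (`d_out`) and the chord inside
#' the breast (`d_in`). Conservation `d_out + d_in = |source - target|` holds
#' exactly by construction.
#'
#' @param source,target xyz points in mm; `source` outside, `target` inside
#'   or on the envelope.
#' @param envelope a [breast_envelope()].
#' @return named numeric vector `c(d_out =, d_in =)` in mm.
#' @export
ray_path_split <- function(source, target, envelope) {
  if (env_inside(envelope, source))
    stop("source must lie outside the envelope")
  L <- sqrt(sum((target - source)^2))
  if (!env_inside(envelope, target)) {
    # target outside: whole path in the transition liquid
    return(c(d_out = L, d_in = 0))
  }
  tau <- ray_entry_fraction(envelope, source, matrix(target, 1, 3), iters = 60L)
  d_out <- tau * L
  c(d_out = d_out, d_in = L - d_out)
}

#' Envelope cross-sectional area at a height
#'
#' @param env a [breast_envelope()].
#' @param z height in mm.
#' @return area in mm^2 (0 outside the envelope's vertical extent).
#' @export
envelope_area <- function(env, z) {
  vapply(z, function(zz) {
    if (zz < env$z_bottom || zz > env$z_top) return(0)
    r <- envelope_radius(env, env$theta, rep(zz, length(env$theta)))
    mean(r^2) * pi                          # 1/2 * integral rho^2 dtheta
  }, numeric(1))
}

#' Detect the uppermost trusted scan slice (cut-out plane)
#'
#' Scan quality degrades at the posterior (table-side) end of the scan when
#' (a) the breast cross-section fills too much of the ring aperture, or (b)
#' the chest wall intrudes into the scanning zone. Slices failing either rule
#' are flagged excluded; the function returns the index (into
#' `array$z_positions`, ordered from the table downwards) of the uppermost
#' slice that is trusted.
#'
#' @param envelope a [breast_envelope()].
#' @param array a [probe_array()].
#' @param chest_intrusion chest-wall intrusion depth below the table plane in
#'   mm; any positive value excludes all slices above
#'   `-(top_offset + chest_intrusion)`.
#' @param area_fraction maximal admissible ratio of envelope cross-section to
#'   ring aperture area (default 0.9).
#' @return integer index of the first valid slice, or `NA_integer_` when the
#'   whole scan is valid.
#' @export
detect_cutout_slice <- function(envelope, array, chest_intrusion = 0,
                                area_fraction = 0.9) {
  z <- array$z_positions
  aperture <- pi * array$ring_radius^2
  bad <- envelope_area(envelope, z) > area_fraction * aperture
  if (chest_intrusion > 0)
    bad <- bad | (z > -(array$top_offset + chest_intrusion) + 1e-9)
  if (!any(bad)) return(NA_integer_)
  idx <- which(!bad)
  if (length(idx) == 0) return(length(z) + 1L)   # whole scan excluded
  idx[1]
}
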