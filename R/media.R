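SPEED_OF_LIGHT <- 299792458   # m/s

#' Dispersive media table
#'
#' Holds the relative permittivity and loss tangent of every propagation
#' medium of the imaging problem, as mildly dispersive linear-in-frequency
#' profiles around a reference frequency. The published system description
#' does not disclose the transition liquid's dielectric profile (only that it
#' is close to skin); all values here are configurable defaults in the range
#' reported by the microwave tissue-dielectric literature.
#'
#' @param media named list; each entry a list with `er0`, `tand0` (values at
#'   `f_ref`) and relative slopes `er_slope`, `tand_slope` per unit relative
#'   frequency offset.
#' @param f_ref reference frequency in Hz (default mid-band 2.45 GHz).
#' @return object of class `medium_model`.
#' @export
medium_model <- function(media = default_media_table(), f_ref = 2.45e9) {
  for (nm in names(media)) {
    m <- media[[nm]]
    if (m$er0 < 1) stop("relative permittivity must be >= 1 (", nm, ")")
    if (m$tand0 < 0) stop("loss tangent must be >= 0 (", nm, ")")
  }
  obj <- structure(list(media = media, f_ref = f_ref), class = "medium_model")
  # fibroglandular must dominate adipose across the scan band
  f <- seq(0.8e9, 4.1e9, length.out = 12)
  if (any(medium_eval(obj, "fibroglandular", f)$er <
          medium_eval(obj, "adipose", f)$er))
    stop("fibroglandular permittivity must be >= adipose at every frequency")
  obj
}

#' @rdname medium_model
#' @export
default_media_table <- function() {
  list(
    transition     = list(er0 = 23.0, er_slope = -0.06, tand0 = 0.13, tand_slope = 0.10),
    adipose        = list(er0 = 4.5,  er_slope = -0.04, tand0 = 0.12, tand_slope = 0.12),
    fibroglandular = list(er0 = 35.0, er_slope = -0.08, tand0 = 0.25, tand_slope = 0.10),
    skin           = list(er0 = 38.0, er_slope = -0.08, tand0 = 0.28, tand_slope = 0.10)
  )
}

#' Evaluate a medium's dielectric profile on a frequency grid
#'
#' @param model a [medium_model()].
#' @param name medium name.
#' @param f frequencies in Hz.
#' @return list with numeric vectors `er` and `tand`.
#' @export
medium_eval <- function(model, name, f) {
  m <- model$media[[name]]
  if (is.null(m)) stop("unknown medium: ", name)
  x <- (f - model$f_ref) / model$f_ref
  list(er = pmax(1, m$er0 * (1 + m$er_slope * x)),
       tand = pmax(0, m$tand0 * (1 + m$tand_slope * x)))
}

#' Complex wavenumber of a lossy dielectric
#'
#' Transmission-line propagation constant of a homogeneous lossy medium:
#' attenuation `alpha = (2 pi f / c0) sqrt(er/2 (sqrt(1 + tand^2) - 1))`
#' (Np/m) and phase `beta = (2 pi f / c0) sqrt(er/2 (sqrt(1 + tand^2) + 1))`
#' (rad/m). In the lossless limit `tand = 0` this reduces to `alpha = 0`,
#' `beta = 2 pi f sqrt(er) / c0`.
#'
#' @param f frequency in Hz (> 0); vectorized.
#' @param er relative permittivity (>= 1).
#' @param tand loss tangent (>= 0).
#' @return complex vector with `Re = alpha` (Np/m) and `Im = beta` (rad/m).
#' @export
complex_wavenumber <- function(f, er, tand) {
  if (any(f <= 0)) stop("frequency must be positive")
  if (any(er < 1)) stop("relative permittivity must be >= 1")
  if (any(tand < 0)) stop("loss tangent must be nonnegative")
  w <- 2 * pi * f / SPEED_OF_LIGHT
  root <- sqrt(1 + tand^2)
  complex(real = w * sqrt(er / 2 * (root - 1)),
          imaginary = w * sqrt(er / 2 * (root + 1)))
}

# Wavenumber of a named medium on a frequency grid.
medium_wavenumber <- function(model, name, f) {
  d <- medium_eval(model, name, f)
  complex_wavenumber(f, d$er, d$tand)
}

#' In-breast attenuation as a fibroglandular-content mixture
#'
#' The in-breast attenuation constant is the `pc_fib`-weighted mixture of the
#' fibroglandular and adipose attenuation profiles:
#' `alpha_in(f) = pc_fib * alpha_fib(f) + (1 - pc_fib) * alpha_adip(f)`.
#'
#' @param model a [medium_model()].
#' @param f frequencies in Hz.
#' @param pc_fib fibroglandular fraction in `[0, 1]`.
#' @return attenuation in Np/m.
#' @export
alpha_inbreast <- function(model, f, pc_fib) {
  if (pc_fib < 0 || pc_fib > 1) stop("pc_fib must lie in [0, 1]")
  pc_fib * Re(medium_wavenumber(model, "fibroglandular", f)) +
    (1 - pc_fib) * Re(medium_wavenumber(model, "adipose", f))
}

# Complex in-breast wavenumber from the linearly mixed dielectric profile;
# used by the forward model and the imaging steering vectors (the loss
# compensation term uses the weighted-alpha mixture above, as published).
wavenumber_inbreast <- function(model, f, pc_fib) {
  fib <- medium_eval(model, "fibroglandular", f)
  adi <- medium_eval(model, "adipose", f)
  complex_wavenumber(f, pc_fib * fib$er + (1 - pc_fib) * adi$er,
                     pc_fib * fib$tand + (1 - pc_fib) * adi$tand)
}
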