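#' Default stepped-frequency sweep
#'
#' Uniform sweep over the scanner band 0.8-4.1 GHz.
#'
#' @param n number of frequency points (default 34).
#' @return frequencies in Hz.
#' @export
scan_frequencies <- function(n = 34) seq(0.8e9, 4.1e9, length.out = n)

# Two-media Green's function: exponential decay along the split ray plus
# 1/d spherical spreading (distances in mm, wavenumbers in 1/m).
two_media_green <- function(d_out, d_in, k_t, k_in) {
  exp(-(k_t * d_out + k_in * d_in) * 1e-3) / pmax(d_out + d_in, 1e-6)
}

# Out-of-breast / in-breast path split from every probe to every target of
# one coronal slice (targets projected to the slice plane; per-slice 2D
# propagation). Returns list of np x nv matrices d_out, d_in.
slice_path_split <- function(env, probes, targets) {
  np <- nrow(probes); nv <- nrow(targets)
  d_out <- d_in <- matrix(0, np, nv)
  inside <- env_inside(env, targets)
  for (p in seq_len(np)) {
    L <- sqrt((targets[, 1] - probes[p, 1])^2 +
              (targets[, 2] - probes[p, 2])^2 +
              (targets[, 3] - probes[p, 3])^2)
    tau <- rep(1, nv)
    if (any(inside))
      tau[inside] <- ray_entry_fraction(env, probes[p, ],
                                        targets[inside, , drop = FALSE])
    d_out[p, ] <- tau * L
    d_in[p, ] <- (1 - tau) * L
  }
  list(d_out = d_out, d_in = d_in)
}

# Nominal echo scale of the default geometry (single ~14 mm lesion at
# mid-depth, 120 mm ring): used to anchor the default coupling amplitude
# ~30 dB above lesion echoes.
NOMINAL_ECHO_RMS <- 2e-5

#' Default artifact configuration of the scan simulator
#'
#' @param coupling logical; inject the inter-probe coupling common mode.
#' @param coupling_amp coupling amplitude (default about 30 dB above the
#'   nominal lesion echo level).
#' @param skin logical; inject the skin-reflection term.
#' @param skin_amp skin reflection coefficient.
#' @param fold_amp relative amplitude of the skin-fold echo (used when the
#'   phantom carries a fold flag).
#' @export
artifact_config <- function(coupling = TRUE,
                            coupling_amp = NOMINAL_ECHO_RMS * 10^(30 / 20),
                            skin = TRUE, skin_amp = 0.15,
                            fold_amp = 40) {
  list(coupling = coupling, coupling_amp = coupling_amp,
       skin = skin, skin_amp = skin_amp, fold_amp = fold_amp)
}

#' Synthesize a multistatic MWBI scan
#'
#' Born-approximation forward model: every lesion voxel within the +/- 2 mm
#' slab of a scan position acts as an independent point scatterer, and the
#' bistatic channel response is the sum of two-way two-media Green's
#' functions weighted by the voxel contrast. Additive artifact terms emulate
#' inter-probe coupling (a frequency-smooth common mode identical across
#' channel pairs), the skin reflection (delay set by the envelope first
#' intersection), and optionally a localized skin-fold echo. Circular complex
#' Gaussian noise is scaled to `noise_level` times the pre-noise signal RMS.
#' Reciprocity `S21[i,j,f] = S21[j,i,f]` holds exactly before noise; the
#' monostatic diagonal is absent (NA).
#'
#' @param phantom a [make_phantom()] object.
#' @param array a [probe_array()].
#' @param freq frequency grid in Hz (default [scan_frequencies()]).
#' @param media a [medium_model()].
#' @param grid imaging lattice ([voxel_grid()]); defaults to a 64 x 64
#'   lattice on the array's scan heights.
#' @param noise_level noise RMS relative to the pre-noise signal RMS
#'   (0 disables noise; 0.1 corresponds to 20 dB SNR).
#' @param artifacts an [artifact_config()].
#' @param seed integer seed for the noise stream.
#' @return object of class `scan_data`: complex array `s21` of dimension
#'   `(n_probes, n_probes, n_freq, n_slices)` plus geometry and metadata.
#' @export
synthesize_scan <- function(phantom, array, freq = scan_frequencies(),
                            media = medium_model(), grid = NULL,
                            noise_level = 0, artifacts = artifact_config(),
                            seed = 1L) {
  if (length(freq) == 0) stop("config error: empty frequency grid")
  env <- phantom$envelope
  if (is.null(grid)) {
    zs <- array$z_positions[array$z_positions >= env$z_bottom]
    grid <- voxel_grid(64, z = zs)
  }
  np <- array$n_probes; nf <- length(freq); nz <- length(grid$z)
  k_t <- medium_wavenumber(media, "transition", freq)
  k_in <- wavenumber_inbreast(media, freq, phantom$pc_fib)
  s21 <- array(0i, c(np, np, nf, nz))

  for (iz in seq_len(nz)) {
    z <- grid$z[iz]
    probes <- probe_positions(array, z)
    sc <- slab_scatterers(phantom, grid, z)
    if (nrow(sc$points) > 0) {
      tg <- sc$points; tg[, 3] <- z            # project into the slice plane
      ps <- slice_path_split(env, probes, tg)
      for (ifr in seq_len(nf)) {
        G <- two_media_green(ps$d_out, ps$d_in, k_t[ifr], k_in[ifr])
        s21[, , ifr, iz] <- (G * rep(sc$contrast, each = np)) %*% t(G)
      }
    }
    if (isTRUE(artifacts$skin) && z >= env$z_bottom) {
      s21[, , , iz] <- s21[, , , iz] + skin_term(env, probes, freq, media,
                                                 artifacts$skin_amp)
    }
    if (!is.null(phantom$fold) && abs(z - phantom$fold$z) <= 6) {
      s21[, , , iz] <- s21[, , , iz] +
        fold_term(env, array, probes, z, freq, media, phantom$fold,
                  artifacts$fold_amp)
    }
  }
  if (isTRUE(artifacts$coupling)) {
    cp <- coupling_waveform(freq, artifacts$coupling_amp)
    s21 <- s21 + rep(cp, each = np * np)       # identical across pairs/slices
  }
  pre_noise_rms <- sqrt(mean(Mod(s21)^2))
  if (noise_level > 0 && pre_noise_rms > 0) {
    sigma <- noise_level * pre_noise_rms / sqrt(2)
    local_rng(seed, {
      s21 <- s21 + complex(real = stats::rnorm(length(s21), sd = sigma),
                           imaginary = stats::rnorm(length(s21), sd = sigma))
    })
  }
  for (p in seq_len(np)) s21[p, p, , ] <- NA_complex_   # monostatic absent
  structure(list(s21 = s21, freq = freq, z = grid$z, array = array,
                 grid = grid, media = media, noise_level = noise_level,
                 artifacts = artifacts, seed = as.integer(seed),
                 phantom_pc_fib = phantom$pc_fib),
            class = "scan_data")
}

#' @export
print.scan_data <- function(x, ...) {
  cat(sprintf("<scan_data> %d probes, %d frequencies (%.2f-%.2f GHz), %d slices\n",
              dim(x$s21)[1], length(x$freq), min(x$freq) / 1e9,
              max(x$freq) / 1e9, length(x$z)))
  invisible(x)
}

# Frequency-smooth common coupling waveform: near-zero delay, gaussian
# amplitude taper over the band.
coupling_waveform <- function(freq, amp) {
  f0 <- mean(freq); bw <- diff(range(freq))
  tau <- 0.05e-9                               # 0.05 ns residual delay
  amp * exp(-((freq - f0) / (0.8 * bw))^2) * exp(-2i * pi * freq * tau)
}

# Skin reflection: specular echo from the envelope surface point facing the
# arc midpoint of each probe pair; symmetric in (i, j) by construction.
skin_term <- function(env, probes, freq, media, skin_amp) {
  np <- nrow(probes); nf <- length(freq)
  k_t <- medium_wavenumber(media, "transition", freq)
  z <- probes[1, 3]
  # surface point at each probe's azimuth
  th <- atan2(probes[, 2], probes[, 1])
  r_s <- envelope_radius(env, th, rep(z, np))
  surf <- cbind(r_s * cos(th), r_s * sin(th), z)
  out <- array(0i, c(np, np, nf))
  d_probe_surf <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    # mid-azimuth surface point between probes i and j
    d_probe_surf[i, j] <-
      sqrt(sum((probes[i, ] - surf[j, ])^2))
  }
  for (i in seq_len(np)) for (j in i:np) {
    d <- (d_probe_surf[i, i] + d_probe_surf[j, j] +
          d_probe_surf[i, j] + d_probe_surf[j, i]) / 2
    w <- skin_amp * exp(-k_t * d * 1e-3) / pmax(d, 1)
    out[i, j, ] <- w
    out[j, i, ] <- w
  }
  out
}

# Localized skin-fold echo: strong surface scatterer at the fold azimuth,
# visible to probes within a +/- 75 degree arc (inframammary folds extend
# over a broad arc of the breast surface).
fold_term <- function(env, array, probes, z, freq, media, fold, fold_amp) {
  np <- nrow(probes); nf <- length(freq)
  k_t <- medium_wavenumber(media, "transition", freq)
  r_s <- envelope_radius(env, fold$azimuth, z)
  q <- c(r_s * cos(fold$azimuth), r_s * sin(fold$azimuth), z)
  dang <- abs(((array$azimuth - fold$azimuth + pi) %% (2 * pi)) - pi)
  vis <- dang <= 5 * pi / 12
  amp <- fold_amp * NOMINAL_ECHO_RMS * (fold$amplitude %||% 1)
  out <- array(0i, c(np, np, nf))
  d <- sqrt(colSums((t(probes) - q)^2))
  for (i in which(vis)) for (j in which(vis)) {
    w <- amp * exp(-k_t * (d[i] + d[j]) * 1e-3)
    out[i, j, ] <- w
  }
  out
}

#' Empty-container calibration scan
#'
#' Simulates the scan of the empty container (no breast): coupling plus
#' noise only. Its median channel energy anchors the PSD normalization used
#' by the amplitude filter.
#'
#' @inheritParams synthesize_scan
#' @param n_slices number of scan heights to simulate.
#' @export
calibration_scan <- function(array, freq = scan_frequencies(),
                             media = medium_model(),
                             artifacts = artifact_config(),
                             noise_level = 0.01, n_slices = 1, seed = 99L) {
  np <- array$n_probes; nf <- length(freq)
  s21 <- array(0i, c(np, np, nf, n_slices))
  if (isTRUE(artifacts$coupling)) {
    cp <- coupling_waveform(freq, artifacts$coupling_amp)
    s21 <- s21 + rep(cp, each = np * np)
  }
  rms <- sqrt(mean(Mod(s21)^2))
  if (noise_level > 0 && rms > 0) {
    sigma <- noise_level * rms / sqrt(2)
    local_rng(seed, {
      s21 <- s21 + complex(real = stats::rnorm(length(s21), sd = sigma),
                           imaginary = stats::rnorm(length(s21), sd = sigma))
    })
  }
  for (p in seq_len(np)) s21[p, p, , ] <- NA_complex_
  structure(list(s21 = s21, freq = freq,
                 z = array$z_positions[seq_len(n_slices)], array = array,
                 media = media, noise_level = noise_level,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "scan_data")
}
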