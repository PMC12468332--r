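#' Convert a channel spectrum to the time domain
#'
#' Inverse DFT of the measured one-sided S21 spectrum. Since the measured
#' spectrum has no negative-frequency content, the time signal is the complex
#' analytic signal directly. The spectrum is zero-padded (default 4x) for
#' time-axis oversampling, and the time axis is annotated with one-way radar
#' distance through the transition liquid.
#'
#' @param spectrum complex S21 samples on a uniform frequency grid.
#' @param freq frequency grid in Hz (uniform, >= 4 points).
#' @param pad zero-padding factor.
#' @param media a [medium_model()] used for the distance annotation.
#' @return object of class `time_channel`: `signal` (complex analytic),
#'   `t` (s), `dist` (one-way mm), `freq`, `pad`.
#' @export
to_time_domain <- function(spectrum, freq, pad = 4, media = medium_model(),
                           taper = 0.25) {
  n <- length(freq)
  if (n < 4) stop("resolution error: need at least 4 frequency points")
  df <- freq[2] - freq[1]
  npad <- n * pad
  w <- tukey_window(n, taper)
  spad <- c(spectrum * w, rep(0i, npad - n))
  sig <- stats::fft(spad, inverse = TRUE) / npad
  t <- (seq_len(npad) - 1) / (npad * df)
  er <- medium_eval(media, "transition", mean(freq))$er
  v <- SPEED_OF_LIGHT / sqrt(er)               # phase velocity, m/s
  structure(list(signal = sig, t = t, dist = t * v / 2 * 1e3,
                 freq = freq, pad = pad, window = w),
            class = "time_channel")
}

# Tukey (tapered cosine) window; suppresses the range sidelobes of strong
# early echoes so that distance gating is effective.
tukey_window <- function(n, taper = 0.5) {
  if (taper <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < taper / 2
  hi <- x > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / taper - 1)))
  w
}

#' Recover the channel spectrum from a time channel
#'
#' Exact inverse of [to_time_domain()] (forward DFT, first `n` bins).
#'
#' @param tc a `time_channel` (or a complex signal vector).
#' @param n number of frequency bins to return.
#' @param window spectral taper applied on the way in (divided back out,
#'   floored at 5 percent of its maximum).
#' @export
to_freq_domain <- function(tc, n = length(tc$freq), window = NULL) {
  sig <- if (inherits(tc, "time_channel")) tc$signal else tc
  if (is.null(window) && inherits(tc, "time_channel")) window <- tc$window
  sp <- stats::fft(sig)[seq_len(n)]
  if (!is.null(window)) sp <- sp / pmax(window, 0.05)
  sp
}

# Analytic signal of a real vector (one-sided spectrum via FFT).
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Remove the common coupling component across a channel group by PCA
#'
#' Stacks the channels of one sub-array context as rows, computes the SVD,
#' and subtracts the leading principal component(s) -- the strong common
#' mode dominated by inter-probe coupling and the (rotationally slowly
#' varying) skin reflection -- from every channel. When `groups` is given,
#' the subtraction is applied within each channel ensemble separately:
#' grouping the bistatic channels by Tx-Rx probe separation makes the
#' common mode of each ensemble capture the separation-dependent surface
#' bounce as well (rotation subtraction), while lesion echoes, whose delays
#' vary quickly from channel to channel, survive.
#'
#' @param x complex matrix, channels x time samples.
#' @param n_comp number of leading components to remove per ensemble
#'   (default 1).
#' @param groups optional grouping vector (length `nrow(x)`); ensembles
#'   with fewer than 2 channels are left untouched.
#' @return cleaned matrix of the same dimension, with attribute
#'   `"projector"`: a function applying the fitted removal operator to any
#'   conformable matrix (used to account for how much of a known injected
#'   component the removal captured).
#' @export
pca_coupling_removal <- function(x, n_comp = 1, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, nrow(x))
  if (nrow(x) <= n_comp)
    stop("config error: fewer channels than components to remove")
  out <- x
  basis <- list()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) <= n_comp) next
    xg <- x[rows, , drop = FALSE]
    sv <- La.svd(xg, nu = n_comp, nv = 0)
    u <- sv$u[, seq_len(n_comp), drop = FALSE]
    out[rows, ] <- xg - u %*% (Conj(t(u)) %*% xg)
    basis[[as.character(g)]] <- list(rows = rows, u = u)
  }
  attr(out, "projector") <- function(m) {
    res <- m
    for (b in basis)
      res[b$rows, ] <- m[b$rows, , drop = FALSE] -
        b$u %*% (Conj(t(b$u)) %*% m[b$rows, , drop = FALSE])
    res
  }
  out
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a real signal into intrinsic mode functions (IMFs) by the
#' classical sifting procedure: cubic-spline envelopes through local maxima
#' and minima (mirrored boundary extrema), mean-envelope subtraction, a
#' standard-deviation stop criterion per IMF, and extraction until the
#' residual is monotone or `max_imf` is reached. Completeness (sum of IMFs
#' plus residual equals the input) holds to machine precision by
#' construction.
#'
#' @param x real numeric signal (length >= 16).
#' @param max_imf maximal number of IMFs (default 10).
#' @param sd_thresh sifting stop threshold (default 0.2).
#' @param max_sift maximal sifting iterations per IMF (default 10).
#' @return object of class `imf_set`: `imfs` (list of numeric vectors),
#'   `residual`, `input`.
#' @export
emd_decompose <- function(x, max_imf = 10, sd_thresh = 0.2, max_sift = 10) {
  if (length(x) < 16) stop("signal too short for EMD (need >= 16 samples)")
  if (!all(is.finite(x))) stop("signal must be finite")
  imfs <- list()
  resid <- x
  for (k in seq_len(max_imf)) {
    ext <- find_extrema(resid)
    if (length(ext$max) < 2 || length(ext$min) < 2) break   # monotone residual
    h <- resid
    for (s in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h1 <- h - env
      sd_k <- sum((h - h1)^2) / max(sum(h^2), 1e-300)
      h <- h1
      if (sd_k < sd_thresh) break
    }
    imfs[[k]] <- h
    resid <- resid - h
  }
  structure(list(imfs = imfs, residual = resid, input = x),
            class = "imf_set")
}

find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse plateaus
  idx <- which(s[-1] * s[-(n - 1)] < 0) + 1L
  list(max = idx[x[idx] > x[idx - 1L]], min = idx[x[idx] < x[idx - 1L]])
}

# Mean of upper/lower cubic-spline envelopes; NULL when too few extrema.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  mx <- ext$max; mn <- ext$min
  if (length(mx) < 2 || length(mn) < 2) return(NULL)
  spline_env <- function(idx) {
    # mirror two boundary extrema on each side for end behaviour
    i <- c(2 - rev(idx[seq_len(min(2, length(idx)))]), idx,
           2 * n - rev(idx[seq(max(1, length(idx) - 1), length(idx))]))
    v <- c(rev(x[idx[seq_len(min(2, length(idx)))]]), x[idx],
           rev(x[idx[seq(max(1, length(idx) - 1), length(idx))]]))
    keep <- !duplicated(i)
    stats::splinefun(i[keep], v[keep], method = "fmm")(seq_len(n))
  }
  (spline_env(mx) + spline_env(mn)) / 2
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, n = %d\n",
              length(x$imfs), length(x$input)))
  invisible(x)
}

#' Annotate and flag IMFs by dominant echo distance
#'
#' Each IMF's dominant echo distance is the one-way distance annotation at
#' the arg-max of its analytic envelope. IMFs peaking in the probes'
#' immediate vicinity are flagged as residual antenna coupling; IMFs peaking
#' at unrealistically long distances are flagged as multipath; the rest are
#' kept.
#'
#' @param imfset an [emd_decompose()] result.
#' @param dist one-way distance annotation of the time axis, mm.
#' @param d_near coupling cutoff in mm (default 10).
#' @param d_far multipath cutoff in mm; default `ring diameter + 2 * max
#'   chord` when `array` and `envelope` are given.
#' @param d_skin out-of-breast cutoff in mm (channel's probe-to-envelope
#'   distance plus a margin): IMFs peaking between the probe vicinity and
#'   the breast border are dominated by skin/surface reflections and
#'   dropped. `NULL` disables the rule.
#' @param array,envelope optional geometry used for the `d_far` default.
#' @return data frame with one row per IMF: `distance`, `keep`, `reason`.
#' @export
classify_imfs <- function(imfset, dist, d_near = 10, d_far = NULL,
                          d_skin = NULL, array = NULL, envelope = NULL) {
  if (is.null(d_far)) {
    d_far <- if (!is.null(array) && !is.null(envelope))
      2 * array$ring_radius + 4 * max(envelope$rho)
    else 0.9 * max(dist)
  }
  k <- length(imfset$imfs)
  if (k == 0)
    return(data.frame(distance = numeric(0), keep = logical(0),
                      reason = character(0)))
  distance <- vapply(imfset$imfs, function(h) {
    dist[which.max(Mod(hilbert_analytic(h)))]
  }, numeric(1))
  reason <- ifelse(distance < d_near, "coupling",
                   ifelse(distance > d_far, "multipath",
                          ifelse(!is.null(d_skin) & distance < (d_skin %||% 0),
                                 "skin", "kept")))
  data.frame(distance = distance, keep = reason == "kept", reason = reason)
}

#' Propagation loss compensation multiplier
#'
#' Frequency-domain multiplicative compensation of the two-media propagation
#' loss: `exp(alpha_trans(f) * d_out + alpha_in(f) * d_in)` with the
#' in-breast attenuation the `pc_fib`-weighted fibroglandular/adipose
#' mixture. The multiplier is >= 1 and non-decreasing in each distance, in
#' `pc_fib`, and in frequency.
#'
#' @param freq frequencies in Hz.
#' @param d_out,d_in out-of-breast / in-breast path lengths in mm (>= 0);
#'   pass round-trip totals to compensate a two-way echo.
#' @param pc_fib fibroglandular fraction in `[0, 1]`.
#' @param media a [medium_model()].
#' @return numeric multiplier per frequency.
#' @export
loss_multiplier <- function(freq, d_out, d_in, pc_fib, media = medium_model()) {
  if (d_out < 0 || d_in < 0) stop("distances must be nonnegative")
  a_t <- Re(medium_wavenumber(media, "transition", freq))
  a_in <- alpha_inbreast(media, freq, pc_fib)
  exp((a_t * d_out + a_in * d_in) * 1e-3)
}

#' Compensate a spectrum for propagation loss
#'
#' @param spectrum complex spectrum of one IMF / channel.
#' @inheritParams loss_multiplier
#' @export
loss_compensate <- function(spectrum, freq, d_out, d_in, pc_fib,
                            media = medium_model()) {
  spectrum * loss_multiplier(freq, d_out, d_in, pc_fib, media)
}

# Time-localized loss + spreading compensation of a channel signal: each
# sample is scaled so that the envelope peak of an echo at the sample's
# annotated distance is restored to the level of an echo at the breast
# surface. Over a wide band the attenuation disperses strongly (deep
# echoes red-shift), so the gain inverts the band-integrated peak decay:
# for a smooth nonnegative model spectrum the IDFT envelope peak equals
# the spectral mean, giving the closed form
# `g(d) = mean_f W(f) exp(-2(a_t(f) d_out + a_in(f) d_in)) / d_phys^2`.
# The annotation maps delay to distance at the transition-liquid velocity,
# so the in-breast leg is rescaled to physical length by the velocity
# ratio. Unlike a single per-IMF multiplier, the per-sample gain equalizes
# several echoes of different depths sharing one IMF.
compensate_signal <- function(signal, dist, d_surf, pc_fib, media, freq,
                              window = NULL, spreading = TRUE) {
  if (is.null(window)) window <- rep(1, length(freq))
  a_t <- Re(medium_wavenumber(media, "transition", freq))
  a_in <- alpha_inbreast(media, freq, pc_fib)
  f_c <- mean(freq)
  er_t <- medium_eval(media, "transition", f_c)$er
  fib <- medium_eval(media, "fibroglandular", f_c)$er
  adi <- medium_eval(media, "adipose", f_c)$er
  er_in <- pc_fib * fib + (1 - pc_fib) * adi
  stretch <- sqrt(er_t / er_in)            # annotated -> physical in-breast
  d_in1 <- pmax(0, dist - d_surf) * stretch
  d_out1 <- pmin(dist, d_surf)
  decay <- vapply(seq_along(dist), function(k) {
    mean(window * exp(-2 * (a_t * d_out1[k] + a_in * d_in1[k]) * 1e-3))
  }, numeric(1))
  ref <- mean(window * exp(-2 * a_t * d_surf * 1e-3))
  gain <- ref / decay
  if (spreading) gain <- gain * pmax(d_out1 + d_in1, 1)^2 / max(d_surf, 1)^2
  signal * gain
}

#' Integrated-PSD amplitude filter
#'
#' The power spectral density integrated over the full signal equals the
#' channel energy (Parseval); normalized by the median channel energy of the
#' empty-container calibration scan it is expected to stay below
#' `psd_thresh` at nominal system behaviour. Channels at or above the
#' threshold are dropped, except under the CUSTOM1 mode, which disables the
#' amplitude filter.
#'
#' @param signal complex channel signal (time domain).
#' @param calib_ref calibration reference energy (median empty-container
#'   channel energy).
#' @param mode an [imaging_mode()].
#' @return list `keep` (logical) and `psd_tot` (numeric).
#' @export
psd_filter <- function(signal, calib_ref, mode = imaging_mode("DEFAULT")) {
  psd_tot <- sum(Mod(signal)^2) / calib_ref
  keep <- if (!mode$psd_enabled) TRUE else psd_tot < mode$psd_thresh
  list(keep = keep, psd_tot = psd_tot)
}

#' Calibration reference energy
#'
#' Median channel energy (time domain) of an empty-container calibration
#' scan.
#'
#' @param calib a [calibration_scan()] result.
#' @param pad zero-padding factor matching the analysis settings.
#' @export
calibration_reference <- function(calib, pad = 4) {
  np <- dim(calib$s21)[1]
  en <- c()
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    tc <- to_time_domain(calib$s21[i, j, , 1], calib$freq, pad = pad,
                         media = calib$media)
    en <- c(en, sum(Mod(tc$signal)^2))
  }
  stats::median(en)
}

#' Operating mode of the preprocessing scheme
#'
#' Three modes: DEFAULT (`N_PCA = N_S + 4 = 12` probes, amplitude filter
#' on), CUSTOM1 (amplitude filter disabled, for very small breasts or large
#' superficial lesions), CUSTOM2 (`N_PCA = N_S + 2 = 10` probes for more
#' severe common-mode filtering, for very large breasts, skin folds, or
#' extreme density). `N_S = 8` probes per imaging sector always.
#'
#' @param name one of "DEFAULT", "CUSTOM1", "CUSTOM2".
#' @param psd_thresh integrated-PSD threshold (default 5).
#' @return object of class `imaging_mode`.
#' @export
imaging_mode <- function(name = c("DEFAULT", "CUSTOM1", "CUSTOM2"),
                         psd_thresh = 5) {
  name <- match.arg(name)
  structure(list(
    name = name,
    n_s = 8L,
    n_pca = if (name == "CUSTOM2") 10L else 12L,
    psd_enabled = name != "CUSTOM1",
    psd_thresh = psd_thresh
  ), class = "imaging_mode")
}

#' @export
print.imaging_mode <- function(x, ...) {
  cat(sprintf("<imaging_mode> %s: N_S = %d, N_PCA = %d, amplitude filter %s\n",
              x$name, x$n_s, x$n_pca,
              if (x$psd_enabled) sprintf("on (threshold %g)", x$psd_thresh)
              else "off"))
  invisible(x)
}

#' Rule-based mode attribution for a breast scan
#'
#' CUSTOM1 for very small breasts or a large superficial lesion; CUSTOM2 for
#' very large breasts, skin folds, or extreme-density breasts; DEFAULT
#' otherwise. Thresholds are configurable; the triggering rule is recorded.
#'
#' @param volume_ml breast volume in mL.
#' @param lesion_size_mm,lesion_depth_mm optional lesion hints (mm).
#' @param fold logical skin-fold flag.
#' @param extreme_density logical density flag.
#' @param v_small,v_large volume thresholds in mL.
#' @param large_lesion_mm,superficial_mm lesion-hint thresholds in mm.
#' @return an [imaging_mode()] with attribute `"rule"`.
#' @export
select_mode <- function(volume_ml, lesion_size_mm = NA, lesion_depth_mm = NA,
                        fold = FALSE, extreme_density = FALSE,
                        v_small = 350, v_large = 1300,
                        large_lesion_mm = 20, superficial_mm = 15) {
  rule <- "default"
  name <- "DEFAULT"
  if (isTRUE(fold)) { name <- "CUSTOM2"; rule <- "skin fold" }
  else if (isTRUE(extreme_density)) { name <- "CUSTOM2"; rule <- "extreme density" }
  else if (is.finite(volume_ml) && volume_ml > v_large) {
    name <- "CUSTOM2"; rule <- "very large breast"
  } else if (is.finite(volume_ml) && volume_ml < v_small) {
    name <- "CUSTOM1"; rule <- "very small breast"
  } else if (is.finite(lesion_size_mm) && is.finite(lesion_depth_mm) &&
             lesion_size_mm >= large_lesion_mm &&
             lesion_depth_mm <= superficial_mm) {
    name <- "CUSTOM1"; rule <- "large superficial lesion"
  }
  m <- imaging_mode(name)
  attr(m, "rule") <- rule
  m
}

#' Breast volume from the envelope
#'
#' @param env a [breast_envelope()].
#' @return volume in mL.
#' @export
envelope_volume <- function(env) {
  z <- seq(env$z_bottom, env$z_top, length.out = 121)
  a <- envelope_area(env, z)
  sum((a[-1] + a[-length(a)]) / 2 * diff(z)) / 1000   # mm^3 -> mL
}

# --- sector-level preprocessing -------------------------------------------

# Preprocess the channels of one sub-array context of one slice:
# time-domain conversion, PCA common-mode removal over the extended N_PCA
# probe group, EMD + distance filtering and PSD filtering per central-sector
# channel. Loss compensation is deferred to sector_spectra() because it
# depends on the pc_fib assumption. Returns filtered (uncompensated)
# channel signals plus the per-channel filter log.
preprocess_sector <- function(scan, iz, center, mode, envelope,
                              media = scan$media, calib_ref = NULL,
                              pad = 4, d_near = 10, d_far = NULL,
                              n_pca_comp = 1) {
  array <- scan$array
  np <- array$n_probes
  sub <- form_subarray(array, center)                 # 8 central probes
  grp <- sort(form_group(center, mode$n_pca, np))     # extended PCA context
  pairs_grp <- t(utils::combn(grp, 2))                # rows are (min, max)
  # time-domain conversion of the group channels
  first <- to_time_domain(scan$s21[pairs_grp[1, 1], pairs_grp[1, 2], , iz],
                          scan$freq, pad = pad, media = media)
  nt <- length(first$signal)
  X <- matrix(0i, nrow(pairs_grp), nt)
  X[1, ] <- first$signal
  for (r in 2:nrow(pairs_grp))
    X[r, ] <- to_time_domain(scan$s21[pairs_grp[r, 1], pairs_grp[r, 2], , iz],
                             scan$freq, pad = pad, media = media)$signal
  sep <- abs(pairs_grp[, 1] - pairs_grp[, 2])
  sep <- pmin(sep, np - sep)                 # ring separation class
  Xc <- pca_coupling_removal(X, n_comp = n_pca_comp, groups = sep)
  # central 8-probe sector pairs
  pairs <- t(utils::combn(sub, 2))
  row_of <- function(i, j) which(pairs_grp[, 1] == min(i, j) &
                                 pairs_grp[, 2] == max(i, j))
  probes <- probe_positions(array, scan$z[iz])
  d_surf <- surface_distance(envelope, probes)
  if (is.null(d_far)) d_far <- 2 * array$ring_radius + 4 * max(envelope$rho)
  sig <- matrix(0i, nrow(pairs), nt)
  log <- vector("list", nrow(pairs))
  # the IDFT wrap region (negative-delay tails of the coupling) is always
  # excluded; in-band artifact content is handled by the grouped PCA and
  # the IMF distance filter, not by hard gating, which would act as a
  # channel-dependent spectral convolution and blunt the subspace nulls
  gate_cut <- first$dist > min(d_far, 0.95 * max(first$dist))
  for (r in seq_len(nrow(pairs))) {
    x <- Xc[row_of(pairs[r, 1], pairs[r, 2]), ]
    x[gate_cut] <- 0i
    dec <- emd_decompose(Re(x))
    cls <- classify_imfs(dec, first$dist, d_near = d_near, d_far = d_far,
                         array = array, envelope = envelope)
    keep <- which(cls$keep)
    xr <- if (length(keep)) Reduce(`+`, dec$imfs[keep]) else numeric(nt)
    # the residual is classified like an IMF: short gated packets can carry
    # few oscillations, leaving most echo energy in the residual
    if (any(dec$residual != 0)) {
      rp <- first$dist[which.max(Mod(hilbert_analytic(dec$residual)))]
      if (rp >= d_near && rp <= d_far) xr <- xr + dec$residual
    }
    xa <- hilbert_analytic(xr)
    xa[gate_cut] <- 0i
    psd <- if (!is.null(calib_ref)) psd_filter(xa, calib_ref, mode)
           else list(keep = TRUE, psd_tot = NA_real_)
    if (!psd$keep) xa <- rep(0i, nt)
    sig[r, ] <- xa
    log[[r]] <- data.frame(tx = pairs[r, 1], rx = pairs[r, 2],
                           imf = seq_len(max(1, nrow(cls))),
                           distance = if (nrow(cls)) cls$distance else NA,
                           reason = if (nrow(cls)) cls$reason else "empty",
                           psd_tot = psd$psd_tot, channel_kept = psd$keep)
  }
  list(sub = sub, pairs = pairs, signals = sig, dist = first$dist,
       d_surf = d_surf, freq = scan$freq, f_centre = mean(scan$freq),
       window = first$window, z = scan$z[iz], log = do.call(rbind, log))
}

# Contiguous probe group of size n, same centring convention as the
# 8-probe sub-array: floor((n-1)/2) probes left of the centre, rest right.
form_group <- function(center, n, np = 21L) {
  offs <- seq.int(-floor((n - 1) / 2), length.out = n)
  ((center - 1L + offs) %% np) + 1L
}

# One-way annotated distance of the specular surface bounce per probe pair
# (same geometry as the simulator's skin term: probe -> mid-azimuth surface
# point -> probe, halved for the one-way annotation).
skin_path_oneway <- function(env, probes) {
  np <- nrow(probes)
  z <- probes[1, 3]
  th <- atan2(probes[, 2], probes[, 1])
  if (z < env$z_bottom || z > env$z_top)
    return(matrix(sqrt(probes[1, 1]^2 + probes[1, 2]^2), np, np))
  r_s <- envelope_radius(env, th, rep(z, np))
  surf <- cbind(r_s * cos(th), r_s * sin(th), z)
  dps <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    dps[i, j] <- sqrt(sum((probes[i, ] - surf[j, ])^2))
  out <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    out[i, j] <- (dps[i, i] + dps[j, j] + dps[i, j] + dps[j, i]) / 4
  out
}

# Average probe-to-envelope surface distance per probe (first intersection
# toward the axis) at the probes' scan height.
surface_distance <- function(env, probes) {
  th <- atan2(probes[, 2], probes[, 1])
  z <- probes[1, 3]
  if (z < env$z_bottom || z > env$z_top)
    return(rep(sqrt(probes[1, 1]^2 + probes[1, 2]^2), nrow(probes)))
  r_s <- envelope_radius(env, th, rep(z, nrow(probes)))
  sqrt(probes[, 1]^2 + probes[, 2]^2) - r_s
}

# 8x8 multistatic spectra of one preprocessed sector, loss-compensated
# under a pc_fib assumption (`pc_fib = NULL` skips compensation, leaving
# the natural dissipative decay in the data); monostatic diagonal left
# zero (absent).
sector_spectra <- function(prep, pc_fib, media) {
  ns <- length(prep$sub)
  nf <- length(prep$freq)
  M <- array(0i, c(ns, ns, nf))
  ds <- max(mean(prep$d_surf[prep$sub]), 1)  # sector-common split reference
  for (r in seq_len(nrow(prep$pairs))) {
    i <- match(prep$pairs[r, 1], prep$sub)
    j <- match(prep$pairs[r, 2], prep$sub)
    xc <- if (is.null(pc_fib)) prep$signals[r, ]
          else compensate_signal(prep$signals[r, ], prep$dist, ds,
                                 pc_fib, media, prep$freq, prep$window)
    # the spectral taper is left in place: it scales every channel of a
    # frequency identically and the pseudospectrum is scale-invariant
    sp <- to_freq_domain(xc, n = nf)
    M[i, j, ] <- sp
    M[j, i, ] <- sp
  }
  M
}
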