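test_that("time-domain conversion is an exact Fourier pair", {
  freq <- scan_frequencies(34)
  # flat unit spectrum -> impulse at zero delay
  tc0 <- to_time_domain(rep(1 + 0i, 34), freq, taper = 0)
  expect_equal(which.max(Mod(tc0$signal)), 1L)
  # linear-phase spectrum -> envelope peak at 2 ns within one bin
  tau <- 2e-9
  tc <- to_time_domain(exp(-2i * pi * freq * tau), freq, taper = 0)
  expect_lt(abs(tc$t[which.max(Mod(tc$signal))] - tau), tc$t[2] - tc$t[1])
  # round trip reproduces the spectrum to 1e-10
  sp <- complex(real = rnorm(34), imaginary = rnorm(34))
  tc2 <- to_time_domain(sp, freq, taper = 0)
  expect_lt(max(Mod(to_freq_domain(tc2) - sp)), 1e-10 * max(Mod(sp)))
  expect_error(to_time_domain(rep(1 + 0i, 3), freq[1:3]), "resolution")
})

test_that("EMD is complete and separates tones", {
  # constant signal: no extrema, residual carries everything
  d0 <- emd_decompose(rep(3, 32))
  expect_equal(length(d0$imfs), 0L)
  expect_equal(d0$residual, rep(3, 32))
  # completeness on random band-limited signals
  set.seed(11)
  for (k in 1:20) {
    x <- as.numeric(stats::filter(rnorm(128), rep(1, 4), sides = 2))
    x[is.na(x)] <- 0
    d <- emd_decompose(x)
    rec <- Reduce(`+`, c(d$imfs, list(d$residual)))
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-10)
  }
  # a pure tone lands in the first IMF almost unchanged
  t <- seq(0, 1, length.out = 256)
  x <- sin(2 * pi * 20 * t)
  d1 <- emd_decompose(x)
  expect_gt(cor(d1$imfs[[1]], x), 0.99)
  # 50 + 400 MHz mixture: two dominant IMFs recover both tones
  t2 <- seq(0, 2e-7, length.out = 512)
  x2 <- sin(2 * pi * 4e8 * t2) + sin(2 * pi * 5e7 * t2)
  d2 <- emd_decompose(x2)
  fgrid <- (0:255) / (512 * (t2[2] - t2[1]))
  peaks <- vapply(d2$imfs[1:2], function(h) {
    fgrid[which.max(Mod(stats::fft(h))[1:256])]
  }, numeric(1))
  df <- fgrid[2] - fgrid[1]
  expect_lt(abs(peaks[1] - 4e8), df + 1e-6)
  expect_lt(abs(peaks[2] - 5e7), df + 1e-6)
})

test_that("IMFs are flagged by dominant echo distance", {
  freq <- scan_frequencies(16)
  tc <- to_time_domain(rep(1 + 0i, 16), freq, taper = 0)
  nt <- length(tc$signal)
  mk_packet <- function(d0) {
    env <- exp(-((tc$dist - d0) / 6)^2)
    env * cos(2 * pi * seq_len(nt) / 6)
  }
  imfset <- structure(list(imfs = list(mk_packet(2), mk_packet(60),
                                       mk_packet(120)),
                           residual = numeric(nt), input = numeric(nt)),
                      class = "imf_set")
  cls <- classify_imfs(imfset, tc$dist, d_near = 10, d_far = 100)
  expect_equal(cls$reason, c("coupling", "kept", "multipath"))
  expect_equal(cls$keep, c(FALSE, TRUE, FALSE))
})

test_that("loss multiplier follows the weighted-attenuation form", {
  m <- medium_model()
  freq <- scan_frequencies(12)
  expect_equal(loss_multiplier(freq, 0, 0, 0.5, m), rep(1, 12))
  # mixture endpoints
  a_adip <- Re(mwbim:::medium_wavenumber(m, "adipose", freq))
  a_fib <- Re(mwbim:::medium_wavenumber(m, "fibroglandular", freq))
  expect_equal(loss_multiplier(freq, 0, 30, 0, m), exp(a_adip * 0.03))
  expect_equal(loss_multiplier(freq, 0, 30, 1, m), exp(a_fib * 0.03))
  # >= 1 and monotone in distance, pc_fib and frequency
  lm1 <- loss_multiplier(freq, 10, 20, 0.3, m)
  lm2 <- loss_multiplier(freq, 10, 30, 0.3, m)
  lm3 <- loss_multiplier(freq, 10, 30, 0.6, m)
  expect_true(all(lm1 >= 1))
  expect_true(all(lm2 >= lm1) && all(lm3 >= lm2))
  expect_true(all(diff(lm3) > 0))
  expect_error(loss_multiplier(freq, -1, 5, 0.3, m), "nonnegative")
})

test_that("amplitude filter respects the threshold and the CUSTOM1 bypass", {
  ref <- 2
  mk <- function(psd_tot) {
    # complex signal of energy psd_tot * ref
    z <- complex(real = rnorm(64), imaginary = rnorm(64))
    z * sqrt(psd_tot * ref / sum(Mod(z)^2))
  }
  set.seed(1)
  expect_true(psd_filter(mk(4.9), ref, imaging_mode("DEFAULT"))$keep)
  expect_false(psd_filter(mk(7), ref, imaging_mode("DEFAULT"))$keep)
  expect_true(psd_filter(mk(7), ref, imaging_mode("CUSTOM1"))$keep)
})

test_that("modes carry the published PCA contexts and filter flags", {
  expect_equal(imaging_mode("DEFAULT")$n_pca, 12L)
  expect_equal(imaging_mode("CUSTOM1")$n_pca, 12L)
  expect_equal(imaging_mode("CUSTOM2")$n_pca, 10L)
  expect_false(imaging_mode("CUSTOM1")$psd_enabled)
  expect_true(imaging_mode("DEFAULT")$psd_enabled)
  expect_equal(imaging_mode("DEFAULT")$n_s, 8L)
  expect_equal(imaging_mode("DEFAULT")$psd_thresh, 5)
})

test_that("mode attribution follows the breast-configuration rules", {
  expect_equal(select_mode(200)$name, "CUSTOM1")
  expect_equal(select_mode(1500, fold = TRUE)$name, "CUSTOM2")
  expect_equal(select_mode(750)$name, "DEFAULT")
  expect_equal(select_mode(800, fold = TRUE)$name, "CUSTOM2")
  expect_equal(select_mode(800, extreme_density = TRUE)$name, "CUSTOM2")
  expect_equal(select_mode(700, lesion_size_mm = 25,
                           lesion_depth_mm = 10)$name, "CUSTOM1")
  expect_equal(attr(select_mode(200), "rule"), "very small breast")
})

test_that("PCA removes a pure common mode and is nearly idempotent", {
  set.seed(8)
  t <- seq(0, 1, length.out = 128)
  common <- complex(real = sin(2 * pi * 5 * t), imaginary = cos(2 * pi * 5 * t))
  X <- t(sapply(1:20, function(i) common))
  Xc <- pca_coupling_removal(X, 1)
  expect_lt(max(Mod(Xc)), 1e-10 * max(Mod(X)))
  # idempotency within tolerance: a second application removes less than
  # 1 percent of the original channel energy
  X2 <- X * 30 + t(sapply(1:20, function(i)
    complex(real = rnorm(128), imaginary = rnorm(128))))
  X2c <- pca_coupling_removal(X2, 1)
  X2cc <- pca_coupling_removal(X2c, 1)
  extra <- sum(Mod(X2c - X2cc)^2) / sum(Mod(X2)^2)
  expect_lt(extra, 0.01)
  expect_error(pca_coupling_removal(X[1, , drop = FALSE], 1), "config error")
})

test_that("narrower PCA context filters a localized fold more aggressively", {
  # fold artifact confined to an arc, on top of the global coupling: the
  # 10-probe ensemble leaves less fold energy in the central sector pairs
  # than the 12-probe default (injected-artifact energy accounting)
  array <- default_array()
  freq <- scan_frequencies(12)
  media <- medium_model()
  env <- pendulous_envelope(55, 75)
  grid <- voxel_grid(48, z = array$z_positions)
  art <- artifact_config(skin = FALSE)
  ph_f <- make_phantom(list(envelope = env, pc_fib = 0.35, lesions = list(),
                            fold = list(azimuth = 0.2, z = -38,
                                        amplitude = 4)), seed = 4)
  ph_0 <- make_phantom(list(envelope = env, pc_fib = 0.35,
                            lesions = list()), seed = 4)
  s_f <- synthesize_scan(ph_f, array, freq, media, grid = grid,
                         noise_level = 0, artifacts = art)
  s_0 <- synthesize_scan(ph_0, array, freq, media, grid = grid,
                         noise_level = 0, artifacts = art)
  iz <- which(s_f$z == -38)
  residual <- sapply(c(12L, 10L), function(npca) {
    grp <- sort(mwbim:::form_group(1, npca, 21))
    pg <- t(utils::combn(grp, 2))
    tc_of <- function(scan, r)
      to_time_domain(scan$s21[pg[r, 1], pg[r, 2], , iz], freq,
                     taper = 0.25, media = media)$signal
    X <- t(sapply(seq_len(nrow(pg)), function(r) tc_of(s_f, r)))
    Ffold <- X - t(sapply(seq_len(nrow(pg)), function(r) tc_of(s_0, r)))
    Xc <- pca_coupling_removal(X, 2)
    P <- attr(Xc, "projector")
    sub <- form_subarray(array, 1)
    keep <- pg[, 1] %in% sub & pg[, 2] %in% sub
    sum(Mod(P(Ffold)[keep, ])^2)
  })
  expect_lt(residual[2], residual[1])
})

test_that("sector preprocessing is deterministic", {
  fx <- point_target_scan(noise_level = 0.1, seed = 3, n_freq = 12)
  iz <- which(fx$scan$z == -38)
  p1 <- mwbim:::preprocess_sector(fx$scan, iz, 4, imaging_mode("DEFAULT"),
                                  fx$phantom$envelope, medium_model())
  p2 <- mwbim:::preprocess_sector(fx$scan, iz, 4, imaging_mode("DEFAULT"),
                                  fx$phantom$envelope, medium_model())
  expect_identical(p1$signals, p2$signals)
})
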