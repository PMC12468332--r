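test_that("sub-array formation walks the ring with wrap-around", {
  a <- default_array()
  # centre probe 1 (first on the ring): 3 left of centre, 4 right
  expect_equal(form_subarray(a, 1), c(19L, 20L, 21L, 1L, 2L, 3L, 4L, 5L))
  # union over all centres covers every probe
  expect_setequal(unique(unlist(lapply(1:21, form_subarray, array = a))), 1:21)
  # adjacent centres share exactly 7 probes
  expect_equal(length(intersect(form_subarray(a, 7), form_subarray(a, 8))), 7L)
  expect_error(form_subarray(a, 25), "out of range")
})

test_that("the 11 published search ranges and composites are wired exactly", {
  r <- pcfib_ranges()
  expect_length(r, 11)
  expect_true(all(vapply(r, function(x) x[1] < x[2], logical(1))))
  lo <- Filter(function(x) x[2] <= 50, r)
  hi <- Filter(function(x) x[1] >= 50, r)
  expect_length(lo, 4)
  expect_length(hi, 4)
  # composite arithmetic
  grid <- voxel_grid(8, z = c(-30))
  mask <- array(TRUE, c(8, 8, 1))
  mk <- function(val) structure(list(data = array(val, c(8, 8, 1)),
                                     grid = grid, mask = mask,
                                     cutout = NA_integer_, excluded = FALSE,
                                     provenance = "x"),
                                class = "volume_image")
  vols <- lapply(1:11, mk)
  comp <- composite_images(vols)
  expect_equal(comp$GLOBAL$data[1], mean(1:11))
  expect_equal(comp$LOW$data[1], mean(which(vapply(r, function(x) x[2] <= 50,
                                                   logical(1)))))
  expect_equal(comp$HIGH$data[1], mean(which(vapply(r, function(x) x[1] >= 50,
                                                    logical(1)))))
  # identical inputs -> identical composites
  same <- composite_images(lapply(1:11, function(i) mk(2)))
  expect_equal(same$GLOBAL$data, same$LOW$data)
  expect_error(composite_images(vols[1:5]), "config error")
})

test_that("TR-MUSIC nulls the steering vector at a point scatterer", {
  fx <- point_target_scan(n_freq = 16)
  scan <- fx$scan
  iz <- which(scan$z == -38)
  sub <- form_subarray(fx$array, 1)
  probes <- probe_positions(fx$array, -38)[sub, ]
  media <- medium_model()
  Mf <- scan$s21[sub, sub, 5, iz]
  Mf[is.na(Mf)] <- 0i
  Mf <- mwbim:::complete_diagonal(Mf, cap = 4)
  sv <- La.svd(Mf)
  r <- mwbim:::rank_by_gap(sv$d, 4)
  expect_equal(r, 1L)
  ps <- mwbim:::slice_path_split(fx$phantom$envelope, probes,
                                 matrix(c(19, 7, -38), 1, 3))
  k_t <- mwbim:::medium_wavenumber(media, "transition", scan$freq[5])
  k_in <- mwbim:::wavenumber_inbreast(media, scan$freq[5], 0.35)
  g <- mwbim:::two_media_green(ps$d_out, ps$d_in, k_t, k_in)
  g <- g / sqrt(sum(Mod(g)^2))
  Un <- sv$u[, (r + 1):8]
  expect_lt(sum(Mod(Conj(t(Un)) %*% g)^2), 1e-6)
})

test_that("two point scatterers 12 mm apart resolve as two maxima", {
  array <- default_array()
  freq <- scan_frequencies(16)
  media <- medium_model()
  env <- pendulous_envelope(55, 75)
  ph <- make_phantom(list(envelope = env, pc_fib = 0.35,
    lesions = list(lesion_spec(c(19, 13, -38), axes = c(0.9, 0.9, 0.9),
                               contrast = 3),
                   lesion_spec(c(19, 1, -38), axes = c(0.9, 0.9, 0.9),
                               contrast = 3))), seed = 2)
  grid <- voxel_grid(64, z = array$z_positions)
  scan <- synthesize_scan(ph, array, freq, media, grid = grid,
                          noise_level = 0,
                          artifacts = artifact_config(coupling = FALSE,
                                                      skin = FALSE))
  iz <- which(scan$z == -38)
  sub <- form_subarray(array, 2)
  probes <- probe_positions(array, -38)[sub, ]
  msk <- mwbim:::slice_mask(env, grid, -38, 6)
  in_idx <- which(msk)
  tg <- cbind(grid$x[(in_idx - 1) %% 64 + 1],
              grid$y[(in_idx - 1) %/% 64 + 1], -38)
  M <- scan$s21[sub, sub, , iz]
  img <- trmusic_sector(M, probes, tg, freq, 0.35, env, media)
  # local maxima by 6 mm neighbourhood suppression
  o <- order(-img$values)
  peaks <- matrix(numeric(0), 0, 2)
  for (i in o) {
    p <- tg[i, 1:2]
    if (nrow(peaks) == 0 ||
        min(sqrt(rowSums(sweep(peaks, 2, p)^2))) > 8) {
      peaks <- rbind(peaks, p)
    }
    if (nrow(peaks) == 2) break
  }
  truth <- rbind(c(19, 13), c(19, 1))
  d <- apply(truth, 1, function(tr)
    min(sqrt(rowSums(sweep(peaks, 2, tr)^2))))
  expect_true(all(d <= 2 * sqrt(2)))
})

test_that("pseudospectrum is invariant to global data scaling", {
  fx <- point_target_scan(n_freq = 8)
  scan <- fx$scan
  iz <- which(scan$z == -38)
  sub <- form_subarray(fx$array, 1)
  probes <- probe_positions(fx$array, -38)[sub, ]
  tg <- cbind(c(19, 15, 11), c(7, 9, 3), -38)
  M <- scan$s21[sub, sub, , iz]
  i1 <- trmusic_sector(M, probes, tg, scan$freq, 0.35, fx$phantom$envelope)
  i2 <- trmusic_sector(M * (3 - 2i), probes, tg, scan$freq, 0.35,
                       fx$phantom$envelope)
  expect_equal(i1$values, i2$values, tolerance = 1e-8)
  expect_warning(trmusic_sector(M * 0, probes, tg, scan$freq, 0.35,
                                fx$phantom$envelope), "all-zero")
})

test_that("focus quality ranks concentration", {
  expect_equal(focus_quality(rep(1, 100)), 1)
  expect_equal(focus_quality(rep(0, 50)), 0)
  imp <- c(1, rep(0, 99))
  expect_equal(focus_quality(imp), 100)
  x <- seq(-10, 10)
  g2 <- exp(-as.vector(outer(x^2, x^2, "+")) / (2 * 2^2))
  g6 <- exp(-as.vector(outer(x^2, x^2, "+")) / (2 * 6^2))
  expect_gt(focus_quality(g2), focus_quality(g6))
  # scale invariance
  expect_equal(focus_quality(5 * g2), focus_quality(g2))
})

test_that("assumption selection maximizes focus with midpoint tie-break", {
  mk <- function(pc, values) structure(list(values = values, pc_fib = pc,
                                            focus = focus_quality(values)),
                                       class = "sector_image")
  flat <- rep(1, 50)
  imp <- c(10, rep(0.1, 49))
  # dominance: the impulse image wins
  sel <- select_pcfib(list(mk(0.2, flat), mk(0.35, imp), mk(0.5, flat)),
                      c(20, 50))
  expect_equal(sel$pc_fib, 0.35)
  # identical candidates: the midpoint-closest is returned
  sel2 <- select_pcfib(list(mk(0.2, flat), mk(0.3, flat), mk(0.5, flat)),
                       c(20, 50))
  expect_equal(sel2$pc_fib, 0.3)
  expect_error(select_pcfib(list(), c(20, 50)), "config error")
})

test_that("stitching is a partition of unity and tolerates dead sectors", {
  dims <- c(16, 16)
  mask <- matrix(TRUE, 16, 16)
  idx_all <- which(mask)
  n <- length(idx_all)
  mk <- function(values) structure(list(values = values, pc_fib = 0.3,
                                        focus = 1), class = "sector_image")
  sectors <- lapply(1:21, function(s) mk(rep(1, n)))
  wedge <- lapply(1:21, function(s) idx_all)
  wts <- lapply(1:21, function(s) runif(n, 0.2, 1))
  out <- stitch_sectors(sectors, wedge, wts, dims, mask)
  expect_equal(out, matrix(1, 16, 16))
  # one all-zero sector: output stays finite (weights renormalized)
  sectors[[5]] <- mk(rep(0, n))
  out2 <- stitch_sectors(sectors, wedge, wts, dims, mask)
  expect_true(all(is.finite(out2)))
  expect_equal(out2, matrix(1, 16, 16))
  # a coverage gap raises an error naming the pixel count
  wedge_gap <- lapply(1:21, function(s) idx_all[-1])
  sec_gap <- lapply(1:21, function(s) mk(rep(1, n - 1)))
  wts_gap <- lapply(1:21, function(s) rep(1, n - 1))
  expect_error(stitch_sectors(sec_gap, wedge_gap, wts_gap, dims, mask),
               "coverage gap")
})

test_that("slice stacking respects slabs and the cut-out plane", {
  grid <- voxel_grid(8, z = c(-30, -32, -34))
  mask <- array(TRUE, c(8, 8, 3))
  s1 <- matrix(1, 8, 8); s2 <- matrix(2, 8, 8); s3 <- matrix(3, 8, 8)
  v <- stack_slices(list(s1, s2, s3), c(-30, -32, -34), grid, mask)
  expect_equal(v$data[, , 1], s1)
  expect_equal(v$data[, , 2], s2)
  # scatterer in exactly one slab -> volume max at that z
  sp <- matrix(0, 8, 8); sp[4, 4] <- 7
  v2 <- stack_slices(list(s1 * 0, sp, s1 * 0), c(-30, -32, -34), grid, mask)
  expect_equal(which.max(apply(v2$data, 3, max)), 2L)
  # cut-out zeroes the flagged slices
  v3 <- stack_slices(list(s1, s2, s3), c(-30, -32, -34), grid, mask,
                     cutout = 2L)
  expect_true(all(v3$data[, , 1] == 0))
  expect_equal(v3$excluded, c(TRUE, FALSE, FALSE))
})

test_that("volume NIfTI export round-trips the lattice", {
  grid <- voxel_grid(10, z = c(-30, -32, -34))
  vol <- structure(list(data = array(runif(300), c(10, 10, 3)), grid = grid,
                        mask = array(TRUE, c(10, 10, 3)),
                        cutout = NA_integer_, excluded = rep(FALSE, 3),
                        provenance = "test"), class = "volume_image")
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- read_volume_nifti(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$grid$x, grid$x)
  expect_equal(back$grid$z, grid$z)
  unlink(path)
})
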