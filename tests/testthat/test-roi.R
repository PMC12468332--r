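mk_volume <- function(data, mask = NULL) {
  dims <- dim(data)
  grid <- voxel_grid(dims[1], z = seq(-30, by = -2, length.out = dims[3]))
  if (is.null(mask)) mask <- array(TRUE, dims)
  structure(list(data = data, grid = grid, mask = mask,
                 cutout = NA_integer_, excluded = rep(FALSE, dims[3]),
                 provenance = "test"), class = "volume_image")
}

gauss_blob <- function(dims, ctr, sigma = 2, amp = 10) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  array(amp * exp(-rowSums(sweep(co, 2, ctr)^2) / (2 * sigma^2)), dims)
}

test_that("convex hull volume and area are exact on canonical shapes", {
  pts <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  h <- convex_hull_3d(pts)
  expect_equal(h$volume, 1000)
  expect_equal(h$area, 600)
  # interior points do not change the hull
  set.seed(2)
  h2 <- convex_hull_3d(rbind(pts, matrix(runif(300, 0.5, 9.5), ncol = 3)))
  expect_equal(h2$volume, 1000, tolerance = 1e-9)
  # degenerate coplanar cloud
  flat <- cbind(runif(20), runif(20), 1)
  expect_equal(convex_hull_3d(flat)$volume, 0)
  # points on a sphere: volume below the ball volume, approaching it
  v <- matrix(rnorm(1500), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * 5
  hv <- convex_hull_3d(v)$volume
  expect_lt(hv, 4 / 3 * pi * 125)
  expect_gt(hv, 0.9 * 4 / 3 * pi * 125)
})

test_that("Otsu threshold separates a balanced bimodal sample", {
  set.seed(4)
  x <- c(rnorm(250, 1, 0.2), rnorm(250, 8, 0.2))
  th <- otsu_threshold(x)
  # the threshold falls in the gap and splits the classes exactly
  expect_equal(sum(x < th), 250L)
  expect_equal(otsu_threshold(rep(3, 10)), 3)
})

test_that("segmentation finds blob components and their extent", {
  dims <- c(24, 24, 8)
  # one blob, peak 10x background
  d1 <- gauss_blob(dims, c(12, 12, 4)) + 1
  v1 <- mk_volume(d1)
  c1 <- segment_candidates(v1)
  expect_length(c1, 1)
  pk <- arrayInd(which.max(d1), dims)
  expect_true(which.max(d1) %in% c1[[1]]$idx)
  # two blobs 30 mm apart
  d2 <- gauss_blob(dims, c(6, 6, 4)) + gauss_blob(dims, c(21, 21, 4)) + 1
  c2 <- segment_candidates(mk_volume(d2))
  expect_length(c2, 2)
  # rasterized 10 mm-radius sphere: component voxel count matches the
  # direct enumeration oracle within one surface layer
  co <- arrayInd(seq_len(prod(dims)), dims)
  sph <- array(sqrt(rowSums(sweep(co * 2, 2, c(24, 24, 8))^2)) <= 10, dims)
  d3 <- array(1, dims); d3[sph] <- 10
  c3 <- segment_candidates(mk_volume(d3))
  expect_length(c3, 1)
  n_oracle <- sum(sph)
  n_surface <- sum(sph & !mwbim:::erode3d(sph))
  expect_lte(abs(c3[[1]]$n_vox - n_oracle), n_surface)
  # empty volume warns
  expect_warning(segment_candidates(mk_volume(array(0, dims))), "empty")
})

test_that("persistence filter enforces the quorum rule", {
  cand <- list(list(idx = 1:3, centroid = c(0, 0, -30), n_vox = 3))
  near <- list(list(idx = 1:3, centroid = c(1, 1, -30), n_vox = 3))
  far <- list(list(idx = 1:3, centroid = c(40, 0, -30), n_vox = 3))
  rc_all <- replicate(11, near, simplify = FALSE)
  expect_equal(persistence_filter(cand, rc_all)[[1]]$persistence, 11)
  rc_one <- c(list(near), replicate(10, far, simplify = FALSE))
  expect_length(persistence_filter(cand, rc_one, quorum = 6), 0)
  # boundary: exactly the quorum count is kept (rule is >=)
  rc_k <- c(replicate(6, near, simplify = FALSE),
            replicate(5, far, simplify = FALSE))
  expect_length(persistence_filter(cand, rc_k, quorum = 6), 1)
})

test_that("structural filter rejects specks, filaments and faint blobs", {
  dims <- c(24, 24, 10)
  bg <- array(1, dims)
  set.seed(9)
  bg <- bg + array(rnorm(prod(dims), 0, 0.1), dims)
  # a 0.1 mL speck (12 voxels)
  speck <- as.matrix(expand.grid(4:6, 4:7, 3)) ; speck <- speck[1:12, ]
  # a 1 mL solid ball
  co <- arrayInd(seq_len(prod(dims)), dims)
  ball <- which(array(sqrt(rowSums(sweep(co * 2, 2, c(32, 32, 12))^2)) <= 6.5,
                      dims))
  # an L-shaped 1-voxel filament (low solidity, just above the volume gate)
  fil <- unique(rbind(cbind(2:21, 18, 8), cbind(21, 4:17, 8)))
  data <- bg
  data[speck] <- 8; data[ball] <- 8
  fil_idx <- fil[, 1] + (fil[, 2] - 1) * dims[1] + (fil[, 3] - 1) * prod(dims[1:2])
  data[fil_idx] <- 8
  vol <- mk_volume(data)
  cands <- list(
    list(idx = speck[, 1] + (speck[, 2] - 1) * 24 + (speck[, 3] - 1) * 576,
         centroid = c(0, 0, -34), n_vox = 12),
    list(idx = ball, centroid = c(8, 8, -42), n_vox = length(ball)),
    list(idx = fil_idx, centroid = c(0, 10, -44), n_vox = nrow(fil))
  )
  out <- structural_filter(cands, vol)
  expect_length(out$rois, 1)
  expect_equal(out$rois[[1]]$n_vox, length(ball))
  expect_setequal(out$rejects$reason, c("volume", "solidity"))
  # filament solidity against the shoelace-prism hull oracle: the hull of
  # the L's voxel corner points is a 2D convex polygon extruded 2 mm
  sol <- mwbim:::mask_solidity(fil_idx, dims, 2)
  xy <- unique(rbind(cbind(2:21, 18), cbind(21, 4:17)))
  corners <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
    cbind(xy[i, 1] * 2 + c(-1, 1, -1, 1), xy[i, 2] * 2 + c(-1, -1, 1, 1))))
  ch <- grDevices::chull(corners)
  poly <- corners[ch, ]
  n <- nrow(poly)
  area2d <- abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
                    poly[c(2:n, 1), 1] * poly[, 2]) / 2)
  sol_oracle <- (nrow(fil) * 8) / (area2d * 2)
  expect_equal(sol, sol_oracle, tolerance = 1e-8)
  expect_lt(sol, 0.3)
})

test_that("ROI metrics are definitional and affine-consistent", {
  dims <- c(16, 16, 6)
  data <- array(2, dims)
  set.seed(3)
  data <- data + array(rnorm(prod(dims)), dims)
  # build a compact ROI block with constant value 10
  blk <- as.matrix(expand.grid(7:9, 7:9, 3:4))
  idx <- blk[, 1] + (blk[, 2] - 1) * 16 + (blk[, 3] - 1) * 256
  data[idx] <- 10
  vol <- mk_volume(data)
  met <- roi_metrics(idx, vol)
  bgmask <- array(TRUE, dims); bgmask[idx] <- FALSE
  excl <- array(FALSE, dims); excl[idx] <- TRUE
  excl <- mwbim:::dilate3d(mwbim:::dilate3d(excl))
  bg <- data[!excl]
  expect_equal(met$snr, mean(data[idx]) / sd(bg), tolerance = 1e-12)
  expect_equal(met$cnr, (mean(data[idx]) - mean(bg)) / sd(bg),
               tolerance = 1e-12)
  expect_equal(met$volume_ml, length(idx) * 0.008)
  # adding a constant leaves CNR unchanged, shifts SNR as per the formulas
  vol2 <- mk_volume(data + 5)
  met2 <- roi_metrics(idx, vol2)
  expect_equal(met2$cnr, met$cnr, tolerance = 1e-10)
  expect_equal(met2$snr, met$snr + 5 / sd(bg), tolerance = 1e-10)
  # 3 collinear voxels at 2 mm pitch -> max dimension 4 mm
  tri <- cbind(3:5, 2, 2)
  idx3 <- tri[, 1] + (tri[, 2] - 1) * 16 + (tri[, 3] - 1) * 256
  expect_equal(roi_metrics(idx3, vol)$max_dim_mm, 4)
  # random blob: max dimension equals the exhaustive pairwise oracle
  set.seed(5)
  rnd <- unique(cbind(sample(4:13, 30, TRUE), sample(4:13, 30, TRUE),
                      sample(2:5, 30, TRUE)))
  idxr <- rnd[, 1] + (rnd[, 2] - 1) * 16 + (rnd[, 3] - 1) * 256
  met_r <- roi_metrics(idxr, vol)
  co <- arrayInd(idxr, dims)
  pts <- cbind(vol$grid$x[co[, 1]], vol$grid$y[co[, 2]], vol$grid$z[co[, 3]])
  dmax <- 0
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
    dmax <- max(dmax, sum((pts[i, ] - pts[j, ])^2))
  expect_equal(met_r$max_dim_mm, sqrt(dmax), tolerance = 1e-10)
})

test_that("validated ROIs satisfy all structural thresholds post hoc", {
  dims <- c(24, 24, 8)
  data <- gauss_blob(dims, c(12, 12, 4), sigma = 3) + 1
  set.seed(6)
  data <- data + array(rnorm(prod(dims), 0, 0.05), dims)
  vol <- mk_volume(data)
  out <- extract_rois(vol, min_volume = 0.1, min_solidity = 0.3,
                      min_contrast = 2)
  expect_gt(length(out$rois), 0)
  for (r in out$rois) {
    expect_gte(r$volume_ml, 0.1)
    expect_gte(r$solidity, 0.3)
    expect_gte(r$cnr, 2)
  }
})
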