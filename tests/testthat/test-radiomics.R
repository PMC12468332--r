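test_that("fixed-bin quantization follows the equal-width arithmetic", {
  expect_equal(quantize(rep(2.5, 9)), rep(1L, 9))
  # values spanning [0, 64) with unit steps -> floor(value) + 1
  x <- 0:63
  expect_equal(quantize(x), as.integer(floor(x / 63 * 64)) + 1L -
                 as.integer(floor(x / 63 * 64) == 64))
  # histogram matches an independent binning pass
  set.seed(7)
  y <- rnorm(500)
  lv <- quantize(y)
  r <- range(y)
  lv_oracle <- pmin(floor((y - r[1]) / diff(r) * 64) + 1, 64)
  expect_equal(lv, as.integer(lv_oracle))
  expect_true(all(lv >= 1 & lv <= 64))
  expect_error(quantize(numeric(0)), "empty")
})

test_that("first-order features match closed forms and the moment oracle", {
  f0 <- first_order_features(rep(4, 20))
  expect_equal(f0[["entropy"]], 0)
  expect_equal(f0[["uniformity"]], 1)
  expect_equal(f0[["variance"]], 0)
  expect_true(is.na(f0[["skewness"]]))
  # two equiprobable levels -> 1 bit, uniformity 0.5
  f2 <- first_order_features(rep(c(0, 10), 25))
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["uniformity"]], 0.5)
  # normal-ish sample: uncorrected kurtosis near 3, oracle equality
  set.seed(12)
  x <- rnorm(4000)
  fx <- first_order_features(x)
  expect_equal(fx[["kurtosis"]], 3, tolerance = 0.2)
  orc <- oracle_first_order(x)
  for (nm in names(orc))
    expect_equal(fx[[nm]], orc[[nm]], tolerance = 1e-10)
})

test_that("shape features behave on canonical solids", {
  dims <- c(24, 24, 24)
  co <- arrayInd(seq_len(prod(dims)), dims)
  # filled box: solidity exactly 1
  box <- array(FALSE, dims); box[5:12, 5:12, 5:14] <- TRUE
  sb <- shape_features(which(box), dims, 2)
  expect_equal(sb[["solidity"]], 1)
  # digital ball: near-spherical, rounder than a 3:1 ellipsoid
  ball <- array(sqrt(rowSums((co - 12.5)^2)) <= 8, dims)
  se <- shape_features(which(ball), dims, 2)
  expect_gte(se[["sphericity"]], 0.9)
  expect_lte(se[["sphericity"]], 1.0)
  ell <- array(((co[, 1] - 12.5) / 10.5)^2 + ((co[, 2] - 12.5) / 3.5)^2 +
               ((co[, 3] - 12.5) / 3.5)^2 <= 1, dims)
  sl <- shape_features(which(ell), dims, 2)
  expect_gt(se[["sphericity"]], sl[["sphericity"]])
  expect_equal(se[["elongation"]], 1, tolerance = 0.02)
  # 3:1:1 ellipsoid: axis ratios from the explicit covariance oracle;
  # flatness equals elongation by symmetry
  pts <- co[ell, ] * 2
  n <- nrow(pts)
  ctr <- colMeans(pts)
  S <- matrix(0, 3, 3)
  for (i in seq_len(n)) S <- S + tcrossprod(pts[i, ] - ctr)
  S <- S / (n - 1)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(sl[["elongation"]], sqrt(ev[2] / ev[1]), tolerance = 1e-10)
  expect_equal(sl[["flatness"]], sqrt(ev[3] / ev[1]), tolerance = 1e-10)
  expect_equal(sl[["flatness"]], sl[["elongation"]], tolerance = 0.03)
  # coplanar mask: flatness flagged
  flat <- array(FALSE, dims); flat[3:10, 3:10, 5] <- TRUE
  expect_true(is.na(shape_features(which(flat), dims, 2)[["flatness"]]))
})

test_that("GLCM features match hand enumeration and the brute-force oracle", {
  # constant ROI: a single co-occurrence cell
  lev_const <- array(1L, c(3, 3, 3))
  g0 <- glcm_features(lev_const)
  expect_equal(g0[["joint_entropy"]], 0)
  expect_equal(g0[["joint_energy"]], 1)
  expect_equal(g0[["contrast"]], 0)
  # 2x2x1 hand enumeration: horizontal+vertical pairs of [[1,1],[1,2]]
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[2, 1, 1] <- 1L; lev[1, 2, 1] <- 1L; lev[2, 2, 1] <- 2L
  # direction (1,0,0): pairs (1,1),(1,2); direction (0,1,0): (1,1),(1,2);
  # symmetrized counts per direction {(1,1):2,(1,2):1,(2,1):1}
  # diagonal directions add {(1,2)} and {(1,1)} pairs
  g <- glcm_features(lev)
  orc <- oracle_glcm(lev)
  for (nm in names(orc)) expect_equal(g[[nm]], orc[[nm]], tolerance = 1e-12)
  # the in-plane horizontal/vertical sub-check by explicit counts:
  # p(1,1) = 1/2, p(1,2) = p(2,1) = 1/4 -> joint entropy 1.5 bits
  ph <- c(0.5, 0.25, 0.25)
  expect_equal(-sum(ph * log2(ph)), 1.5)
  # random arrays against the exhaustive pair-counting oracle
  for (s in 1:3) {
    lr <- random_level_array(c(6, 6, 6), 8, seed = s)
    lr[sample(length(lr), 40)] <- NA                # ragged mask
    gr <- glcm_features(lr)
    orr <- oracle_glcm(lr)
    for (nm in names(orr))
      expect_equal(gr[[nm]], orr[[nm]], tolerance = 1e-10)
  }
  # no valid pair -> NA
  single <- array(NA_integer_, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_true(all(is.na(glcm_features(single))))
})

test_that("NGTDM features match the brute-force neighbourhood oracle", {
  lev_const <- array(1L, c(4, 4, 4))
  n0 <- ngtdm_features(lev_const)
  expect_equal(n0[["contrast"]], 0)
  expect_equal(n0[["strength"]], 0)
  expect_equal(n0[["coarseness"]], 1e6)           # guarded maximum
  for (s in 1:3) {
    lr <- random_level_array(c(6, 6, 6), 8, seed = s + 10)
    lr[sample(length(lr), 40)] <- NA
    nr <- ngtdm_features(lr)
    orr <- oracle_ngtdm(lr)
    for (nm in names(orr))
      expect_equal(nr[[nm]], orr[[nm]], tolerance = 1e-10)
  }
  single <- array(NA_integer_, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_true(all(is.na(ngtdm_features(single))))
})

test_that("level-based features are invariant to affine intensity rescaling", {
  dims <- c(8, 8, 8)
  set.seed(21)
  data <- array(runif(prod(dims)), dims)
  idx <- which(array(sqrt(rowSums((arrayInd(seq_len(prod(dims)), dims) -
                                     4.5)^2)) <= 3.2, dims))
  f1 <- roi_feature_vector(idx, data)
  f2 <- roi_feature_vector(idx, data * 7 + 3)
  level_feats <- grep("entropy|uniformity|glcm|ngtdm|shape",
                      names(f1), value = TRUE)
  for (nm in level_feats) expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-9)
  # raw-intensity statistics shift as expected
  expect_equal(f2[["firstorder_mean"]], 7 * f1[["firstorder_mean"]] + 3,
               tolerance = 1e-10)
})

test_that("the feature vector has the 25 canonical entries and bounds", {
  dims <- c(10, 10, 10)
  set.seed(31)
  data <- array(runif(prod(dims)) + 1, dims)
  co <- arrayInd(seq_len(prod(dims)), dims)
  idx <- which(array(sqrt(rowSums((co - 5.5)^2)) <= 3.4, dims))
  fv <- roi_feature_vector(idx, data)
  expect_length(fv, 25)
  expect_gte(fv[["firstorder_entropy"]], 0)
  expect_gt(fv[["firstorder_uniformity"]], 0)
  expect_lte(fv[["firstorder_uniformity"]], 1)
  expect_gt(fv[["glcm_joint_energy"]], 0)
  expect_lte(fv[["glcm_joint_energy"]], 1)
  expect_gt(fv[["shape_solidity"]], 0)
  expect_lte(fv[["shape_solidity"]], 1)
  expect_lte(fv[["shape_elongation"]], 1)
  expect_lte(fv[["shape_flatness"]], 1)
})
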