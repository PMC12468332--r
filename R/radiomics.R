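#' Fixed-bin-number gray-level quantization
#'
#' Maps ROI intensities to gray levels 1..`n_levels` with equal-width bins
#' over the ROI's min-max range (fixed bin number, 64 by default). A
#' constant ROI maps to level 1. The min-max normalization makes every
#' level-based texture feature invariant to positive affine intensity
#' rescaling.
#'
#' @param x numeric intensities.
#' @param n_levels number of gray levels (default 64).
#' @return integer levels in 1..`n_levels`.
#' @export
quantize <- function(x, n_levels = 64L) {
  if (length(x) == 0) stop("ROI is empty")
  if (!all(is.finite(x))) stop("ROI intensities must be finite")
  r <- range(x)
  if (diff(r) == 0) return(rep(1L, length(x)))
  pmin(as.integer(floor((x - r[1]) / diff(r) * n_levels)) + 1L, n_levels)
}

#' First-order intensity statistics
#'
#' Mean, median and (population) variance on the raw intensities; entropy
#' (`-sum p log2 p`, bits), uniformity (`sum p^2`) on the fixed-bin level
#' histogram; skewness and kurtosis as standardized moments (kurtosis
#' uncorrected: 3 for a normal distribution). Single-voxel ROIs get
#' undefined skewness/kurtosis flagged `NA`.
#'
#' @param x raw ROI intensities.
#' @param levels quantized levels ([quantize()]); computed when missing.
#' @param n_levels number of gray levels.
#' @return named numeric vector with `mean`, `median`, `variance`,
#'   `entropy`, `skewness`, `kurtosis`, `uniformity`.
#' @export
first_order_features <- function(x, levels = quantize(x, n_levels),
                                 n_levels = 64L) {
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  p <- tabulate(levels, n_levels) / n
  p <- p[p > 0]
  if (n > 1 && v > 0) {
    skw <- (sum((x - m)^3) / n) / v^1.5
    krt <- (sum((x - m)^4) / n) / v^2
  } else {
    skw <- NA_real_; krt <- NA_real_
  }
  c(mean = m, median = stats::median(x), variance = v,
    entropy = -sum(p * log2(p)), skewness = skw, kurtosis = krt,
    uniformity = sum(p^2))
}

#' Shape features of a voxel mask
#'
#' Solidity (voxel volume over convex-hull volume, hull of the voxel corner
#' points); sphericity `(36 pi V^2)^(1/3) / A` with the surface area `A`
#' estimated from the exposed voxel faces with the 2/3 orientation-average
#' correction (both capped at 1, their theoretical maximum); elongation
#' `sqrt(l2/l1)` and flatness `sqrt(l3/l1)` from the ordered eigenvalues of
#' the voxel-centre coordinate covariance. Coplanar masks get flatness `NA`.
#'
#' @param idx linear voxel indices of the (connected) mask.
#' @param dims volume dimensions.
#' @param spacing voxel spacing in mm.
#' @return named vector `solidity`, `sphericity`, `elongation`, `flatness`.
#' @export
shape_features <- function(idx, dims, spacing = 2) {
  sol <- mask_solidity(idx, dims, spacing)
  v <- length(idx) * spacing^3
  a <- mask_surface_area(idx, dims, spacing)
  sph <- min(1, (36 * pi * v^2)^(1 / 3) / a)
  co <- arrayInd(idx, dims) * spacing
  el <- fl <- NA_real_
  if (nrow(co) >= 4) {
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    if (ev[1] > 0) {
      el <- sqrt(ev[2] / ev[1])
      fl <- if (ev[3] / ev[1] > 1e-12) sqrt(ev[3] / ev[1]) else NA_real_
    }
  }
  c(solidity = sol, sphericity = sph, elongation = el, flatness = fl)
}

# Surface area estimate: exposed voxel faces, scaled by 2/3 (the average of
# |nx|+|ny|+|nz| over orientations of a smooth surface patch is 3/2, so raw
# face counting overestimates smooth areas by that factor).
mask_surface_area <- function(idx, dims, spacing = 2) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  faces <- 0
  for (k in seq_len(nrow(OFF6))) {
    nb <- shift_array(m, OFF6[k, 1], OFF6[k, 2], OFF6[k, 3], fill = FALSE)
    faces <- faces + sum(m & !nb)
  }
  faces * spacing^2 * 2 / 3
}

# The 13 unique 3D direction offsets at distance 1.
GLCM_OFFSETS <- local({
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
      (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
})

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Co-occurrence over the 13 unique 3D directions at distance 1, restricted
#' to in-mask voxel pairs, symmetrized and normalized per direction;
#' features are computed per direction and averaged. Masks without any valid
#' neighbour pair return `NA`s.
#'
#' @param lev integer 3D array of quantized levels, `NA` outside the mask.
#' @param n_levels number of gray levels.
#' @return named vector: `autocorrelation`, `contrast`, `correlation`,
#'   `difference_average`, `inverse_difference`, `joint_average`,
#'   `joint_energy`, `joint_entropy`, `sum_of_squares`.
#' @export
glcm_features <- function(lev, n_levels = 64L) {
  feats <- NULL
  for (k in seq_len(nrow(GLCM_OFFSETS))) {
    o <- GLCM_OFFSETS[k, ]
    nb <- shift_array(lev, o[1], o[2], o[3], fill = NA_integer_)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    i <- lev[ok]; j <- nb[ok]
    counts <- tabulate((i - 1L) * n_levels + j, n_levels * n_levels) +
              tabulate((j - 1L) * n_levels + i, n_levels * n_levels)
    p <- matrix(counts / sum(counts), n_levels, n_levels, byrow = TRUE)
    feats <- rbind(feats, glcm_stats(p))
  }
  if (is.null(feats))
    return(stats::setNames(rep(NA_real_, 9), colnames(glcm_stats(NULL))))
  colMeans(feats)
}

glcm_stats <- function(p) {
  nms <- c("autocorrelation", "contrast", "correlation",
           "difference_average", "inverse_difference", "joint_average",
           "joint_energy", "joint_entropy", "sum_of_squares")
  if (is.null(p)) return(matrix(NA_real_, 0, 9, dimnames = list(NULL, nms)))
  ng <- nrow(p)
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)           # row level
  J <- t(I)                         # column level
  px <- rowSums(p)
  mu <- sum(iv * px)
  sg <- sqrt(sum((iv - mu)^2 * px))
  pos <- p > 0
  corr <- if (sg > 0) (sum(I * J * p) - mu^2) / sg^2 else 1
  out <- c(
    autocorrelation   = sum(I * J * p),
    contrast          = sum((I - J)^2 * p),
    correlation       = corr,
    difference_average = sum(abs(I - J) * p),
    inverse_difference = sum(p / (1 + abs(I - J))),
    joint_average     = sum(I * p),
    joint_energy      = sum(p^2),
    joint_entropy     = -sum(p[pos] * log2(p[pos])),
    sum_of_squares    = sum((I - mu)^2 * p)
  )
  matrix(out, 1, 9, dimnames = list(NULL, nms))
}

#' Neighbourhood gray-tone difference (NGTDM) texture features
#'
#' For each gray level `i` present in the mask: `n_i` voxels, `p_i =
#' n_i / N`, and `s_i`, the summed absolute difference between the level and
#' the mean of each voxel's valid 26-neighbours. `N` counts voxels with at
#' least one valid neighbour; single-voxel masks return `NA`s. A small guard
#' `eps = 1e-6` bounds coarseness on homogeneous masks.
#'
#' @param lev integer 3D array of quantized levels, `NA` outside the mask.
#' @param n_levels number of gray levels.
#' @param eps coarseness guard.
#' @return named vector: `coarseness`, `contrast`, `busyness`,
#'   `complexity`, `strength`.
#' @export
ngtdm_features <- function(lev, n_levels = 64L, eps = 1e-6) {
  off <- neighbor_offsets(26L)
  nbsum <- array(0, dim(lev))
  nbcnt <- array(0, dim(lev))
  lev0 <- lev; lev0[is.na(lev0)] <- 0
  inm <- !is.na(lev)
  for (k in seq_len(nrow(off))) {
    sh <- shift_array(lev0, off[k, 1], off[k, 2], off[k, 3], fill = 0)
    shm <- shift_array(inm, off[k, 1], off[k, 2], off[k, 3], fill = FALSE)
    nbsum <- nbsum + sh * shm
    nbcnt <- nbcnt + shm
  }
  valid <- inm & nbcnt > 0
  nms <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  if (!any(valid)) return(stats::setNames(rep(NA_real_, 5), nms))
  i_val <- lev[valid]
  abar <- nbsum[valid] / nbcnt[valid]
  d <- abs(i_val - abar)
  N <- sum(valid)
  lv <- sort(unique(i_val))
  n_i <- vapply(lv, function(l) sum(i_val == l), numeric(1))
  s_i <- vapply(lv, function(l) sum(d[i_val == l]), numeric(1))
  p_i <- n_i / N
  ngp <- length(lv)
  psum <- sum(p_i * s_i)
  coarseness <- 1 / (eps + psum)
  if (ngp > 1) {
    PI <- outer(p_i, p_i)
    DI <- outer(lv, lv, `-`)
    contrast <- sum(PI * DI^2) / (ngp * (ngp - 1)) * sum(s_i) / N
    denom <- sum(abs(outer(lv * p_i, lv * p_i, `-`)))
    busyness <- if (denom > 0) psum / denom else 0
    PS <- outer(p_i * s_i, p_i * s_i, `+`)
    PP <- outer(p_i, p_i, `+`)
    complexity <- sum(abs(DI) * PS / PP) / N
    strength <- sum(PP * DI^2) / (eps + sum(s_i))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' The 25-feature radiomic vector of one ROI
#'
#' Shape (4), first-order (7), GLCM (9) and NGTDM (5) features with
#' fixed-bin-number 64 quantization.
#'
#' @param idx linear voxel indices of the ROI.
#' @param volume a `volume_image` (or a plain numeric 3D array).
#' @param n_levels gray levels (default 64).
#' @return named numeric vector of length 25.
#' @export
roi_feature_vector <- function(idx, volume, n_levels = 64L) {
  data <- if (inherits(volume, "volume_image")) volume$data else volume
  spacing <- if (inherits(volume, "volume_image")) volume$grid$spacing else 2
  x <- data[idx]
  lv <- quantize(x, n_levels)
  lev <- array(NA_integer_, dim(data))
  lev[idx] <- lv
  shp <- shape_features(idx, dim(data), spacing)
  fo <- first_order_features(x, lv, n_levels)
  gl <- glcm_features(lev, n_levels)
  ng <- ngtdm_features(lev, n_levels)
  c(stats::setNames(shp, paste0("shape_", names(shp))),
    stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(gl, paste0("glcm_", names(gl))),
    stats::setNames(ng, paste0("ngtdm_", names(ng))))
}

#' Feature table over a set of ROIs
#'
#' One row per ROI: identifiers, quality/size metrics, and the 25 radiomic
#' features.
#'
#' @param rois ROI records (from [extract_rois()], possibly [label_rois()]).
#' @param volume the analysis `volume_image`.
#' @param breast_id identifier prefix.
#' @return data frame.
#' @export
feature_table <- function(rois, volume, breast_id = "SYN") {
  if (length(rois) == 0) return(NULL)
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    fv <- roi_feature_vector(r$idx, volume)
    data.frame(breast_id = sprintf("%s_R%02d", breast_id, i),
               label = r$label %||% "UNSPECIFIED",
               class = r$class %||% NA_character_,
               snr = r$snr, cnr = r$cnr, max_dim_mm = r$max_dim_mm,
               volume_ml = r$volume_ml,
               persistence = r$persistence %||% NA_integer_,
               t(fv))
  })
  do.call(rbind, rows)
}

#' Write a feature table as delimited text
#'
#' @param tab a [feature_table()] data frame.
#' @param path output path (CSV).
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
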