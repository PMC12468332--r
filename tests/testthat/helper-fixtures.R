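# Shared small fixtures, built in code.

default_array <- function() probe_array(120, z_min = -120)

small_envelope <- function() pendulous_envelope(55, 75)

# Clean calibration-target scan: one compact scatterer, no artifact terms.
point_target_scan <- function(noise_level = 0, seed = 1L, n_freq = 16,
                              centre = c(19, 7, -38), contrast = 3) {
  array <- default_array()
  ph <- make_phantom(list(envelope = list(r_max = 55, depth = 75),
                          pc_fib = 0.35,
                          lesions = list(lesion_spec(centre,
                                                     axes = c(0.9, 0.9, 0.9),
                                                     contrast = contrast))),
                     seed = 5)
  grid <- voxel_grid(64, z = array$z_positions)
  scan <- synthesize_scan(ph, array, scan_frequencies(n_freq), medium_model(),
                          grid = grid, noise_level = noise_level,
                          artifacts = artifact_config(coupling = FALSE,
                                                      skin = FALSE),
                          seed = seed)
  list(scan = scan, phantom = ph, array = array, grid = grid)
}

# Random connected-ish voxel mask inside a small array (for feature oracles).
random_level_array <- function(dims = c(6, 6, 6), n_levels = 8, seed = 1) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  lev
}

# Brute-force GLCM feature oracle: explicit pair loops over the 13 unique
# 3D directions at distance 1, symmetrized, per-direction features averaged.
oracle_glcm <- function(lev, n_levels = 64L) {
  dims <- dim(lev)
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[dirs[, 3] > 0 | (dirs[, 3] == 0 & dirs[, 2] > 0) |
               (dirs[, 3] == 0 & dirs[, 2] == 0 & dirs[, 1] > 0), ]
  per_dir <- NULL
  for (d in seq_len(nrow(dirs))) {
    cnt <- matrix(0, n_levels, n_levels)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      if (is.na(lev[x, y, z])) next
      x2 <- x + dirs[d, 1]; y2 <- y + dirs[d, 2]; z2 <- z + dirs[d, 3]
      if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          z2 < 1 || z2 > dims[3]) next
      if (is.na(lev[x2, y2, z2])) next
      i <- lev[x, y, z]; j <- lev[x2, y2, z2]
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    iv <- seq_len(n_levels)
    px <- rowSums(p)
    mu <- sum(iv * px)
    sg2 <- sum((iv - mu)^2 * px)
    ac <- co <- da <- id <- ja <- je <- jent <- ss <- xy <- 0
    for (i in iv) for (j in iv) {
      pij <- p[i, j]
      ac <- ac + i * j * pij
      co <- co + (i - j)^2 * pij
      da <- da + abs(i - j) * pij
      id <- id + pij / (1 + abs(i - j))
      ja <- ja + i * pij
      je <- je + pij^2
      if (pij > 0) jent <- jent - pij * log2(pij)
      ss <- ss + (i - mu)^2 * pij
      xy <- xy + i * j * pij
    }
    corr <- if (sg2 > 0) (xy - mu^2) / sg2 else 1
    per_dir <- rbind(per_dir,
                     c(ac, co, corr, da, id, ja, je, jent, ss))
  }
  out <- colMeans(per_dir)
  names(out) <- c("autocorrelation", "contrast", "correlation",
                  "difference_average", "inverse_difference",
                  "joint_average", "joint_energy", "joint_entropy",
                  "sum_of_squares")
  out
}

# Brute-force NGTDM oracle: explicit 26-neighbour loops.
oracle_ngtdm <- function(lev, n_levels = 64L, eps = 1e-6) {
  dims <- dim(lev)
  i_val <- c(); dsum <- c()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(lev[x, y, z])) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          z2 < 1 || z2 > dims[3]) next
      if (!is.na(lev[x2, y2, z2])) nb <- c(nb, lev[x2, y2, z2])
    }
    if (length(nb) == 0) next
    i_val <- c(i_val, lev[x, y, z])
    dsum <- c(dsum, abs(lev[x, y, z] - mean(nb)))
  }
  if (length(i_val) == 0)
    return(stats::setNames(rep(NA_real_, 5),
                           c("coarseness", "contrast", "busyness",
                             "complexity", "strength")))
  N <- length(i_val)
  lv <- sort(unique(i_val))
  n_i <- sapply(lv, function(l) sum(i_val == l))
  s_i <- sapply(lv, function(l) sum(dsum[i_val == l]))
  p_i <- n_i / N
  ngp <- length(lv)
  psum <- sum(p_i * s_i)
  if (ngp > 1) {
    ctr <- 0; bden <- 0; cpx <- 0; stg <- 0
    for (a in seq_len(ngp)) for (b in seq_len(ngp)) {
      ctr <- ctr + p_i[a] * p_i[b] * (lv[a] - lv[b])^2
      bden <- bden + abs(lv[a] * p_i[a] - lv[b] * p_i[b])
      if (a != b) {
        cpx <- cpx + abs(lv[a] - lv[b]) *
          (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
        stg <- stg + (p_i[a] + p_i[b]) * (lv[a] - lv[b])^2
      }
    }
    c(coarseness = 1 / (eps + psum),
      contrast = ctr / (ngp * (ngp - 1)) * sum(s_i) / N,
      busyness = if (bden > 0) psum / bden else 0,
      complexity = cpx / N,
      strength = stg / (eps + sum(s_i)))
  } else {
    c(coarseness = 1 / (eps + psum), contrast = 0, busyness = 0,
      complexity = 0, strength = 0)
  }
}

# Brute-force first-order oracle.
oracle_first_order <- function(x, n_levels = 64L) {
  n <- length(x)
  r <- range(x)
  lev <- if (diff(r) == 0) rep(1L, n)
         else pmin(floor((x - r[1]) / diff(r) * n_levels) + 1L, n_levels)
  p <- sapply(seq_len(n_levels), function(l) sum(lev == l)) / n
  p <- p[p > 0]
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  c(mean = m, median = stats::median(x), variance = v,
    entropy = -sum(p * log2(p)),
    skewness = (sum((x - m)^3) / n) / v^1.5,
    kurtosis = (sum((x - m)^4) / n) / v^2,
    uniformity = sum(p^2))
}

# Independent convex-hull volume oracle (qhull via scipy).
oracle_hull_volume <- function(pts) {
  f_in <- tempfile(fileext = ".csv")
  utils::write.table(pts, f_in, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy, scipy.spatial, sys;",
    "p = numpy.loadtxt('", f_in, "', delimiter=',');",
    "print(repr(scipy.spatial.ConvexHull(p).volume))"))),
    stdout = TRUE)
  unlink(f_in)
  as.numeric(out[length(out)])
}
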