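#' The 11 fibroglandular-content search ranges
#'
#' Ordered set of (low, high) percentage pairs under which the parametric
#' volumes are reconstructed: 7 narrow and 4 wide ranges.
#'
#' @return list of 11 numeric pairs (percent).
#' @export
pcfib_ranges <- function() {
  list(c(10, 30), c(20, 40), c(30, 50), c(40, 60), c(50, 70), c(60, 80),
       c(70, 90), c(20, 50), c(50, 80), c(10, 60), c(40, 90))
}

#' Contiguous 8-probe sub-array around a centre probe
#'
#' Probes are indexed 1..n around the ring; the sub-array takes 3 probes to
#' the left and 4 to the right of the centre (fixed tie convention), with
#' wrap-around. Adjacent centres share 7 of their 8 probes and the union
#' over all centres covers the full ring.
#'
#' @param array a [probe_array()].
#' @param center centre probe index (1..n_probes).
#' @param n_s sub-array size (default 8).
#' @return integer vector of probe indices.
#' @export
form_subarray <- function(array, center, n_s = 8L) {
  if (center < 1 || center > array$n_probes) stop("centre index out of range")
  form_group(as.integer(center), as.integer(n_s), array$n_probes)
}

# Signal-subspace rank by the largest relative singular-value gap, capped.
rank_by_gap <- function(s, cap = 4L) {
  n <- length(s)
  if (s[1] <= 0) return(0L)
  g <- s[-n] / pmax(s[-1], s[1] * 1e-15)
  min(which.max(g[seq_len(min(cap, n - 1))]), cap)
}

# Iterative reciprocity-consistent completion of the absent monostatic
# diagonal: alternate low-rank approximation and diagonal replacement until
# the diagonal converges.
complete_diagonal <- function(M, cap = 4L, iters = 30L, tol = 1e-12) {
  d <- rep(0i, nrow(M))
  scale <- max(Mod(M), 0)
  if (scale == 0) return(M)
  for (k in seq_len(iters)) {
    A <- M; diag(A) <- d
    sv <- La.svd(A)
    r <- rank_by_gap(sv$d, cap)
    if (r == 0) break
    Ar <- sv$u[, seq_len(r), drop = FALSE] %*%
      (sv$d[seq_len(r)] * sv$vt[seq_len(r), , drop = FALSE])
    d_new <- diag(Ar)
    if (max(Mod(d_new - d)) < tol * scale) { d <- d_new; break }
    d <- d_new
  }
  diag(M) <- d
  M
}

#' Sector pseudospectrum by wideband TR-MUSIC
#'
#' For each frequency the 8 x 8 multistatic matrix of the sub-array is
#' completed on its (absent) monostatic diagonal, decomposed by SVD, and the
#' signal-subspace rank chosen by the largest relative singular-value gap
#' (capped). The pseudospectrum is `P(r) = 1 / sum_k |<u_k, g(r)>|^2` over
#' the noise-subspace vectors, with unit-norm steering vectors built from
#' two-media straight-ray propagation (transition liquid outside, pc_fib
#' mixed interior inside the envelope). Per-frequency pseudospectra are
#' normalized to unit maximum and averaged (incoherent wideband fusion).
#'
#' @param M complex array `n_s x n_s x n_freq` (cleaned multistatic data).
#' @param probes `n_s x 3` probe positions (mm).
#' @param targets `N x 3` voxel centres of the sector wedge (mm).
#' @param freq frequency grid (Hz).
#' @param pc_fib fibroglandular fraction assumption in `[0, 1]`.
#' @param envelope a [breast_envelope()].
#' @param media a [medium_model()].
#' @param max_rank signal-subspace rank cap (default 4).
#' @param paths optional precomputed [slice_path_split()] result for
#'   `(probes, targets)`; computed when `NULL`.
#' @param attenuation steering-vector amplitude model: `FALSE` (default)
#'   pairs phase + spreading steering with loss-compensated data; `TRUE`
#'   includes the dissipative decay (for uncompensated data).
#' @return object of class `sector_image`: `values` (nonnegative, one per
#'   target), `pc_fib`, `focus` (peak-to-mean score).
#' @export
trmusic_sector <- function(M, probes, targets, freq, pc_fib, envelope,
                           media = medium_model(), max_rank = 4L,
                           paths = NULL, attenuation = FALSE) {
  if (pc_fib < 0 || pc_fib > 1) stop("pc_fib must lie in [0, 1]")
  nf <- length(freq); ns <- nrow(probes); nv <- nrow(targets)
  if (all(Mod(M) == 0 | is.na(M))) {
    warning("all-zero data matrix: returning uniform sector image")
    return(structure(list(values = rep(1, nv), pc_fib = pc_fib, focus = 1),
                     class = "sector_image"))
  }
  if (is.null(paths)) paths <- slice_path_split(envelope, probes, targets)
  k_t <- medium_wavenumber(media, "transition", freq)
  k_in <- wavenumber_inbreast(media, freq, pc_fib)
  if (!attenuation) {
    k_t <- complex(real = 0, imaginary = Im(k_t))
    k_in <- complex(real = 0, imaginary = Im(k_in))
  }
  acc <- numeric(nv)
  for (ifr in seq_len(nf)) {
    Mf <- M[, , ifr]
    Mf[is.na(Mf)] <- 0i
    if (all(Mod(Mf) == 0)) { acc <- acc + 1 / nv; next }
    Mf <- complete_diagonal(Mf, cap = max_rank)
    sv <- La.svd(Mf)
    r <- rank_by_gap(sv$d, cap = max_rank)
    if (r >= ns) r <- ns - 1L
    G <- two_media_green(paths$d_out, paths$d_in, k_t[ifr], k_in[ifr])
    G <- G / rep(sqrt(colSums(Mod(G)^2)), each = ns)
    Un <- t(Conj(sv$u[, (r + 1):ns, drop = FALSE]))
    proj <- colSums(Mod(Un %*% G)^2)
    P <- 1 / pmax(proj, 1e-300)
    acc <- acc + P / max(P)
  }
  vals <- acc / nf
  structure(list(values = vals, pc_fib = pc_fib,
                 focus = focus_quality_values(vals)),
            class = "sector_image")
}

focus_quality_values <- function(v) {
  if (all(v == 0)) return(0)
  max(v) / mean(v)
}

#' Focus quality of a sector image
#'
#' Sharpness score: peak-to-mean ratio of the (nonnegative) sector image.
#' Invariant to global intensity scaling; 1 for a uniform image; 0 for an
#' all-zero image.
#'
#' @param image a `sector_image` or a nonnegative numeric vector/array.
#' @export
focus_quality <- function(image) {
  v <- if (inherits(image, "sector_image")) image$values else as.numeric(image)
  if (any(v < 0)) stop("sector image must be nonnegative")
  focus_quality_values(v)
}

#' Select the best-fitting pc_fib assumption of one sector
#'
#' Among candidate sector images reconstructed under different pc_fib
#' assumptions within one search range, returns the one with maximal focus
#' quality. Candidates whose focus lies within `tie_tol` (relative) of the
#' best are treated as ties and broken towards the range midpoint, so
#' sectors carrying no focusing evidence fall back to the least informative
#' assumption instead of an arbitrary edge.
#'
#' @param candidates list of `sector_image` objects.
#' @param range numeric `(low, high)` pair in percent.
#' @param tie_tol relative focus tolerance treated as a tie (default 0.02).
#' @return the selected `sector_image`.
#' @export
select_pcfib <- function(candidates, range, tie_tol = 0.02) {
  if (length(candidates) == 0) stop("config error: empty candidate list")
  f <- vapply(candidates, function(s) s$focus, numeric(1))
  pc <- vapply(candidates, function(s) s$pc_fib, numeric(1))
  best <- max(f)
  sel <- which(f >= best * (1 - tie_tol))
  mid <- mean(range) / 100
  candidates[[sel[which.min(abs(pc[sel] - mid))]]]
}

# Angular taper weight of a sector wedge: 1 over the 8-probe arc,
# raised-cosine roll-off over the margin.
sector_weight <- function(dtheta, core, margin) {
  a <- abs(dtheta)
  w <- numeric(length(a))
  w[a <= core] <- 1
  tp <- a > core & a < core + margin
  w[tp] <- 0.5 * (1 + cos(pi * (a[tp] - core) / margin))
  w
}

#' Stitch 21 sector images into a slice image
#'
#' Each sector image is normalized to unit maximum and the images are
#' combined by angular raised-cosine taper weighted averaging; at every
#' covered pixel the weights sum to one (partition of unity). All-zero
#' sectors are excluded from the weight renormalization.
#'
#' @param sectors list of `sector_image` objects (one per centre probe).
#' @param wedge_idx list of integer vectors: in-slice linear voxel indices of
#'   each sector's wedge.
#' @param weights list of numeric vectors: angular taper weight of each wedge
#'   voxel.
#' @param dims slice dimensions `c(nx, ny)`.
#' @param mask logical in-breast mask (nx x ny); pixels outside stay 0.
#' @return numeric matrix nx x ny.
#' @export
stitch_sectors <- function(sectors, wedge_idx, weights, dims, mask) {
  num <- matrix(0, dims[1], dims[2])
  den <- matrix(0, dims[1], dims[2])
  for (s in seq_along(sectors)) {
    v <- sectors[[s]]$values
    m <- max(v)
    if (m <= 0) next                       # all-zero sector: renormalize
    num[wedge_idx[[s]]] <- num[wedge_idx[[s]]] + weights[[s]] * (v / m)
    den[wedge_idx[[s]]] <- den[wedge_idx[[s]]] + weights[[s]]
  }
  uncovered <- mask & den == 0
  if (any(uncovered))
    stop("coverage gap at ", sum(uncovered), " in-breast pixel(s)")
  out <- matrix(0, dims[1], dims[2])
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[!mask] <- 0
  out
}

#' Stack coronal slice images into a volume
#'
#' Voxel planes take the triangular-weighted average of the +/- `half` mm
#' slabs covering their height; with 2 mm slices and the default half-width
#' the planes coincide with the slices. Slices above the cut-out plane are
#' zeroed and flagged.
#'
#' @param slices list of nx x ny matrices.
#' @param z slice heights (mm, ordered as `slices`).
#' @param grid a [voxel_grid()] (its `z` defines the output planes).
#' @param mask logical nx x ny x nz in-breast mask.
#' @param cutout index of the first valid slice ([detect_cutout_slice()]);
#'   `NA` for none.
#' @param half slab half-width in mm (default 2).
#' @param provenance character tag stored with the volume.
#' @return object of class `volume_image`.
#' @export
stack_slices <- function(slices, z, grid, mask, cutout = NA_integer_,
                         half = 2, provenance = "volume") {
  dims <- c(dim(slices[[1]]), length(grid$z))
  vol <- array(0, dims)
  for (k in seq_along(grid$z)) {
    w <- pmax(0, 1 - abs(grid$z[k] - z) / half)
    if (sum(w) == 0) next
    w <- w / sum(w)
    for (s in which(w > 0)) vol[, , k] <- vol[, , k] + w[s] * slices[[s]]
  }
  excluded <- rep(FALSE, length(grid$z))
  if (!is.na(cutout) && cutout > 1) {
    # grid z ordered as array z positions (table downwards)
    excluded <- seq_along(grid$z) < cutout
    vol[, , excluded] <- 0
  }
  vol[!mask] <- 0
  structure(list(data = vol, grid = grid, mask = mask, cutout = cutout,
                 excluded = excluded, provenance = provenance),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %d x %d x %d @ %g mm, max %.3g%s\n",
              x$provenance, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$grid$spacing, max(x$data),
              if (!is.na(x$cutout)) sprintf(", cut-out at slice %d", x$cutout)
              else ""))
  invisible(x)
}

#' Composite volumes over the pc_fib search ranges
#'
#' GLOBAL averages all 11 range volumes; LOW averages the ranges lying
#' entirely at or below 50 percent; HIGH averages the ranges entirely at or
#' above 50 percent. With the printed range set, LOW and HIGH each average 4
#' volumes.
#'
#' @param volumes list of `volume_image`s, one per range (co-registered).
#' @param ranges the matching list of `(low, high)` pairs
#'   (default [pcfib_ranges()]).
#' @return named list of `volume_image`s: `GLOBAL`, `LOW`, `HIGH`.
#' @export
composite_images <- function(volumes, ranges = pcfib_ranges()) {
  if (length(volumes) != length(ranges))
    stop("config error: need one volume per pc_fib range")
  avg <- function(vs, tag) {
    out <- vs[[1]]
    out$data <- Reduce(`+`, lapply(vs, function(v) v$data)) / length(vs)
    out$provenance <- tag
    out
  }
  lo <- vapply(ranges, function(r) r[2] <= 50, logical(1))
  hi <- vapply(ranges, function(r) r[1] >= 50, logical(1))
  out <- list(GLOBAL = avg(volumes, "GLOBAL"))
  if (any(lo)) out$LOW <- avg(volumes[lo], "LOW")
  if (any(hi)) out$HIGH <- avg(volumes[hi], "HIGH")
  out
}

# In-breast mask of one slice on the lattice. `interior_margin` (mm)
# excludes the skin shell: reconstruction support and ROI analysis are
# restricted to interior tissue, where surface-reflection residuals do not
# contaminate the pseudospectrum.
slice_mask <- function(envelope, grid, z, interior_margin = 0) {
  nx <- length(grid$x); ny <- length(grid$y)
  pts <- cbind(rep(grid$x, ny), rep(grid$y, each = nx), z)
  ins <- env_inside(envelope, pts)
  if (interior_margin > 0 && z >= envelope$z_bottom && z <= envelope$z_top) {
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    th <- atan2(pts[, 2], pts[, 1])
    rho <- envelope_radius(envelope, th, rep(z, nrow(pts)))
    ins <- ins & r <= rho - interior_margin
  }
  matrix(ins, nx, ny)
}

#' Reconstruct parametric volumes from a scan
#'
#' Full sectorized imaging chain: per slice and per centre probe the sector
#' data are preprocessed (PCA + EMD + distance and amplitude filtering),
#' compensated and imaged by wideband TR-MUSIC under every pc_fib candidate
#' of the union of the search ranges; per range and sector the best-focused
#' candidate is selected (ties to the range midpoint), sectors are stitched,
#' and slices stacked into one volume per range.
#'
#' @param scan a [synthesize_scan()] result.
#' @param envelope a [breast_envelope()].
#' @param mode an [imaging_mode()].
#' @param ranges list of `(low, high)` percent pairs (default the 11 printed
#'   ranges); alternatively pass `pc_fib` to image under fixed assumptions.
#' @param pc_fib optional fixed assumption(s) (fractions); overrides
#'   `ranges`.
#' @param pc_step candidate grid step within each range, percent points
#'   (default 5).
#' @param slices integer indices of scan slices to image (default all).
#' @param media a [medium_model()] (defaults to the scan's).
#' @param calib_ref calibration reference energy for the amplitude filter
#'   (`NULL` disables it).
#' @param max_rank signal-subspace rank cap.
#' @param margin_deg stitching taper margin in degrees.
#' @param chest_intrusion chest-wall intrusion (mm) for cut-out detection.
#' @param pad time-domain zero-padding factor.
#' @param gamma intensity exponent applied to each stitched slice (default
#'   3): MUSIC pseudospectra carry a compressed dynamic range, and a power
#'   rendering restores the contrast that detection and contrast metrics
#'   operate on.
#' @return list with `volumes` (one `volume_image` per range, or per fixed
#'   pc_fib), `ranges`, `selected_pcfib` (array range x sector x slice), and
#'   `cutout`.
#' @export
reconstruct_volume <- function(scan, envelope, mode = imaging_mode("DEFAULT"),
                               ranges = pcfib_ranges(), pc_fib = NULL,
                               pc_step = 5, slices = NULL,
                               media = scan$media, calib_ref = NULL,
                               max_rank = 4L, margin_deg = 10,
                               chest_intrusion = 0, pad = 4,
                               interior_margin = 6, gamma = 3) {
  array <- scan$array
  np <- array$n_probes
  if (is.null(slices)) slices <- seq_along(scan$z)
  if (!is.null(pc_fib)) ranges <- lapply(pc_fib * 100, function(p) c(p, p))
  cand_sets <- lapply(ranges, function(r)
    unique(seq(r[1], r[2], by = pc_step)) / 100)
  cand_all <- sort(unique(unlist(cand_sets)))
  nr <- length(ranges)
  grid <- voxel_grid(length(scan$grid$x %||% 64), z = scan$z[slices],
                     spacing = scan$grid$spacing %||% 2)
  grid$x <- scan$grid$x; grid$y <- scan$grid$y
  nx <- length(grid$x); ny <- length(grid$y)
  core <- (mode$n_s - 1) * (2 * pi / np) / 2
  margin <- margin_deg * pi / 180
  sel_pc <- array(NA_real_, c(nr, np, length(slices)))
  slice_imgs <- replicate(nr, vector("list", length(slices)), simplify = FALSE)
  mask3 <- array(FALSE, c(nx, ny, length(slices)))

  for (si in seq_along(slices)) {
    iz <- slices[si]
    z <- scan$z[iz]
    msk <- slice_mask(envelope, grid, z, interior_margin)
    mask3[, , si] <- msk
    in_idx <- which(msk)
    vox_xy <- cbind(grid$x[(in_idx - 1) %% nx + 1],
                    grid$y[(in_idx - 1) %/% nx + 1])
    vox_th <- atan2(vox_xy[, 2], vox_xy[, 1])
    sector_sel <- replicate(nr, vector("list", np), simplify = FALSE)
    wedge_idx <- weights <- vector("list", np)
    for (ctr in seq_len(np)) {
      ctr_th <- array$azimuth[ctr] + (2 * pi / np) / 2  # arc centre offset
      dth <- ((vox_th - ctr_th + pi) %% (2 * pi)) - pi
      w <- sector_weight(dth, core + 0 , margin)
      inw <- which(w > 0)
      wedge_idx[[ctr]] <- in_idx[inw]
      weights[[ctr]] <- w[inw]
      if (length(inw) == 0) next
      targets <- cbind(vox_xy[inw, , drop = FALSE], z)
      prep <- preprocess_sector(scan, iz, ctr, mode, envelope, media,
                                calib_ref = calib_ref, pad = pad)
      probes <- probe_positions(array, z)[prep$sub, ]
      paths <- slice_path_split(envelope, probes, targets)
      # assumption selection runs on the uncompensated spectra with
      # attenuation-matched steering: the exponential compensation
      # envelope would otherwise tilt packet group delays and bias the
      # focus comparison; the selected assumption's image is then built
      # from compensated data with phase-and-spreading steering
      M_ref <- sector_spectra(prep, NULL, media)
      imgs <- lapply(cand_all, function(pc) {
        suppressWarnings(
          trmusic_sector(M_ref, probes, targets, scan$freq, pc, envelope,
                         media, max_rank = max_rank, paths = paths,
                         attenuation = TRUE))
      })
      for (ri in seq_len(nr)) {
        cand <- imgs[match(cand_sets[[ri]], cand_all)]
        sel <- select_pcfib(cand, ranges[[ri]])
        final <- suppressWarnings(
          trmusic_sector(sector_spectra(prep, sel$pc_fib, media), probes,
                         targets, scan$freq, sel$pc_fib, envelope, media,
                         max_rank = max_rank, paths = paths))
        sector_sel[[ri]][[ctr]] <- final
        sel_pc[ri, ctr, si] <- sel$pc_fib
      }
    }
    for (ri in seq_len(nr)) {
      slice_imgs[[ri]][[si]] <-
        stitch_sectors(sector_sel[[ri]], wedge_idx, weights,
                       c(nx, ny), msk)^gamma
    }
  }
  cutout <- detect_cutout_slice(envelope, array, chest_intrusion)
  # map cut-out (index into full z grid) onto the imaged slice subset
  cut_local <- if (is.na(cutout)) NA_integer_
               else sum(array$z_positions[seq_len(cutout - 1)] %in% scan$z[slices]) + 1L
  vols <- lapply(seq_len(nr), function(ri) {
    tag <- if (!is.null(pc_fib)) sprintf("pc_fib %.0f%%", ranges[[ri]][1])
           else sprintf("range %d:%d%%", ranges[[ri]][1], ranges[[ri]][2])
    stack_slices(slice_imgs[[ri]], scan$z[slices], grid, mask3,
                 cutout = cut_local, provenance = tag)
  })
  list(volumes = vols, ranges = ranges, selected_pcfib = sel_pc,
       cutout = cut_local)
}
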