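# --- small 3D binary-image toolbox ----------------------------------------
# (3D morphology on the 2 mm lattice; volumes here are small enough for
# vectorized whole-array shifts)

shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  vx <- sx >= 1 & sx <= d[1]; vy <- sy >= 1 & sy <= d[2]; vz <- sz >= 1 & sz <= d[3]
  out[xs[vx], ys[vy], zs[vz]] <- a[sx[vx], sy[vy], sz[vz]]
  out
}

neighbor_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, ]
  off
}

#' Binary dilation / erosion with a 1-voxel ball
#'
#' 6-connected (face-touching) structuring element.
#'
#' @param mask logical 3D array.
#' @export
dilate3d <- function(mask) {
  out <- mask
  for (k in seq_len(nrow(OFF6))) {
    out <- out | shift_array(mask, OFF6[k, 1], OFF6[k, 2], OFF6[k, 3])
  }
  out
}

#' @rdname dilate3d
#' @export
erode3d <- function(mask) {
  out <- mask
  for (k in seq_len(nrow(OFF6))) {
    out <- out & shift_array(mask, OFF6[k, 1], OFF6[k, 2], OFF6[k, 3], fill = TRUE)
  }
  out
}

OFF6 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
OFF6 <- OFF6[rowSums(abs(OFF6)) == 1, ]

# Surface voxels of a mask (linear indices): voxels with an exposed face.
surface_voxels <- function(idx, dims) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  er <- erode3d(m)
  out <- which(m & !er)
  if (length(out) == 0) idx else out
}

#' 26-connected component labelling
#'
#' Iterative minimum-label propagation over the 26-neighbourhood.
#'
#' @param mask logical 3D array.
#' @return integer array; 0 background, components numbered 1..k by
#'   decreasing voxel count.
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  off <- neighbor_offsets(26L)
  repeat {
    new <- lab
    for (k in seq_len(nrow(off))) {
      sh <- shift_array(lab, off[k, 1], off[k, 2], off[k, 3], fill = 0)
      upd <- mask & sh > 0 & (new == 0 | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  sizes <- tabulate(match(lab[lab > 0], ids))
  ord <- order(sizes, decreasing = TRUE)
  out <- array(0L, d)
  for (r in seq_along(ord)) out[lab == ids[ord[r]]] <- r
  out
}

#' Otsu threshold
#'
#' Maximizes the between-class variance of a 256-bin histogram.
#'
#' @param x numeric values.
#' @param nbins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nbins),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1]
}

# --- ROI extraction --------------------------------------------------------

#' Segment candidate ROIs from a reconstructed volume
#'
#' Thresholds the in-breast voxels (below the cut-out plane) at the Otsu
#' level, applies a morphological opening then closing with a 1-voxel ball,
#' and returns the 26-connected components.
#'
#' @param volume a `volume_image`.
#' @param threshold optional fixed threshold overriding Otsu; a value in
#'   `(0, 1)` interpreted as an intensity quantile when
#'   `threshold_quantile = TRUE`.
#' @param threshold_quantile interpret `threshold` as a quantile.
#' @return list of candidates; each has `idx` (linear voxel indices),
#'   `centroid` (mm), `n_vox`.
#' @export
segment_candidates <- function(volume, threshold = NULL,
                               threshold_quantile = FALSE) {
  valid <- volume$mask
  if (any(volume$excluded)) valid[, , volume$excluded] <- FALSE
  vals <- volume$data[valid]
  if (length(vals) == 0 || all(vals == 0)) {
    warning("empty in-breast region: no candidates")
    return(list())
  }
  th <- if (is.null(threshold)) otsu_threshold(vals)
        else if (threshold_quantile) stats::quantile(vals, threshold)
        else threshold
  bin <- volume$data >= th & valid
  bin <- dilate3d(erode3d(bin))      # opening
  bin <- erode3d(dilate3d(bin))      # closing
  bin <- bin & valid
  lab <- connected_components(bin)
  k <- max(lab)
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    idx <- which(lab == i)
    co <- arrayInd(idx, dim(lab))
    centroid <- c(mean(volume$grid$x[co[, 1]]), mean(volume$grid$y[co[, 2]]),
                  mean(volume$grid$z[co[, 3]]))
    list(idx = idx, centroid = centroid, n_vox = length(idx))
  })
}

#' Persistence filter across the pc_fib range volumes
#'
#' A candidate from the analysis volume is persistent when a candidate with
#' a centroid within `r_match` mm exists in at least `quorum` of the range
#' volumes.
#'
#' @param candidates candidates from the analysis volume
#'   ([segment_candidates()]).
#' @param range_candidates list (one entry per range volume) of candidate
#'   lists.
#' @param r_match centroid matching radius in mm (default 5).
#' @param quorum minimal number of supporting range volumes (default 6).
#' @return the persistent subset, each with a `persistence` count added.
#' @export
persistence_filter <- function(candidates, range_candidates, r_match = 5,
                               quorum = 6) {
  keep <- list()
  for (cand in candidates) {
    count <- sum(vapply(range_candidates, function(rc) {
      any(vapply(rc, function(c2)
        sqrt(sum((c2$centroid - cand$centroid)^2)) <= r_match, logical(1)))
    }, logical(1)))
    if (count >= quorum) {
      cand$persistence <- count
      keep[[length(keep) + 1]] <- cand
    }
  }
  keep
}

#' ROI quality and size metrics
#'
#' `SNR = mean(ROI) / sd(background)`, `CNR = (mean(ROI) -
#' mean(background)) / sd(background)`; the background is the in-breast
#' region outside every candidate mask dilated by 2 voxels. The maximal
#' linear dimension is the largest centre-to-centre pairwise voxel distance;
#' the ROI volume is `n_vox * 0.008` mL on the 2 mm lattice.
#'
#' @param idx linear voxel indices of the ROI.
#' @param volume a `volume_image`.
#' @param exclude_idx voxel indices of all candidate ROIs (defaults to
#'   `idx`) removed (with a 2-voxel dilated margin) from the background.
#' @return list with `snr`, `cnr`, `max_dim_mm`, `volume_ml`, `mean`,
#'   `median`.
#' @export
roi_metrics <- function(idx, volume, exclude_idx = idx) {
  dims <- dim(volume$data)
  excl <- array(FALSE, dims)
  excl[exclude_idx] <- TRUE
  excl <- dilate3d(dilate3d(excl))
  valid <- volume$mask
  if (any(volume$excluded)) valid[, , volume$excluded] <- FALSE
  bg <- valid & !excl
  if (!any(bg)) stop("metric error: empty background region")
  bg_vals <- volume$data[bg]
  roi_vals <- volume$data[idx]
  s_bg <- stats::sd(bg_vals)
  co <- arrayInd(idx, dims)
  pts <- cbind(volume$grid$x[co[, 1]], volume$grid$y[co[, 2]],
               volume$grid$z[co[, 3]])
  max_dim <- max_pairwise_distance(pts)
  sp <- volume$grid$spacing
  list(snr = mean(roi_vals) / s_bg,
       cnr = (mean(roi_vals) - mean(bg_vals)) / s_bg,
       max_dim_mm = max_dim,
       volume_ml = length(idx) * sp^3 / 1000,
       mean = mean(roi_vals), median = stats::median(roi_vals))
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(0)
  if (n > 400) {                      # diameter is attained on the hull
    h <- convex_hull_3d(pts)
    pts <- h$points[h$vertices, , drop = FALSE]
    n <- nrow(pts)
  }
  d2 <- 0
  for (i in seq_len(n - 1)) {
    di <- (pts[(i + 1):n, 1] - pts[i, 1])^2 +
          (pts[(i + 1):n, 2] - pts[i, 2])^2 +
          (pts[(i + 1):n, 3] - pts[i, 3])^2
    d2 <- max(d2, max(di))
  }
  sqrt(d2)
}

# Solidity of a voxel mask: voxel volume over convex-hull volume (hull of
# the voxel corner points, so convex digital shapes score 1).
mask_solidity <- function(idx, dims, spacing = 2) {
  h <- mask_hull(idx, dims, spacing)
  v_mask <- length(idx) * spacing^3
  if (h$volume <= 0) return(NA_real_)
  min(1, v_mask / h$volume)
}

#' Structural and contrast ROI validation
#'
#' Keeps candidates with volume >= `min_volume` mL, solidity >=
#' `min_solidity` and CNR >= `min_contrast`; rejects are logged with the
#' failed rule.
#'
#' @param candidates candidate list (from [persistence_filter()] or
#'   [segment_candidates()]).
#' @param volume the analysis `volume_image`.
#' @param min_volume minimal ROI volume in mL (default 0.25).
#' @param min_solidity minimal solidity (default 0.3).
#' @param min_contrast minimal CNR (default 2).
#' @return list with `rois` (validated ROI records) and `rejects` (data
#'   frame of rejected candidates and reasons).
#' @export
structural_filter <- function(candidates, volume, min_volume = 0.25,
                              min_solidity = 0.3, min_contrast = 2) {
  all_idx <- unlist(lapply(candidates, function(c) c$idx))
  rois <- list()
  rejects <- data.frame(candidate = integer(0), reason = character(0),
                        value = numeric(0))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    met <- roi_metrics(cand$idx, volume, exclude_idx = all_idx)
    sol <- mask_solidity(cand$idx, dim(volume$data), volume$grid$spacing)
    if (met$volume_ml < min_volume) {
      rejects <- rbind(rejects, data.frame(candidate = i, reason = "volume",
                                           value = met$volume_ml))
    } else if (!is.na(sol) && sol < min_solidity) {
      rejects <- rbind(rejects, data.frame(candidate = i, reason = "solidity",
                                           value = sol))
    } else if (met$cnr < min_contrast) {
      rejects <- rbind(rejects, data.frame(candidate = i, reason = "contrast",
                                           value = met$cnr))
    } else {
      rois[[length(rois) + 1]] <- c(cand, met, list(solidity = sol,
                                                    label = "UNSPECIFIED"))
    }
  }
  list(rois = rois, rejects = rejects)
}

#' Extract validated ROIs from the analysis volume
#'
#' Chains [segment_candidates()], [persistence_filter()] across the range
#' volumes and [structural_filter()] on the designated analysis volume
#' (default the GLOBAL composite).
#'
#' @param analysis analysis `volume_image` (e.g. the GLOBAL composite).
#' @param range_volumes list of per-range `volume_image`s (for persistence);
#'   `NULL` skips the persistence filter.
#' @param quorum,r_match persistence parameters (quorum defaults to a
#'   majority of the available range volumes, capped at 6).
#' @param threshold,threshold_quantile detection threshold passed to
#'   [segment_candidates()] (`NULL` = Otsu).
#' @param ... thresholds passed to [structural_filter()].
#' @return as [structural_filter()], with a `persistence` field per ROI.
#' @export
extract_rois <- function(analysis, range_volumes = NULL, quorum = NULL,
                         r_match = 5, threshold = NULL,
                         threshold_quantile = FALSE, ...) {
  cands <- segment_candidates(analysis, threshold, threshold_quantile)
  if (!is.null(range_volumes) && length(range_volumes) > 0) {
    rc <- lapply(range_volumes, segment_candidates,
                 threshold = threshold,
                 threshold_quantile = threshold_quantile)
    if (is.null(quorum)) quorum <- min(6L, ceiling(length(range_volumes) / 2))
    cands <- persistence_filter(cands, rc, r_match = r_match, quorum = quorum)
  }
  structural_filter(cands, analysis, ...)
}

#' Label extracted ROIs against phantom ground truth
#'
#' ROIs whose centroid lies within `r_match` mm of a phantom lesion centroid
#' receive the label `CLINICAL` (with the lesion's class recorded);
#' remaining ROIs keep `UNSPECIFIED` unless the phantom carries a fold whose
#' location matches (`ARTIFACT_2`).
#'
#' @param rois ROI records ([extract_rois()]).
#' @param phantom the originating [make_phantom()].
#' @param r_match matching radius in mm beyond the lesion's largest
#'   semi-axis (default 15, about the chain's point-spread scale).
#' @export
label_rois <- function(rois, phantom, r_match = 15) {
  for (i in seq_along(rois)) {
    lab <- "UNSPECIFIED"; cls <- NA_character_
    for (les in phantom$lesions) {
      if (sqrt(sum((rois[[i]]$centroid - les$centre)^2)) <=
          r_match + max(les$axes)) {
        lab <- "CLINICAL"; cls <- les$label
        break
      }
    }
    if (lab == "UNSPECIFIED" && !is.null(phantom$fold)) {
      env <- phantom$envelope
      r_s <- envelope_radius(env, phantom$fold$azimuth, phantom$fold$z)
      fq <- c(r_s * cos(phantom$fold$azimuth),
              r_s * sin(phantom$fold$azimuth), phantom$fold$z)
      if (sqrt(sum((rois[[i]]$centroid - fq)^2)) <= 2 * r_match)
        lab <- "ARTIFACT_2"
    }
    rois[[i]]$label <- lab
    rois[[i]]$class <- cls
  }
  rois
}
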