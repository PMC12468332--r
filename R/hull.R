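# 3D convex hull (quickhull) for voxel point clouds: volume, surface area
# and vertex set. Self-contained; inputs here are small (hundreds to a few
# thousand corner points of ROI masks).

tri_normal <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Convex hull of a 3D point set
#'
#' Quickhull with triangular faces. Degenerate (coplanar or collinear) point
#' sets return zero volume.
#'
#' @param pts N x 3 numeric matrix.
#' @return list with `volume`, `area`, `vertices` (indices into the
#'   de-duplicated point set), `points`.
#' @export
convex_hull_3d <- function(pts) {
  pts <- unique(round(pts, 9))
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(c) diff(range(c))), 1e-12)
  eps <- 1e-9 * scale
  degenerate <- list(volume = 0, area = 0, vertices = seq_len(n), points = pts)
  if (n < 4) return(degenerate)

  # initial extreme tetrahedron
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  if (i1 == i2) return(degenerate)
  d12 <- pts[i2, ] - pts[i1, ]
  # farthest from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dl <- sqrt(rowSums(cr^2))
  i3 <- which.max(dl)
  if (dl[i3] < eps) return(degenerate)
  nrm <- tri_normal(pts[i1, ], pts[i2, ], pts[i3, ])
  dp <- rel %*% nrm
  i4 <- which.max(abs(dp))
  if (abs(dp[i4]) < eps) return(degenerate)

  verts <- c(i1, i2, i3, i4)
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid <- colMeans(pts[verts, ])
  orient <- function(f) {
    nn <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
    if (sum(nn * (centroid - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(faces, orient)
  face_info <- function(f) {
    nn <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
    list(v = f, n = nn, p0 = pts[f[1], ])
  }
  faces <- lapply(faces, face_info)
  # assign outside sets
  assign_out <- function(face, cand) {
    if (length(cand) == 0) return(integer(0))
    d <- sweep(pts[cand, , drop = FALSE], 2, face$p0) %*% face$n
    cand[d > eps]
  }
  remaining <- setdiff(seq_len(n), verts)
  for (k in seq_along(faces)) {
    faces[[k]]$out <- assign_out(faces[[k]], remaining)
  }

  repeat {
    fi <- which(vapply(faces, function(f) length(f$out) > 0, logical(1)))
    if (length(fi) == 0) break
    f <- faces[[fi[1]]]
    d <- sweep(pts[f$out, , drop = FALSE], 2, f$p0) %*% f$n
    p <- f$out[which.max(d)]
    vis <- vapply(faces, function(g)
      sum(g$n * (pts[p, ] - g$p0)) > eps, logical(1))
    if (!any(vis)) { faces[[fi[1]]]$out <- setdiff(f$out, p); next }
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(faces[vis], function(g)
      rbind(g$v[c(1, 2)], g$v[c(2, 3)], g$v[c(3, 1)])))
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    pool <- unique(unlist(lapply(faces[vis], function(g) g$out)))
    pool <- setdiff(pool, p)
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon))) {
      nf <- face_info(c(horizon[e, 1], horizon[e, 2], p))
      # orient outward w.r.t. interior centroid
      if (sum(nf$n * (centroid - nf$p0)) > 0) {
        nf <- face_info(c(horizon[e, 2], horizon[e, 1], p))
      }
      nf$out <- assign_out(nf, pool)
      faces[[length(faces) + 1]] <- nf
    }
  }

  area <- sum(vapply(faces, function(f) {
    nn <- tri_normal(pts[f$v[1], ], pts[f$v[2], ], pts[f$v[3], ])
    sqrt(sum(nn^2)) / 2
  }, numeric(1)))
  vol <- sum(vapply(faces, function(f)
    abs(det(rbind(pts[f$v[2], ] - pts[f$v[1], ],
                  pts[f$v[3], ] - pts[f$v[1], ],
                  centroid - pts[f$v[1], ]))) / 6, numeric(1)))
  list(volume = vol, area = area,
       vertices = sort(unique(unlist(lapply(faces, function(f) f$v)))),
       points = pts)
}

# Corner points (voxel vertices) of the surface voxels of a mask.
mask_corner_points <- function(idx, dims, spacing = 2, origin = c(0, 0, 0)) {
  co <- arrayInd(idx, dims)
  off <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  pts <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
    sweep(co, 2, -off[k, ])))
  unique(sweep(pts * spacing, 2, -origin, `+`))
}

# Hull of a voxel mask (corner points of its surface voxels).
mask_hull <- function(idx, dims, spacing = 2) {
  surf <- surface_voxels(idx, dims)
  convex_hull_3d(mask_corner_points(surf, dims, spacing))
}
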