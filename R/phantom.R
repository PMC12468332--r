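#' Lesion specification
#'
#' Describes one dielectrically contrasted lesion: an ellipsoidal base shape
#' with optional angular spiculation and random surface roughness, a bulk
#' dielectric contrast multiplier against the breast interior, and a voxelwise
#' heterogeneity level. "Malignant-like" presets are spiculated, rough and
#' heterogeneous; "benign-like" presets are smooth homogeneous ellipsoids.
#'
#' @param centre xyz centroid in mm (z negative below the table plane).
#' @param axes ellipsoid semi-axes in mm (length 3, positive).
#' @param spiculation number of angular spicules (integer >= 0).
#' @param roughness surface roughness amplitude in mm (>= 0).
#' @param contrast dielectric contrast multiplier (>= 1).
#' @param heterogeneity relative sd of voxelwise contrast noise (>= 0).
#' @param label free-text class label carried through the analysis.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(centre, axes, spiculation = 0, roughness = 0,
                        contrast = 2, heterogeneity = 0, label = "lesion") {
  if (any(axes <= 0)) stop("lesion axes must be positive")
  if (contrast < 1) stop("lesion contrast multiplier must be >= 1")
  if (roughness < 0 || heterogeneity < 0)
    stop("roughness and heterogeneity must be nonnegative")
  structure(list(centre = as.numeric(centre), axes = as.numeric(axes),
                 spiculation = as.integer(spiculation), roughness = roughness,
                 contrast = contrast, heterogeneity = heterogeneity,
                 label = label),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @param size maximal lesion diameter in mm.
#' @export
lesion_malignant <- function(centre, size = 14) {
  lesion_spec(centre, axes = size / 2 * c(1, 0.8, 0.7), spiculation = 8,
              roughness = 3, contrast = 3.5, heterogeneity = 0.4,
              label = "malignant")
}

#' @rdname lesion_spec
#' @export
lesion_benign <- function(centre, size = 14) {
  lesion_spec(centre, axes = size / 2 * c(1, 0.85, 0.75), spiculation = 0,
              roughness = 0, contrast = 3.5, heterogeneity = 0,
              label = "benign")
}

#' Build a synthetic breast phantom
#'
#' Assembles the simulation ground truth: a pendulous envelope, a true
#' fibroglandular fraction `pc_fib`, a list of lesions, and artifact flags
#' (skin fold, chest-wall intrusion). Random ingredients (lesion surface
#' roughness harmonics) are drawn here from `seed`, so the phantom is
#' reproducible bit for bit.
#'
#' @param spec list with fields `envelope` (a [breast_envelope()] or a list
#'   of [pendulous_envelope()] arguments), `pc_fib` in `[0, 1]`, `lesions`
#'   (list of [lesion_spec()]), and optionally `fold` (list with `azimuth`
#'   rad, `z` mm, `amplitude` relative) and `chest_intrusion` mm.
#' @param seed integer RNG seed.
#' @return object of class `phantom`.
#' @export
make_phantom <- function(spec, seed = 1L) {
  env <- spec$envelope
  if (!inherits(env, "breast_envelope"))
    env <- do.call(pendulous_envelope, env)
  pc <- spec$pc_fib
  if (is.null(pc) || pc < 0 || pc > 1) stop("pc_fib must lie in [0, 1]")
  lesions <- spec$lesions %||% list()
  for (les in lesions) {
    if (!env_inside(env, les$centre))
      stop("lesion placement error: centroid outside the envelope")
  }
  # freeze per-lesion roughness harmonics
  lesions <- lapply(seq_along(lesions), function(i) {
    les <- lesions[[i]]
    local_rng(seed + 1000L * i, {
      les$rough_coef  <- stats::rnorm(4, sd = 0.5)
      les$rough_phase <- stats::runif(4, 0, 2 * pi)
    })
    les$id <- i
    les
  })
  structure(list(envelope = env, pc_fib = pc, lesions = lesions,
                 fold = spec$fold, chest_intrusion = spec$chest_intrusion %||% 0,
                 seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> pc_fib %.2f, %d lesion(s)%s%s, seed %d\n",
              x$pc_fib, length(x$lesions),
              if (!is.null(x$fold)) ", skin fold" else "",
              if (x$chest_intrusion > 0)
                sprintf(", chest intrusion %g mm", x$chest_intrusion) else "",
              x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a private RNG stream, restoring the caller's RNG state.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Imaging voxel lattice
#'
#' 2 mm isotropic in-plane lattice centred on the scanner axis; x and y voxel
#' centres fall on odd-millimetre coordinates, axial planes coincide with the
#' vertical scan positions.
#'
#' @param n_xy in-plane voxel count per axis.
#' @param z axial plane positions in mm.
#' @param spacing in-plane spacing in mm (default 2).
#' @return list with voxel-centre coordinate vectors `x`, `y`, `z` and
#'   `spacing`.
#' @export
voxel_grid <- function(n_xy = 64, z, spacing = 2) {
  half <- n_xy / 2
  x <- (seq_len(n_xy) - half - 0.5) * spacing
  list(x = x, y = x, z = z, spacing = spacing)
}

# Radius multiplier of the perturbed lesion surface in direction
# (theta azimuth, phi polar), 1 = base ellipsoid.
lesion_surface_mult <- function(les, theta, phi) {
  if (les$roughness <= 0 && les$spiculation == 0) return(rep(1, length(theta)))
  amp <- les$roughness / mean(les$axes)
  m <- rep(0, length(theta))
  if (les$spiculation > 0)
    m <- m + cos(les$spiculation * theta) * sin(phi)^2
  for (k in seq_along(les$rough_coef))
    m <- m + les$rough_coef[k] * cos(k * theta + les$rough_phase[k]) * sin(phi)
  pmax(0.2, 1 + amp * m)
}

#' Rasterize one lesion onto a voxel lattice
#'
#' @param les a [lesion_spec()] (as stored in a [make_phantom()] object, i.e.
#'   with frozen roughness harmonics; a raw spec gets zero roughness noise).
#' @param grid a [voxel_grid()].
#' @return logical array `length(x) x length(y) x length(z)`.
#' @export
lesion_mask <- function(les, grid) {
  if (is.null(les$rough_coef)) { les$rough_coef <- numeric(0) }
  dx <- outer(grid$x - les$centre[1], rep(1, length(grid$y)))
  dy <- outer(rep(1, length(grid$x)), grid$y - les$centre[2])
  mask <- array(FALSE, c(length(grid$x), length(grid$y), length(grid$z)))
  for (k in seq_along(grid$z)) {
    dz <- grid$z[k] - les$centre[3]
    u <- sqrt((dx / les$axes[1])^2 + (dy / les$axes[2])^2 + (dz / les$axes[3])^2)
    theta <- atan2(dy, dx)
    r3 <- sqrt(dx^2 + dy^2 + dz^2)
    phi <- acos(pmin(1, pmax(-1, dz / pmax(r3, 1e-9))))
    mult <- lesion_surface_mult(les, as.vector(theta), as.vector(phi))
    mask[, , k] <- u <= matrix(mult, nrow(u), ncol(u))
  }
  mask
}

#' Voxelwise contrast map of a phantom
#'
#' Rasterizes every lesion of the phantom at the lattice resolution and
#' assigns each lesion voxel the contrast `base contrast * (1 +
#' heterogeneity * noise)`; the noise stream is derived from the phantom
#' seed, so the map is deterministic for a fixed phantom and grid.
#'
#' @param phantom a [make_phantom()] object.
#' @param grid a [voxel_grid()].
#' @return list with `contrast` (numeric array, 0 outside lesions) and
#'   `label` (integer array of lesion ids, 0 outside).
#' @export
phantom_contrast_map <- function(phantom, grid) {
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  contrast <- array(0, dims)
  label <- array(0L, dims)
  for (les in phantom$lesions) {
    m <- lesion_mask(les, grid)
    idx <- which(m)
    if (length(idx) == 0) next
    vals <- rep(les$contrast, length(idx))
    if (les$heterogeneity > 0) {
      # spatially correlated heterogeneity (~2-voxel correlation length):
      # malignant tissue heterogeneity lives at a scale the imaging chain
      # can resolve, not at single-voxel graininess
      field <- local_rng(phantom$seed + 7000L + les$id,
                         array(stats::rnorm(length(m)), dim(m)))
      field <- smooth3d(field, sigma = 2)
      noise <- field[idx]
      s <- stats::sd(noise)
      if (is.finite(s) && s > 0) noise <- noise / s
      vals <- les$contrast * pmax(0.1, 1 + les$heterogeneity * noise)
    }
    contrast[idx] <- vals
    label[idx] <- les$id
  }
  list(contrast = contrast, label = label)
}

# Separable 3D Gaussian smoothing (reflecting boundaries via renormalized
# truncated kernel).
smooth3d <- function(a, sigma = 2) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  sm1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1), n)
      out <- out + k[j + r + 1] * v[idx]
    }
    out / sum(k)
  }
  a <- apply(a, c(2, 3), sm1)          # -> [i, j, k]
  a <- apply(a, c(1, 3), sm1)          # -> [j, i, k]
  a <- apply(a, c(1, 2), sm1)          # -> [k, j, i]
  aperm(a, c(3, 2, 1))
}

# Point scatterers (xyz + contrast) within the +/- halfwidth slab of a slice.
slab_scatterers <- function(phantom, grid, z_slice, halfwidth = 2) {
  keep_z <- which(abs(grid$z - z_slice) <= halfwidth + 1e-9)
  if (length(keep_z) == 0)
    return(list(points = matrix(0, 0, 3), contrast = numeric(0)))
  sub <- voxel_grid(length(grid$x), z = grid$z[keep_z], spacing = grid$spacing)
  sub$x <- grid$x; sub$y <- grid$y
  cm <- phantom_contrast_map(phantom, sub)
  idx <- which(cm$contrast > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(points = matrix(0, 0, 3), contrast = numeric(0)))
  # triangular slab weight centred on the slice plane
  w <- 1 - abs(sub$z[idx[, 3]] - z_slice) / (halfwidth + grid$spacing)
  list(points = cbind(grid$x[idx[, 1]], grid$y[idx[, 2]], sub$z[idx[, 3]]),
       contrast = cm$contrast[cm$contrast > 0] * w)
}
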