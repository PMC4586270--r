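# Synthetic atlas fixtures and 3D Gaussian smoothing.

#' Generate a synthetic atlas label volume
#'
#' Builds an ellipsoidal brain-like mask inscribed in the grid and partitions
#' it into `nRegions` contiguous, non-overlapping regions (Voronoi cells of
#' well-spread seed points, which are convex and hence connected). This is a
#' synthetic stand-in for a parcellation such as the 26 prefrontal regions
#' used by the correlation-pattern analysis; real label volumes are accepted
#' anywhere an atlas is, via [readVolume()].
#'
#' @param dim Integer grid dimensions c(nx, ny, nz).
#' @param nRegions Number of regions (default 26).
#' @param voxelSize Isotropic voxel size in mm.
#' @param seed Integer seed for seed-point placement.
#' @return List of class `atlas`: `labels` (integer array, 0 outside), `mask`
#'   (logical array), `regions` (data frame id, name, nvox, centroid mm),
#'   `voxelSize`.
#' @export
generateAtlasFixture <- function(dim = c(20, 20, 12), nRegions = 26,
                                 voxelSize = 3, seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 2))
  mask <- ellipsoidMask(dim)
  nMask <- sum(mask)
  if (nRegions > nMask) stop("too many regions for grid: mask has ", nMask, " voxels")
  idx <- which(mask, arr.ind = TRUE)
  seeds <- withSeed(seed, {
    # Farthest-point sampling from a random start spreads seeds evenly.
    pick <- sample.int(nMask, 1L)
    d2 <- rowSums((idx - matrix(idx[pick, ], nMask, 3, byrow = TRUE))^2)
    out <- pick
    while (length(out) < nRegions) {
      nxt <- which.max(d2)
      out <- c(out, nxt)
      d2 <- pmin(d2, rowSums((idx - matrix(idx[nxt, ], nMask, 3, byrow = TRUE))^2))
    }
    out
  })
  seedXYZ <- idx[seeds, , drop = FALSE]
  # Voronoi assignment of mask voxels to seeds.
  d2all <- vapply(seq_len(nRegions), function(k)
    rowSums((idx - matrix(seedXYZ[k, ], nMask, 3, byrow = TRUE))^2), numeric(nMask))
  lab <- max.col(-d2all, ties.method = "first")
  labels <- array(0L, dim)
  labels[mask] <- lab
  cent <- vapply(seq_len(nRegions), function(k)
    colMeans(idx[lab == k, , drop = FALSE]) * voxelSize, numeric(3))
  regions <- data.frame(id = seq_len(nRegions),
                        name = sprintf("region%02d", seq_len(nRegions)),
                        nvox = as.integer(table(factor(lab, levels = seq_len(nRegions)))),
                        x_mm = cent[1, ], y_mm = cent[2, ], z_mm = cent[3, ],
                        stringsAsFactors = FALSE)
  if (any(regions$nvox == 0)) stop("degenerate atlas: empty region")
  structure(list(labels = labels, mask = mask, regions = regions,
                 voxelSize = voxelSize),
            class = "atlas")
}

# Ellipsoid inscribed in the grid (semi-axes at dim/2 - 0.5).
ellipsoidMask <- function(dim, shrink = 1) {
  cx <- (dim + 1) / 2
  ax <- (dim / 2 - 0.5) * shrink
  x <- ((seq_len(dim[1]) - cx[1]) / ax[1])^2
  y <- ((seq_len(dim[2]) - cx[2]) / ax[2])^2
  z <- ((seq_len(dim[3]) - cx[3]) / ax[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

#' Brain-like ellipsoidal mask with an exact voxel count
#'
#' Ranks grid voxels by ellipsoidal radius (axis proportions roughly those of
#' a human brain) and keeps exactly `nVoxels`, e.g. the study mask's 82,244
#' voxels at 3 mm.
#'
#' @param nVoxels Exact number of in-mask voxels.
#' @param proportions Relative semi-axis lengths x:y:z.
#' @return Logical 3D array (bounding grid with a 1-voxel margin).
#' @export
brainlikeMask <- function(nVoxels = 82244, proportions = c(1, 1.2, 0.85)) {
  # Solve for semi-axes giving the requested ellipsoid volume.
  a <- (nVoxels * 3 / (4 * pi * prod(proportions / proportions[1])))^(1 / 3)
  semi <- a * proportions / proportions[1]
  dim <- 2 * ceiling(semi + 1) + 1
  cx <- (dim + 1) / 2
  x <- ((seq_len(dim[1]) - cx[1]) / semi[1])^2
  y <- ((seq_len(dim[2]) - cx[2]) / semi[2])^2
  z <- ((seq_len(dim[3]) - cx[3]) / semi[3])^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  cut <- sort(r2, partial = nVoxels)[nVoxels]
  mask <- r2 <= cut
  # Resolve ties at the boundary radius to hit the count exactly.
  extra <- sum(mask) - nVoxels
  if (extra > 0) {
    tieIdx <- which(r2 == cut)
    mask[tieIdx[seq_len(extra)]] <- FALSE
  }
  mask
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an isotropic Gaussian kernel specified by its full
#' width at half maximum, via separable 1D convolutions (zero-padded edges)
#' implemented as banded matrix products along each axis.
#'
#' @param x 3D numeric array.
#' @param fwhmVox FWHM in voxel units (sigma = FWHM / 2.3548).
#' @return Smoothed array of the same dimensions.
#' @export
gaussianSmooth3d <- function(x, fwhmVox) {
  if (fwhmVox <= 0) return(x)
  sigma <- fwhmVox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  convAxis <- function(arr, axis) {
    n <- d[axis]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1, j - half); hi <- min(n, j + half)
      K[lo:hi, j] <- k[(lo:hi) - j + half + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = n)
    m <- crossprod(K, m)
    a <- array(m, dim = d[perm])
    aperm(a, order(perm))
  }
  for (axis in 1:3) x <- convAxis(x, axis)
  x
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("Synthetic atlas: %d regions on %s grid (%g mm voxels), %d mask voxels\n",
              nrow(x$regions), paste(dim(x$labels), collapse = "x"),
              x$voxelSize, sum(x$mask)))
  invisible(x)
}
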