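# Cluster-extent family-wise-error calibration: label permutation on the
# full pipeline and AlphaSim-style Gaussian Monte Carlo, plus residual
# smoothness estimation.

# Smallest cluster size whose null exceedance probability is at most alpha.
extentFromMaxima <- function(maxima, alpha) {
  if (alpha >= 1) return(1L)
  k <- 1L
  while (mean(maxima >= k) > alpha) k <- k + 1L
  k
}

#' Permutation-based cluster-extent threshold
#'
#' Each iteration permutes the trial-type labels independently within every
#' participant (onsets fixed), refits the first-level FIR model, fits the
#' basic (unweighted OLS) second-level maps, thresholds voxelwise, and
#' records the maximum same-sign cluster size pooled over all nine maps (or
#' per map with `perMap = TRUE`). The returned extent is the smallest cluster
#' size whose null exceedance rate is at most `alpha`.
#'
#' @param sessions List of `bold_session`s (one per participant).
#' @param scores Data frame with `arbs`, `bis`.
#' @param nIter Number of permutations (>= 100).
#' @param voxelP Two-tailed voxel threshold.
#' @param alpha Family-wise error target.
#' @param connectivity Cluster connectivity.
#' @param prewhiten Pre-whiten the first-level refits (the second level is
#'   always the basic OLS model here).
#' @param seed Integer seed.
#' @param perMap Calibrate each of the nine maps separately.
#' @return List with `extent`, `maxima` (the null max-cluster distribution),
#'   `alpha`, `voxelP`; with `perMap`, `extent` and `maxima` are per map.
#' @export
permutationClusterThreshold <- function(sessions, scores, nIter = 1000,
                                        voxelP = 0.01, alpha = 0.05,
                                        connectivity = "faces",
                                        prewhiten = TRUE, seed = 1L,
                                        perMap = FALSE) {
  if (nIter < 100) stop("nIter must be >= 100")
  if (nIter * alpha < 5) stop("too few iterations for the requested alpha quantile")
  cds <- contrastDefs()
  mapNames <- as.vector(outer(names(cds), c("mean", "vs_ARBS", "vs_BIS"), paste,
                              sep = ":"))
  maxima <- matrix(0L, nIter, length(mapNames), dimnames = list(NULL, mapNames))
  for (it in seq_len(nIter)) {
    firstLevel <- lapply(seq_along(sessions), function(i) {
      ses <- sessions[[i]]
      pdes <- ses$design
      pdes$trials$trial_type <- withSeed(childSeed(seed, it * 1000L + i),
                                         sample(pdes$trials$trial_type))
      fit <- fitFirstLevel(ses, prewhiten = prewhiten, design = pdes)
      lapply(cds, function(cd) computeContrast(fit, cd))
    })
    sms <- fitGroupMaps(firstLevel, scores, method = "ols")
    j <- 0
    for (cn in names(sms$maps)) for (mn in names(sms$maps[[cn]])) {
      j <- j + 1
      m <- sms$maps[[cn]][[mn]]
      crit <- stats::qt(1 - voxelP / 2, m$df)
      t3d <- toVolume(m$t, sms$voxels, sms$dims)
      maxima[it, j] <- maxClusterSize(t3d, crit, connectivity)
    }
  }
  if (perMap) {
    extent <- apply(maxima, 2, extentFromMaxima, alpha = alpha)
    list(extent = extent, maxima = maxima, alpha = alpha, voxelP = voxelP)
  } else {
    pooled <- apply(maxima, 1, max)
    list(extent = extentFromMaxima(pooled, alpha), maxima = pooled,
         alpha = alpha, voxelP = voxelP)
  }
}

#' Estimate residual spatial smoothness
#'
#' Per-axis FWHM of the effective Gaussian spatial autocorrelation, from the
#' variance of first spatial differences of (normalized) residual volumes:
#' for a Gaussian-smoothed field the lag-1 spatial correlation is
#' `rho = 1 - var(diff) / (2 var)`, giving kernel sigma
#' `sqrt(-1 / (4 log rho))` in voxel units. Estimates are averaged over
#' volumes; the combined FWHM is the geometric mean over axes. Axes whose
#' estimated FWHM falls below the voxel size are flagged sub-voxel.
#'
#' @param res4d 4D residual array (x, y, z, volume), or 3D for one volume.
#' @param mask Logical 3D mask; differences use in-mask neighbour pairs only.
#' @param voxelSize Voxel edge in mm.
#' @return List of class `smoothness_estimate`: `fwhmMm` (per axis),
#'   `fwhmCombinedMm`, `subVoxel` (per-axis flags).
#' @export
estimateSmoothness <- function(res4d, mask, voxelSize = 3) {
  if (length(dim(res4d)) == 3) res4d <- array(res4d, c(dim(res4d), 1))
  d <- dim(res4d)
  if (d[4] < 2 && stats::sd(res4d[, , , 1][mask]) == 0)
    stop("degenerate (constant) residuals")
  rho <- matrix(NA_real_, d[4], 3)
  for (v in seq_len(d[4])) {
    vol <- res4d[, , , v]
    mv <- vol[mask]
    s2 <- stats::var(mv)
    if (s2 == 0) stop("degenerate (constant) residual volume ", v)
    for (axis in 1:3) {
      sel <- function(arr, lo) {
        n <- dim(arr)[axis]
        ix <- lapply(dim(arr), seq_len)
        ix[[axis]] <- if (lo) seq_len(n - 1) else 2:n
        do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
      }
      pairOk <- sel(mask, TRUE) & sel(mask, FALSE)
      dif <- (sel(vol, FALSE) - sel(vol, TRUE))[pairOk]
      rho[v, axis] <- 1 - stats::var(dif) / (2 * s2)
    }
  }
  rhoBar <- colMeans(rho)
  fwhmVox <- vapply(rhoBar, function(r) {
    if (r <= 0) return(0)
    if (r >= 1) return(Inf)
    2 * sqrt(2 * log(2)) * sqrt(-1 / (4 * log(r)))
  }, numeric(1))
  fwhmMm <- fwhmVox * voxelSize
  structure(list(fwhmMm = fwhmMm, fwhmCombinedMm = prod(pmax(fwhmMm, 1e-12))^(1 / 3),
                 subVoxel = fwhmMm < voxelSize),
            class = "smoothness_estimate")
}

#' Monte Carlo (AlphaSim-style) cluster-extent threshold
#'
#' Each iteration fills the mask's bounding grid with Gaussian white noise,
#' smooths it to the target FWHM, renormalizes the in-mask variance,
#' thresholds two-tailed at `voxelP` (normal quantile), and records the
#' maximum same-sign cluster size within the mask. The returned extent is the
#' smallest cluster size whose exceedance rate across iterations is at most
#' `alpha`. With the study's geometry (82,244 3-mm mask voxels, FWHM 12.5 mm,
#' p < 0.01, alpha 0.05) the threshold lands near 106 voxels.
#'
#' @param mask Logical 3D array.
#' @param fwhmMm Residual smoothness FWHM in mm (>= 0).
#' @param voxelSize Voxel edge in mm.
#' @param voxelP Two-tailed voxel threshold.
#' @param alpha Family-wise error target.
#' @param nIter Number of noise simulations.
#' @param connectivity Cluster connectivity.
#' @param seed Integer seed.
#' @return List with `extent`, `maxima`, `alpha`, `voxelP`, `fwhmMm`.
#' @export
montecarloClusterThreshold <- function(mask, fwhmMm, voxelSize = 3,
                                       voxelP = 0.01, alpha = 0.05,
                                       nIter = 1000, connectivity = "faces",
                                       seed = 1L) {
  if (!sum(mask)) stop("mask is empty")
  if (fwhmMm < 0) stop("fwhmMm must be >= 0")
  d <- dim(mask)
  fwhmVox <- fwhmMm / voxelSize
  crit <- stats::qnorm(1 - voxelP / 2)
  maxima <- withSeed(seed, vapply(seq_len(nIter), function(it) {
    z <- array(stats::rnorm(prod(d)), d)
    if (fwhmVox > 0) z <- gaussianSmooth3d(z, fwhmVox)
    zm <- z[mask]
    z[!mask] <- 0
    z <- z / stats::sd(zm)
    maxClusterSize(z, crit, connectivity)
  }, integer(1)))
  list(extent = extentFromMaxima(maxima, alpha), maxima = maxima,
       alpha = alpha, voxelP = voxelP, fwhmMm = fwhmMm)
}
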