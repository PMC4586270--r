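# Second-level inference: the nine group maps (mean and score regressions
# of the three contrasts), voxelwise thresholding, and cluster formation.

#' Fit the nine second-level statistical maps
#'
#' For each first-level contrast (response inhibition, emotional valence,
#' interaction) fits three per-voxel models: mean across participants
#' (design = column of ones), regression on mean-centred ARBS scores, and
#' regression on mean-centred BIS scores (design = ones + centred score).
#' `method = "mixed"` weights participants by the inverse of first-level
#' variance plus a method-of-moments random-effects variance (floored at
#' zero); `method = "ols"` is the basic unweighted fit the permutation
#' calibrator uses. The reported t tests the intercept for the mean model and
#' the slope for the score models; df is analytic (n - rank) unless
#' overridden.
#'
#' @param firstLevel List over participants; each element a named list of
#'   `contrast_map`s (same grid for all participants).
#' @param scores Data frame with `arbs` and `bis` columns (e.g. a `cohort`).
#' @param method "mixed" or "ols".
#' @param dfOverride Optional df to record on every map (the analytic df is
#'   kept alongside).
#' @return List of class `stat_map_set`: `maps[[contrast]][[model]]` each with
#'   `effect`, `se`, `t`, `df`; plus voxel bookkeeping and descriptors.
#' @export
fitGroupMaps <- function(firstLevel, scores, method = c("mixed", "ols"),
                         dfOverride = NULL) {
  method <- match.arg(method)
  n <- length(firstLevel)
  if (n < 3) stop("need at least 3 participants")
  contrasts <- names(firstLevel[[1]])
  proto <- firstLevel[[1]][[1]]
  models <- list(mean = NULL, vs_ARBS = scores$arbs, vs_BIS = scores$bis)
  for (m in c("vs_ARBS", "vs_BIS"))
    if (stats::sd(models[[m]]) == 0)
      stop("constant score vector for model ", m)

  maps <- list()
  for (cn in contrasts) {
    E <- vapply(firstLevel, function(p) p[[cn]]$effect, numeric(length(proto$effect)))
    S <- vapply(firstLevel, function(p) p[[cn]]$se, numeric(length(proto$effect)))
    E <- t(E); S <- t(S)                       # participants x voxels
    maps[[cn]] <- lapply(models, function(x)
      groupRegress(E, S, x, method = method, dfOverride = dfOverride))
  }
  structure(list(maps = maps, voxels = proto$voxels, dims = proto$dims,
                 voxelSize = proto$voxelSize, method = method, n = n),
            class = "stat_map_set")
}

# Per-voxel (weighted) regression of effects on ones [+ centred score],
# vectorized over voxels via weighted-sum closed forms.
groupRegress <- function(E, S, score = NULL, method = "mixed", dfOverride = NULL) {
  n <- nrow(E)
  p <- if (is.null(score)) 1L else 2L
  x <- if (p == 2L) score - mean(score) else NULL
  if (p == 2L && abs(mean(x)) > 1e-10) x <- x - mean(x)

  w0 <- if (method == "mixed") 1 / pmax(S^2, .Machine$double.eps) else
    matrix(1, n, ncol(E))
  fitW <- function(w) {
    if (p == 1L) {
      sw <- colSums(w); sy <- colSums(w * E)
      b <- sy / sw
      list(b = b, varb = 1 / sw, resid = sweep(E, 2, b))
    } else {
      sw <- colSums(w); sx <- colSums(w * x); sxx <- colSums(w * x^2)
      sy <- colSums(w * E); sxy <- colSums(w * x * E)
      det <- sw * sxx - sx^2
      slope <- (sw * sxy - sx * sy) / det
      inter <- (sxx * sy - sx * sxy) / det
      fitted <- outer(rep(1, n), inter) + outer(x, slope)
      list(b = slope, varb = sw / det, resid = E - fitted, inter = inter)
    }
  }
  f0 <- fitW(w0)
  if (method == "mixed") {
    # Method-of-moments between-participant variance (floored at 0).
    Q <- colSums(w0 * f0$resid^2)
    if (p == 1L) {
      cfac <- colSums(w0) - colSums(w0^2) / colSums(w0)
    } else {
      sw <- colSums(w0); sx <- colSums(w0 * x); sxx <- colSums(w0 * x^2)
      det <- sw * sxx - sx^2
      s2w <- colSums(w0^2); s2x <- colSums(w0^2 * x); s2xx <- colSums(w0^2 * x^2)
      trAinvB <- (sxx * s2w - 2 * sx * s2x + sw * s2xx) / det
      cfac <- sw - trAinvB
    }
    tau2 <- pmax(0, (Q - (n - p)) / pmax(cfac, .Machine$double.eps))
    w <- 1 / (S^2 + outer(rep(1, n), tau2))
    f <- fitW(w)
    eff <- f$b; varb <- f$varb
  } else {
    eff <- f0$b
    sigma2 <- colSums(f0$resid^2) / (n - p)
    varb <- f0$varb * sigma2
  }
  df <- n - p
  se <- sqrt(varb)
  list(effect = eff, se = se, t = eff / se,
       df = dfOverride %||% df, dfAnalytic = df)
}

#' @export
print.stat_map_set <- function(x, ...) {
  cat(sprintf("Second-level map set: %d maps (%s x %s), %s fit, n = %d\n",
              sum(lengths(x$maps)), length(x$maps), length(x$maps[[1]]),
              x$method, x$n))
  invisible(x)
}

#' Voxelwise two-tailed threshold
#'
#' Retains voxels whose |t| exceeds the two-tailed critical value of the t
#' distribution at level `p` with `df` degrees of freedom (e.g. p < 0.01 at
#' df = 98 gives |t| > 2.63).
#'
#' @param t Numeric vector or array of t statistics.
#' @param p Two-tailed voxel p threshold in (0, 1).
#' @param df Degrees of freedom (> 0).
#' @return List with `keep` (logical, same shape as `t`) and `criticalT`.
#' @export
thresholdVoxelwise <- function(t, p, df) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (df <= 0) stop("df must be positive")
  crit <- stats::qt(1 - p / 2, df)
  list(keep = abs(t) > crit, criticalT = crit)
}

# Half-space neighbour offsets for the supported connectivities.
connectivityOffsets <- function(connectivity = c("faces", "edges", "corners")) {
  connectivity <- match.arg(connectivity)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity %in% c("edges", "corners"))
    offs <- rbind(offs, c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                  c(0, 1, 1), c(0, 1, -1))
  if (connectivity == "corners")
    offs <- rbind(offs, c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  offs
}

#' Connected components of a binary volume
#'
#' Labels connected components under face (6), face+edge (18) or
#' face+edge+corner (26) connectivity. Components are found by building the
#' neighbour-pair edge list with array shifts and taking graph components.
#'
#' @param bin Logical 3D array.
#' @param connectivity "faces" (default), "edges", or "corners".
#' @return List of class `cluster_set`: `labels` (integer array, 0 outside),
#'   `sizes` (voxel counts, decreasing), `voxels` (list of linear indices per
#'   cluster), `connectivity`.
#' @export
findClusters <- function(bin, connectivity = "faces") {
  d <- dim(bin)
  idx <- which(bin)
  labels <- array(0L, d)
  if (!length(idx))
    return(structure(list(labels = labels, sizes = integer(0), voxels = list(),
                          connectivity = connectivity), class = "cluster_set"))
  nodeId <- array(0L, d)
  nodeId[idx] <- seq_along(idx)
  offs <- connectivityOffsets(connectivity)
  eFrom <- integer(0); eTo <- integer(0)
  rng <- function(n, o) seq(max(1, 1 - o), min(n, n - o))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    r1 <- rng(d[1], o[1]); r2 <- rng(d[2], o[2]); r3 <- rng(d[3], o[3])
    a <- nodeId[r1, r2, r3, drop = FALSE]
    b <- nodeId[r1 + o[1], r2 + o[2], r3 + o[3], drop = FALSE]
    sel <- a > 0L & b > 0L
    eFrom <- c(eFrom, a[sel]); eTo <- c(eTo, b[sel])
  }
  memb <- if (length(eFrom)) {
    g <- igraph::graph_from_edgelist(cbind(eFrom, eTo), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    igraph::components(g)$membership
  } else seq_along(idx)
  sizes <- tabulate(memb)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(seq_along(sizes), ord)
  labels[idx] <- relabel[memb]
  voxels <- split(idx, relabel[memb])
  voxels <- voxels[order(as.integer(names(voxels)))]
  structure(list(labels = labels, sizes = sizes[ord], voxels = unname(voxels),
                 connectivity = connectivity), class = "cluster_set")
}

# Largest same-sign suprathreshold cluster size of a statistic volume
# (positive and negative excursions clustered separately).
maxClusterSize <- function(stat3d, crit, connectivity = "faces") {
  mx <- 0L
  for (sgn in c(1, -1)) {
    cl <- findClusters(sgn * stat3d > crit, connectivity)
    if (length(cl$sizes)) mx <- max(mx, cl$sizes[1])
  }
  mx
}

#' Grow a region around a statistical peak
#'
#' Breadth-first growth from the peak voxel through same-sign suprathreshold
#' face-neighbours, visiting each frontier shell in ascending linear-index
#' order, stopping at `maxSize` voxels or exhaustion. With unlimited size the
#' result equals the peak's connected component.
#'
#' @param t3d 3D t-statistic array.
#' @param peak Voxel index of the peak: length-3 integer or linear index.
#' @param threshold Minimum |t| for membership; the peak must satisfy it.
#' @param maxSize Voxel budget (default unlimited).
#' @param connectivity Neighbourhood definition.
#' @return Integer vector of linear voxel indices (peak first).
#' @export
growRegion <- function(t3d, peak, threshold, maxSize = Inf,
                       connectivity = "faces") {
  d <- dim(t3d)
  if (length(peak) == 3) peak <- peak[1] + (peak[2] - 1) * d[1] +
      (peak[3] - 1) * d[1] * d[2]
  if (abs(t3d[peak]) < threshold) stop("peak is below threshold")
  sgn <- sign(t3d[peak])
  eligible <- array(sgn * t3d >= threshold, d)
  offs <- connectivityOffsets(connectivity)
  offs <- rbind(offs, -offs)
  strides <- c(1, d[1], d[1] * d[2])
  inGrid <- function(ijk) all(ijk >= 1 & ijk <= d)
  visited <- integer(0)
  frontier <- peak
  taken <- array(FALSE, d)
  taken[peak] <- TRUE
  while (length(frontier) && length(visited) < maxSize) {
    frontier <- sort(frontier)
    room <- maxSize - length(visited)
    if (length(frontier) > room) frontier <- frontier[seq_len(room)]
    visited <- c(visited, frontier)
    nxt <- integer(0)
    for (v in frontier) {
      ijk <- arrayInd(v, d)[1, ]
      for (i in seq_len(nrow(offs))) {
        nb <- ijk + offs[i, ]
        if (!inGrid(nb)) next
        li <- sum((nb - 1) * strides) + 1
        if (eligible[li] && !taken[li]) {
          taken[li] <- TRUE
          nxt <- c(nxt, li)
        }
      }
    }
    frontier <- nxt
  }
  visited
}

#' Tabulate suprathreshold clusters of a statistical map
#'
#' Applies the voxelwise threshold and cluster-extent rule to one t-map and
#' reports, per surviving cluster: the peak coordinate (mm), size in voxels,
#' volume in mm^3, and the median p- and t-values across member voxels.
#'
#' @param t Statistic vector over mask voxels.
#' @param df Degrees of freedom for the voxelwise p-values.
#' @param voxels,dims Voxel bookkeeping (as in a `contrast_map`).
#' @param voxelP Two-tailed voxel threshold.
#' @param extent Minimum cluster size in voxels.
#' @param voxelSize Voxel edge in mm.
#' @param connectivity Neighbourhood definition.
#' @return Data frame, one row per surviving cluster, ordered by size.
#' @export
clusterReport <- function(t, df, voxels, dims, voxelP = 0.01, extent = 1,
                          voxelSize = 3, connectivity = "faces") {
  th <- thresholdVoxelwise(t, voxelP, df)
  t3d <- toVolume(t, voxels, dims)
  keep3d <- toVolume(th$keep, voxels, dims, fill = FALSE)
  rows <- list()
  for (sgn in c(1, -1)) {
    cl <- findClusters(keep3d & (sgn * t3d > 0), connectivity)
    for (k in seq_along(cl$sizes)) {
      if (cl$sizes[k] < extent) next
      vox <- cl$voxels[[k]]
      tv <- t3d[vox]
      pv <- 2 * stats::pt(-abs(tv), df)
      pk <- vox[which.max(abs(tv))]
      ijk <- arrayInd(pk, dims)[1, ]
      rows[[length(rows) + 1]] <- data.frame(
        sign = if (sgn > 0) "pos" else "neg",
        peak_x_mm = (ijk[1] - 1) * voxelSize,
        peak_y_mm = (ijk[2] - 1) * voxelSize,
        peak_z_mm = (ijk[3] - 1) * voxelSize,
        size_vox = cl$sizes[k],
        volume_mm3 = cl$sizes[k] * voxelSize^3,
        median_p = stats::median(pv),
        median_t = stats::median(tv),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sign = character(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      size_vox = integer(0), volume_mm3 = numeric(0),
                      median_p = numeric(0), median_t = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$size_vox), , drop = FALSE]
}
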