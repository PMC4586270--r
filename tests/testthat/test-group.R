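# Second-level maps, thresholding, clustering, calibration, smoothness, QA.

test_that("voxelwise threshold reproduces t quantiles and limits", {
  th <- thresholdVoxelwise(c(2.5, 2.7, -3), p = 0.01, df = 98)
  expect_equal(th$criticalT, 2.63, tolerance = 0.005)
  expect_equal(th$keep, c(FALSE, TRUE, TRUE))
  expect_lt(thresholdVoxelwise(0, p = 0.999, df = 10)$criticalT, 0.01)
  expect_equal(thresholdVoxelwise(0, p = 0.01, df = 1e7)$criticalT,
               qnorm(1 - 0.005), tolerance = 1e-3)
  expect_error(thresholdVoxelwise(0, p = 1.2, df = 10), "0, 1")
  expect_error(thresholdVoxelwise(0, p = 0.01, df = 0), "positive")
})

test_that("cluster formation follows connectivity semantics and a flood-fill oracle", {
  b <- array(FALSE, c(5, 5, 3))
  b[2, 2, 2] <- TRUE
  cl <- findClusters(b)
  expect_equal(cl$sizes, 1L)

  # Two blobs touching only at a corner.
  b2 <- array(FALSE, c(6, 6, 3))
  b2[2:3, 2:3, 2] <- TRUE
  b2[4:5, 4:5, 2] <- TRUE
  expect_length(findClusters(b2, "faces")$sizes, 2)
  expect_length(findClusters(b2, "corners")$sizes, 1)

  set.seed(12)
  for (i in 1:8) {
    rb <- array(runif(6 * 6 * 5) < 0.35, c(6, 6, 5))
    expect_equal(sort(findClusters(rb, "faces")$sizes, decreasing = TRUE),
                 oracleClusterSizes(rb))
  }
})

test_that("region growing is budgeted, deterministic, and flood-fill-equivalent", {
  t3d <- array(0, c(7, 7, 4))
  t3d[4, 4, 2] <- 5
  expect_equal(growRegion(t3d, c(4, 4, 2), threshold = 2), which(t3d == 5))

  set.seed(13)
  t3d2 <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  t3d2[3:6, 3:6, 2:4] <- 5
  peak <- c(4, 4, 3)
  grown <- growRegion(t3d2, peak, threshold = 3)
  comp <- findClusters(t3d2 > 3, "faces")
  peakLin <- peak[1] + (peak[2] - 1) * 8 + (peak[3] - 1) * 64
  inComp <- comp$voxels[[comp$labels[peakLin]]]
  expect_setequal(grown, inComp)
  g10 <- growRegion(t3d2, peak, threshold = 3, maxSize = 10)
  expect_length(g10, 10)
  expect_true(all(g10 %in% inComp))
  expect_error(growRegion(t3d2, c(1, 1, 1), threshold = 99), "below threshold")
})

test_that("group maps match a closed-form one-sample oracle and count nine", {
  atl <- miniAtlas()
  nv <- 50
  mkMap <- function(e, s) structure(
    list(effect = e, se = s, t = e / s, df = 100, name = "c",
         voxels = seq_len(nv), dims = c(10, 10, 6), voxelSize = 3),
    class = "contrast_map")
  n <- 9
  coh <- miniCohort(9)
  # Identical effects, equal first-level SEs: tau2 = 0 and the mean-map t
  # equals the one-sample closed form v / (s / sqrt(n)).
  fl <- lapply(seq_len(n), function(i)
    list(a = mkMap(rep(2, nv), rep(0.5, nv)),
         b = mkMap(rep(1, nv), rep(0.5, nv)),
         c = mkMap(rep(0, nv), rep(0.5, nv))))
  sms <- fitGroupMaps(fl, coh)
  expect_equal(sum(lengths(sms$maps)), 9)
  expect_equal(unname(sms$maps$a$mean$t),
               rep(2 / (0.5 / sqrt(n)), nv), tolerance = 1e-10)
  expect_equal(sms$maps$a$mean$df, n - 1)
  expect_equal(sms$maps$a$vs_ARBS$df, n - 2)
  expect_error(fitGroupMaps(fl, transform(coh, arbs = 10)), "constant score")
})

test_that("score-regression maps keep their nominal false-positive rate under the null", {
  set.seed(14)
  n <- 21; nv <- 4000
  coh <- generateCohort(n = 21, nHigh = 10, seed = 15)
  E <- matrix(rnorm(n * nv), n, nv)
  S <- matrix(runif(n * nv, 0.8, 1.2), n, nv)
  mkMap <- function(i) structure(
    list(effect = E[i, ], se = S[i, ], t = E[i, ] / S[i, ], df = 100,
         name = "c", voxels = seq_len(nv), dims = c(20, 20, 10), voxelSize = 3),
    class = "contrast_map")
  fl <- lapply(seq_len(n), function(i) list(c1 = mkMap(i)))
  sms <- fitGroupMaps(fl, coh)
  m <- sms$maps$c1$vs_ARBS
  rate <- mean(abs(m$t) > qt(1 - 0.025, m$df))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("smoothness estimation recovers a known kernel and is scale-invariant", {
  set.seed(16)
  d <- c(30, 30, 20)
  mask <- array(TRUE, d)
  z <- array(rnorm(prod(d)), d)
  zs <- gaussianSmooth3d(z, 9 / 3)       # 9-mm kernel at 3-mm voxels
  est <- estimateSmoothness(zs, mask, voxelSize = 3)
  expect_equal(est$fwhmCombinedMm, 9, tolerance = 0.1 * 9)
  est10 <- estimateSmoothness(zs * 10, mask, voxelSize = 3)
  expect_equal(est10$fwhmMm, est$fwhmMm)
  raw <- estimateSmoothness(z, mask, voxelSize = 3)
  expect_true(all(raw$subVoxel))
  expect_error(estimateSmoothness(array(1, c(d, 1)), mask), "degenerate")
})

test_that("Monte Carlo extent threshold is monotone and matches a brute-force oracle", {
  mask <- ellipsoidMaskForTest <- array(TRUE, c(4, 4, 3))
  expect_equal(montecarloClusterThreshold(mask, 0, nIter = 200, alpha = 1,
                                          seed = 1)$extent, 1)

  # fwhm = 0 on a tiny mask: compare against an independent simulation using
  # the test-side flood fill.
  set.seed(17)
  crit <- qnorm(1 - 0.01 / 2)
  oracleMax <- replicate(3000, {
    z <- array(rnorm(48), c(4, 4, 3))
    mx <- 0
    for (sgn in c(1, -1)) {
      s <- oracleClusterSizes(sgn * z > crit)
      if (length(s)) mx <- max(mx, s[1])
    }
    mx
  })
  k <- 1
  while (mean(oracleMax >= k) > 0.05) k <- k + 1
  got <- montecarloClusterThreshold(mask, 0, voxelP = 0.01, alpha = 0.05,
                                    nIter = 3000, seed = 18)
  expect_equal(got$extent, k)

  # Monotone: non-decreasing in FWHM, non-increasing in voxel p.
  m2 <- array(TRUE, c(12, 12, 8))
  e1 <- montecarloClusterThreshold(m2, 0, nIter = 300, seed = 19)$extent
  e2 <- montecarloClusterThreshold(m2, 6, nIter = 300, seed = 19)$extent
  e3 <- montecarloClusterThreshold(m2, 12, nIter = 300, seed = 19)$extent
  expect_true(e1 <= e2 && e2 <= e3)
  p1 <- montecarloClusterThreshold(m2, 6, voxelP = 0.05, nIter = 300, seed = 20)$extent
  expect_gte(p1, e2 * 0 + 1)
  p2 <- montecarloClusterThreshold(m2, 6, voxelP = 0.001, nIter = 300, seed = 20)$extent
  expect_lte(p2, p1)
})

test_that("permutation and Monte Carlo extents agree on matched stationary null data", {
  atl <- miniAtlas()
  coh <- miniCohort(6)
  eff <- effectSpec(4, amplitudes = 0)
  ns <- noiseSpec(ar = 0, sd = 1, fwhmMm = 6)
  sessions <- lapply(1:6, function(i)
    generateBoldSession(coh[i, ], miniDesign(), eff, ns, atl, seed = 50 + i))
  perm <- permutationClusterThreshold(sessions, coh, nIter = 120,
                                      prewhiten = FALSE, seed = 21)
  # Smoothness of the first participant's residuals feeds the Monte Carlo.
  fit <- fitFirstLevel(sessions[[1]], prewhiten = FALSE)
  res4d <- array(0, c(fit$dims, 6))
  for (k in 1:6) res4d[, , , k] <- toVolume(fit$residuals[k * 20, ], fit$voxels, fit$dims)
  sm <- estimateSmoothness(res4d, sessions[[1]]$mask, atl$voxelSize)
  mc <- montecarloClusterThreshold(sessions[[1]]$mask, sm$fwhmCombinedMm,
                                   voxelSize = atl$voxelSize, nIter = 400,
                                   seed = 22)
  expect_lt(abs(perm$extent - mc$extent) / max(mc$extent, 1), 0.25 + 1e-9)
})

test_that("timecourse QA passes canonical responses and fails inverted ones", {
  ses <- noiselessSession()
  vox <- which(ses$atlas$labels == 2)[1:5]
  qa <- qaClusterTimecourses(vox, list(ses))
  expect_gt(qa$score, 0.9)
  expect_equal(qa$verdict, "pass")
  expect_equal(dim(qa$timecourses), c(7, 4))

  inv <- ses
  inv$data <- 200 - inv$data     # flip responses around baseline
  qaInv <- qaClusterTimecourses(vox, list(inv))
  expect_lt(qaInv$score, -0.9)
  expect_equal(qaInv$verdict, "fail")

  flat <- ses
  flat$data[] <- 100
  qaFlat <- qaClusterTimecourses(vox, list(flat))
  expect_equal(qaFlat$verdict, "indeterminate")
  expect_true(is.na(qaFlat$score))
})
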