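# Correlation patterns, the similarity statistic, and the split test.

test_that("region means equal hand computation and uniform maps are flat", {
  atl <- miniAtlas()
  nv <- length(atl$labels)
  mkMap <- function(vals) structure(
    list(effect = vals[which(atl$mask)], se = 1, t = 1, df = 10, name = "c",
         voxels = which(atl$mask), dims = dim(atl$labels), voxelSize = 3),
    class = "contrast_map")
  uni <- array(7, dim(atl$labels))
  fl <- list(list(c1 = mkMap(uni)), list(c1 = mkMap(uni * 2)))
  v <- regionContrastValues(fl, atl)
  expect_equal(unname(v[1, ]), rep(7, 4))
  expect_equal(unname(v[2, ]), rep(14, 4))

  set.seed(23)
  vol <- array(rnorm(nv), dim(atl$labels))
  v2 <- regionContrastValues(list(list(c1 = mkMap(vol))), atl)
  for (k in 1:4)
    expect_equal(unname(v2[1, k]), mean(vol[atl$labels == k]))
})

test_that("correlation patterns match the textbook Pearson formula", {
  set.seed(24)
  vals <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(NULL, paste0("c", 1:6)))
  scores <- rnorm(10)
  pat <- computePattern(vals, scores, "ARBS")
  oracle <- apply(vals, 2, function(col) {
    sx <- col - mean(col); sy <- scores - mean(scores)
    sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  })
  expect_equal(as.numeric(pat), unname(oracle), tolerance = 1e-12)
  vals[, 2] <- scores
  expect_equal(as.numeric(computePattern(vals, scores)[2]), 1)
  expect_error(computePattern(vals, rep(1, 10)), "constant scores")
  vals[, 3] <- 5
  expect_error(computePattern(vals, scores), "constant contrast-value")
  # Pattern entries are invariant to affine rescaling of the values.
  vals[, 3] <- rnorm(10)
  expect_equal(as.numeric(computePattern(vals * 3 + 2, scores)),
               as.numeric(computePattern(vals, scores)))
})

test_that("similarity statistic follows its defining identities", {
  set.seed(25)
  a <- runif(78, -1, 1)
  expect_equal(patternSimilarity(a, a), 1)
  expect_equal(patternSimilarity(rep(1, 78), rep(0, 78)), 0)
  b <- a
  b[5] <- b[5] - 2
  expect_equal(patternSimilarity(a, b), 1 - 4 / 78)
  expect_equal(patternSimilarity(a, b), patternSimilarity(b, a))
  expect_equal(patternSimilarity(rep(1, 78), rep(-1, 78)), -3)
  # Monotone: any single growing difference decreases S.
  s <- sapply(seq(0, 2, 0.5), function(d) {
    bb <- a; bb[1] <- bb[1] + d; patternSimilarity(a, bb)
  })
  expect_true(all(diff(s) < 0))
  # Literal Euclidean variant for comparison.
  expect_equal(patternSimilarity(rep(1, 78), rep(0, 78), form = "euclidean"),
               1 - sqrt(78) / 78)
  expect_error(patternSimilarity(1:3, 1:4), "length")
})

test_that("split test is exact for deterministic score-coupled data", {
  coh <- generateCohort(n = 12, nHigh = 6, seed = 26)
  # Every column an exact linear function of the (shared) score.
  vals <- outer(as.numeric(coh$arbs), seq_len(8)) +
    matrix(rep(1:8, each = 12), 12, 8)
  colnames(vals) <- paste0("c", 1:8)
  res <- splitSimilarityTest(vals, coh$arbs, coh$arbs, coh$risk_class,
                             nIter = 200, seed = 27)
  expect_equal(res$meanS, 1)
  expect_equal(res$propBelow, 0)
  expect_equal(res$propAbove, 1)
})

test_that("null split test matches an independent resampling oracle", {
  set.seed(28)
  n <- 21
  coh <- generateCohort(n = n, nHigh = 10, seed = 29)
  vals <- matrix(rnorm(n * 78), n, 78, dimnames = list(NULL, paste0("c", 1:78)))
  res <- splitSimilarityTest(vals, coh$arbs, coh$bis, coh$risk_class,
                             nIter = 1500, seed = 30)
  # Oracle: independently coded stratified split loop.
  strata <- split(seq_len(n), coh$risk_class)
  S <- replicate(1500, {
    g1 <- integer(0); g2 <- integer(0)
    for (st in strata) {
      st <- sample(st)
      k1 <- floor(length(st) / 2) + (length(st) %% 2) * rbinom(1, 1, 0.5)
      g1 <- c(g1, st[seq_len(k1)]); g2 <- c(g2, st[-seq_len(k1)])
    }
    pa <- cor(coh$arbs[g1], vals[g1, ])
    pb <- cor(coh$bis[g2], vals[g2, ])
    1 - sum((pa - pb)^2) / 78
  })
  expect_equal(res$meanS, mean(S), tolerance = 4 * sd(S) / sqrt(1500))
  expect_equal(res$sdS, sd(S), tolerance = 0.15 * sd(S))
  # Group sizes within one of each other is implied by mean reproducibility;
  # stratum-too-small input is rejected.
  tiny <- coh[c(1, which(coh$risk_class != coh$risk_class[1])[1]), ]
  expect_error(splitSimilarityTest(vals[1:2, ], tiny$arbs, tiny$bis,
                                   tiny$risk_class, nIter = 10, seed = 1),
               "stratum too small")
})

test_that("split test is reproducible under a fixed seed", {
  coh <- generateCohort(n = 10, nHigh = 5, seed = 31)
  vals <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(NULL, paste0("c", 1:12)))
  r1 <- splitSimilarityTest(vals, coh$arbs, coh$bis, coh$risk_class,
                            nIter = 100, seed = 5)
  r2 <- splitSimilarityTest(vals, coh$arbs, coh$bis, coh$risk_class,
                            nIter = 100, seed = 5)
  expect_identical(r1$S, r2$S)
})
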