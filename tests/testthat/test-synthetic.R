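# Synthetic cohort, HRF, atlas fixture, and BOLD generation.

test_that("cohort reproduces the study's score structure", {
  coh <- generateCohort(n = 21, nHigh = 10, targetCorr = 0.78, seed = 1)
  expect_equal(nrow(coh), 21)
  expect_equal(sum(coh$risk_class == "high"), 10)
  expect_true(all(coh$arbs[coh$risk_class == "high"] >= 17))
  expect_true(all(coh$arbs[coh$risk_class != "high"] <= 13))
  expect_true(all(coh$arbs >= 9 & coh$arbs <= 30))
  expect_true(all(coh$bis >= 30 & coh$bis <= 120))
  # Subscales sum to totals; risk classes consistent with cutoffs.
  subCols <- grep("^bis_", names(coh), value = TRUE)
  expect_equal(unname(rowSums(coh[, subCols])), as.numeric(coh$bis))
  expect_equal(classifyRisk(coh$arbs), coh$risk_class)
  expect_equal(attr(coh, "achievedCorr"), 0.78, tolerance = 0.2)
})

test_that("cohort generation is deterministic and respects a null correlation", {
  expect_identical(generateCohort(seed = 5), generateCohort(seed = 5))
  big <- generateCohort(n = 2000, nHigh = 1000, targetCorr = 0, seed = 6)
  expect_lt(abs(attr(big, "achievedCorr")), 0.05)
  expect_error(generateCohort(n = 5, nHigh = 9), "nHigh")
})

test_that("double-gamma HRF has the canonical shape", {
  expect_equal(hrf(0), 0)
  grid <- seq(0, 20, by = 0.01)
  # Grid-search oracle on the raw difference-of-gammas densities.
  raw <- dgamma(grid, shape = 6, scale = 1) - dgamma(grid, shape = 16, scale = 1) / 6
  expect_equal(grid[which.max(hrf(grid))], grid[which.max(raw)])
  expect_equal(grid[which.max(hrf(grid))], 5, tolerance = 0.1)
  expect_equal(max(hrf(grid)), 1)
  expect_lt(abs(hrf(30)), 0.01)
  expect_error(hrf(-1), ">= 0")
  expect_error(hrf(1, peakDelay = -2), "positive")
})

test_that("atlas fixtures partition the mask into contiguous nonempty regions", {
  one <- generateAtlasFixture(c(8, 8, 5), 1, seed = 1)
  expect_equal(sum(one$labels > 0), sum(one$mask))

  atl <- generateAtlasFixture(c(20, 20, 12), 26, seed = 2)
  expect_equal(nrow(atl$regions), 26)
  expect_true(all(atl$regions$nvox > 0))
  # Labels live inside the mask and counts match the region table.
  expect_true(all(atl$mask[atl$labels > 0]))
  counted <- as.integer(table(factor(atl$labels[atl$labels > 0], levels = 1:26)))
  expect_equal(counted, atl$regions$nvox)
  # Contiguity: each region is one connected component.
  for (k in c(1, 7, 26)) {
    sizes <- oracleClusterSizes(atl$labels == k)
    expect_length(sizes, 1)
  }
  expect_error(generateAtlasFixture(c(4, 4, 3), 500), "too many regions")
})

test_that("zero-noise, zero-effect sessions are constant at baseline", {
  eff <- effectSpec(4, amplitudes = 0)
  ses <- generateBoldSession(miniCohort()[1, ], miniDesign(), eff,
                             noiseSpec(sd = 0), miniAtlas(), seed = 3)
  expect_true(all(ses$data == 100))
  expect_equal(dim(ses$data)[4], 165)
})

test_that("pure-noise timecourses carry the programmed AR structure", {
  eff <- effectSpec(4, amplitudes = 0, baseline = 0)
  ns <- noiseSpec(ar = 0.5, sd = 1, fwhmMm = 0)
  ses <- generateBoldSession(miniCohort()[1, ], miniDesign(), eff, ns,
                             miniAtlas(), seed = 4)
  flat <- matrix(ses$data, prod(dim(ses$data)[1:3]), dim(ses$data)[4])
  vox <- which(ses$mask)
  rho <- sapply(c(1, 2, 3), function(k) {
    x <- flat[vox, 1:(165 - k)]; y <- flat[vox, (k + 1):165]
    sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  })
  expect_equal(rho, 0.5^(1:3), tolerance = 0.05)
  expect_error(noiseSpec(ar = 1.2), "non-stationary")
})

test_that("programmed amplitudes are recovered by the GLM at zero noise", {
  fit <- noiselessFit()
  cm <- computeContrast(fit, contrastDefs()$response_inhibition)
  # Programmed contrast of amplitudes: (2 + 2) - (1 + 1) = 2, scaled by the
  # closed-form FIR unit response.
  expect_equal(mean(cm$effect), 2 * firUnitResponse(), tolerance = 0.01)
  expect_lt(max(abs(cm$effect / (2 * firUnitResponse()) - 1)), 0.01)
})
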