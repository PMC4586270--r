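# First-level GLM: design matrix structure, autocorrelation estimation,
# pre-whitened fitting, contrasts.

test_that("FIR design matrix has the documented column structure", {
  dm <- buildDesignMatrix(miniDesign(), nuisance = NULL)
  # 4 types x 7 FIR timepoints, no error set.
  expect_length(dm$taskCols, 28)
  # Per-run nuisance block: offset, drift, cosine, sine.
  expect_equal(ncol(dm$X), 28 + 4)
  expect_false(anyDuplicated(dm$colnames) > 0)
  expect_true(all(dm$X[, dm$taskCols] %in% c(0, 1)))

  # Error trials get their own collapsed FIR set and leave their type's set.
  err <- miniDesign()$trials[3:5, c("run", "onset_s")]
  dme <- buildDesignMatrix(miniDesign(), errorOnsets = err)
  expect_length(dme$taskCols, 35)
  expect_equal(sum(dme$X[, grep("fir\\[error\\]\\[1\\]", dme$colnames)]), 3)
  nErrByType <- table(miniDesign()$trials$trial_type[3:5])
  for (tt in names(nErrByType))
    expect_equal(sum(dme$X[, sprintf("fir[%s][1]", tt)]),
                 sum(dm$X[, sprintf("fir[%s][1]", tt)]) - nErrByType[[tt]])

  bad <- miniDesign()
  bad$trials$onset_s[4] <- bad$trials$onset_s[4] + 1
  expect_error(buildDesignMatrix(bad), "not aligned")
})

test_that("slice-pooled autocorrelation is null for white noise and follows AR(1)", {
  set.seed(8)
  n <- 160; nv <- 400
  runIdx <- rep(1:2, each = n / 2)
  white <- matrix(rnorm(n * nv), n, nv)
  slice <- rep(1:2, each = nv / 2)
  rho <- estimateAutocorrelation(white, slice, runIdx, maxLag = 10)
  expect_equal(dim(rho), c(10, 2))
  expect_true(all(abs(rho) < 3 / sqrt(n / 2 * nv / 2)))

  ar1 <- apply(matrix(rnorm(n * nv), n, nv), 2, function(e)
    as.numeric(filter(e, 0.5, method = "recursive")))
  rho1 <- estimateAutocorrelation(ar1, rep(1, nv), runIdx, maxLag = 10)
  expect_equal(rho1[1:4, 1], 0.5^(1:4), tolerance = 0.08)
  expect_error(estimateAutocorrelation(white[1:8, ], slice, rep(1, 8), 10),
               "fewer volumes")
})

test_that("pre-whitened fit reduces to OLS with no AR and equals a dense GLS oracle", {
  dm <- buildDesignMatrix(miniDesign())
  n <- nrow(dm$X)
  set.seed(9)
  Y <- matrix(rnorm(n * 30), n, 30)
  slice <- rep(1L, 30)

  fit0 <- prewhitenAndFit(Y, dm, slice, ar = NULL)
  bOls <- qr.solve(dm$X, Y)
  expect_equal(unname(fit0$betas), unname(bOls), tolerance = 1e-8)

  # Dense GLS oracle under a known AR(1) correlation: feed the theoretical
  # ACF so Levinson-Durbin recovers phi = 0.6 exactly, then compare against
  # the explicit (X' V^-1 X)^-1 X' V^-1 y solution.
  phi <- 0.6
  ar <- matrix(phi^(1:10), 10, 1, dimnames = list(NULL, "1"))
  fitG <- prewhitenAndFit(Y, dm, slice, ar = ar)
  V <- toeplitz(phi^(0:(n - 1)))
  Vi <- solve(V)
  bGls <- solve(t(dm$X) %*% Vi %*% dm$X, t(dm$X) %*% Vi %*% Y)
  expect_lt(max(abs(fitG$betas - bGls)) / max(abs(bGls)), 1e-6)
})

test_that("noiseless data reproduce their generating betas exactly", {
  dm <- buildDesignMatrix(miniDesign())
  set.seed(10)
  beta0 <- matrix(rnorm(ncol(dm$X) * 5), ncol(dm$X), 5)
  Y <- dm$X %*% beta0
  fit <- prewhitenAndFit(Y, dm, rep(1L, 5), ar = NULL)
  expect_equal(unname(fit$betas), unname(beta0), tolerance = 1e-9)
})

test_that("contrasts use the documented weights, scale linearly, and vanish on symmetry", {
  cds <- contrastDefs()
  expect_equal(cds$response_inhibition$weights,
               c("neutral-go" = -1, "aversive-go" = -1,
                 "neutral-nogo" = 1, "aversive-nogo" = 1))
  fit <- noiselessFit()
  cm <- computeContrast(fit, cds$response_inhibition)
  # Linearity: scaling all betas scales the effect.
  fit2 <- fit
  fit2$betas <- fit$betas * 3
  cm2 <- computeContrast(fit2, cds$response_inhibition)
  expect_equal(cm2$effect, 3 * cm$effect)
  # Symmetric betas across types give identically zero contrasts.
  fit3 <- fit
  for (tt in trialTypes())
    for (l in 1:7)
      fit3$betas[sprintf("fir[%s][%d]", tt, l), ] <- l
  for (cd in cds)
    expect_equal(max(abs(computeContrast(fit3, cd)$effect)), 0)
})

test_that("voxelwise null false-positive rate is nominal through the full first level", {
  eff <- effectSpec(4, amplitudes = 0)
  ns <- noiseSpec(ar = 0.3, sd = 1, fwhmMm = 0)   # independent voxels
  rates <- sapply(1:2, function(k) {
    ses <- generateBoldSession(miniCohort()[1, ], miniDesign(), eff, ns,
                               miniAtlas(), seed = 40 + k)
    fit <- fitFirstLevel(ses, includeMotion = FALSE)
    cm <- computeContrast(fit, contrastDefs()$response_inhibition)
    crit <- qt(1 - 0.01 / 2, cm$df)
    mean(abs(cm$t) > crit)
  })
  nTot <- 2 * sum(miniAtlas()$mask)
  ci <- qbinom(c(0.005, 0.995), nTot, 0.01) / nTot
  expect_gte(mean(rates), ci[1])
  expect_lte(mean(rates), ci[2])
})
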