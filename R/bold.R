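# Synthetic 4D BOLD sessions: double-gamma responses with per-region
# amplitudes (optionally modulated by participant scores), AR-correlated
# spatially smooth noise, drift and motion-like nuisance signals.

#' Ground-truth effect specification
#'
#' Programs the region-by-trial-type response amplitudes of a synthetic
#' session plus per-region linear modulation of those amplitudes by
#' mean-centred ARBS and BIS scores (the generator's ground truth for
#' recovery tests).
#'
#' @param amplitudes Regions x 4 matrix of response amplitudes (BOLD units;
#'   columns in [trialTypes()] order), or a single number recycled.
#' @param arbsSlopes,bisSlopes Regions x 4 matrices (or scalars) of amplitude
#'   change per mean-centred score unit.
#' @param scoreCenters Centering constants for the modulation (study means).
#' @param baseline Baseline signal level.
#' @param nRegions Number of atlas regions the spec addresses.
#' @return List of class `effect_spec`.
#' @export
effectSpec <- function(nRegions, amplitudes = 0, arbsSlopes = 0, bisSlopes = 0,
                       scoreCenters = c(arbs = 15.6, bis = 67.6), baseline = 100) {
  expand <- function(x) {
    m <- matrix(x, nRegions, 4, dimnames = list(NULL, trialTypes()))
    if (!all(is.finite(m))) stop("amplitudes must be finite")
    m
  }
  structure(list(amplitudes = expand(amplitudes), arbsSlopes = expand(arbsSlopes),
                 bisSlopes = expand(bisSlopes), scoreCenters = scoreCenters,
                 baseline = baseline, nRegions = nRegions),
            class = "effect_spec")
}

#' Noise specification for synthetic BOLD data
#'
#' @param ar Numeric AR coefficients (lags 1..p, p <= 10); the AR polynomial
#'   must be stationary.
#' @param sd Innovation standard deviation.
#' @param fwhmMm Spatial smoothing FWHM of the noise field, in mm.
#' @param driftAmp Amplitude of per-run low-frequency drift.
#' @param motionAmp Amplitude of motion-like nuisance components.
#' @return List of class `noise_spec`.
#' @export
noiseSpec <- function(ar = numeric(0), sd = 1, fwhmMm = 6,
                      driftAmp = 0, motionAmp = 0) {
  if (length(ar) > 10) stop("at most 10 AR lags supported")
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop("AR coefficients are non-stationary")
  if (fwhmMm < 0 || sd < 0) stop("sd and fwhmMm must be >= 0")
  structure(list(ar = ar, sd = sd, fwhmMm = fwhmMm,
                 driftAmp = driftAmp, motionAmp = motionAmp),
            class = "noise_spec")
}

#' Per-unit-amplitude FIR contrast response
#'
#' The closed-form mean double-gamma response over the FIR timepoints used by
#' the contrasts (default 3rd and 4th, i.e. 4 and 6 s after trial onset): a
#' programmed amplitude `a` yields a first-level contrast-map effect of
#' `a * firUnitResponse()` per unit contrast weight.
#'
#' @param timepoints FIR timepoints (1-based; timepoint k is 2(k-1) s).
#' @param tr Volume time in seconds.
#' @param combine "mean" (default) or "sum" over timepoints.
#' @return Scalar unit response.
#' @export
firUnitResponse <- function(timepoints = c(3, 4), tr = 2, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  v <- hrf((timepoints - 1) * tr)
  if (combine == "mean") mean(v) else sum(v)
}

#' Generate a synthetic 4D BOLD session
#'
#' Simulates `length(unique(design$trials$run))` runs on the atlas grid at
#' TR 2 s. Each in-mask voxel carries `baseline + sum over trials of
#' amplitude(region, type, scores) * hrf(t - onset)`, where the amplitude is
#' the programmed region/type amplitude plus the participant's mean-centred
#' ARBS and BIS scores times the programmed slopes. Noise is white Gaussian
#' innovation smoothed spatially (variance renormalized), recursively
#' AR-filtered over time within run, plus drift (linear + one-cycle sinusoid)
#' and motion-like nuisance timecourses with random spatial loadings. The
#' first `leadInVolumes` volumes of each run are generated and flagged for
#' discard, exercising the spin-saturation discard rule.
#'
#' @param participant One-row slice of a `cohort` (needs `arbs`, `bis`).
#' @param design A `session_design`.
#' @param effects An `effect_spec` with `nRegions` matching the atlas.
#' @param noise A `noise_spec`.
#' @param atlas An `atlas` (labels + mask + voxel size).
#' @param seed Integer seed.
#' @param tr Volume time, seconds.
#' @param leadInVolumes Lead-in volumes per run flagged as discarded.
#' @return List of class `bold_session`: `data` (x,y,z,t array over all runs),
#'   `mask`, `atlas`, `design`, `tr`, `leadInVolumes`, `runLength` (volumes
#'   per run), `nuisance` (per-run data frames of motion-like regressors),
#'   `truth` (effects, noise, seed, participant scores).
#' @export
generateBoldSession <- function(participant, design, effects, noise, atlas,
                                seed = 1L, tr = 2, leadInVolumes = 6) {
  stopifnot(inherits(design, "session_design"), inherits(effects, "effect_spec"),
            inherits(noise, "noise_spec"), inherits(atlas, "atlas"))
  if (effects$nRegions != nrow(atlas$regions))
    stop("effect spec regions (", effects$nRegions, ") do not match atlas (",
         nrow(atlas$regions), ")")
  dims <- dim(atlas$labels)
  runs <- sort(unique(design$trials$run))
  nVolRun <- as.integer(round(design$runDuration / tr))
  nVox <- prod(dims)
  types <- trialTypes()

  # Participant-specific amplitude per (region, type).
  amp <- effects$amplitudes +
    effects$arbsSlopes * (participant$arbs - effects$scoreCenters["arbs"]) +
    effects$bisSlopes * (participant$bis - effects$scoreCenters["bis"])

  # Per-voxel amplitude rows (0 outside labeled regions).
  lab <- as.integer(atlas$labels)
  ampVox <- matrix(0, nVox, 4)
  inReg <- lab > 0
  ampVox[inReg, ] <- amp[lab[inReg], ]

  fwhmVox <- noise$fwhmMm / atlas$voxelSize
  data <- array(0, c(dims, nVolRun * length(runs)))
  nuisance <- vector("list", length(runs))

  withSeed(seed, {
    for (r in seq_along(runs)) {
      tgrid <- (seq_len(nVolRun) - 1) * tr
      # Per-type convolved stick functions.
      S <- matrix(0, nVolRun, 4, dimnames = list(NULL, types))
      trRun <- design$trials[design$trials$run == runs[r], ]
      for (i in seq_len(nrow(trRun))) {
        dtv <- tgrid - trRun$onset_s[i]
        ok <- dtv >= 0
        S[ok, trRun$trial_type[i]] <- S[ok, trRun$trial_type[i]] + hrf(dtv[ok])
      }
      signal <- tcrossprod(S, ampVox)            # nVol x nVox
      signal <- signal + effects$baseline

      if (noise$sd > 0) {
        eps <- array(stats::rnorm(nVox * nVolRun), c(dims, nVolRun))
        if (fwhmVox > 0) {
          for (v in seq_len(nVolRun)) {
            sm <- gaussianSmooth3d(eps[, , , v], fwhmVox)
            eps[, , , v] <- sm / stats::sd(sm)   # variance renormalization
          }
        }
        em <- t(matrix(eps, nVox, nVolRun)) * noise$sd
        if (length(noise$ar))
          em <- stats::filter(em, noise$ar, method = "recursive")
        signal <- signal + em
      }

      if (noise$driftAmp > 0) {
        drift <- noise$driftAmp *
          (stats::rnorm(1) * scale(tgrid) +
             stats::rnorm(1) * sin(2 * pi * tgrid / (2 * design$runDuration)) +
             stats::rnorm(1) * cos(2 * pi * tgrid / (2 * design$runDuration)))
        signal <- signal + as.numeric(drift) %o% stats::rnorm(nVox, 1, 0.2)
      }

      mot <- matrix(0, nVolRun, 6,
                    dimnames = list(NULL, paste0("motion", 1:6)))
      if (noise$motionAmp > 0) {
        for (j in 1:6)
          mot[, j] <- stats::filter(stats::rnorm(nVolRun), rep(1 / 8, 8),
                                    sides = 1, circular = TRUE)
        signal <- signal +
          (mot %*% matrix(stats::rnorm(6 * nVox, 0, noise$motionAmp), 6, nVox))
      }
      nuisance[[r]] <- as.data.frame(mot)
      data[, , , (r - 1) * nVolRun + seq_len(nVolRun)] <- array(t(signal), c(dims, nVolRun))
    }
  })

  structure(list(data = data, mask = atlas$mask, atlas = atlas, design = design,
                 tr = tr, leadInVolumes = leadInVolumes, runLength = nVolRun,
                 nuisance = nuisance,
                 truth = list(effects = effects, noise = noise, seed = seed,
                              arbs = participant$arbs, bis = participant$bis)),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Synthetic BOLD session: %dx%dx%d grid, %d volumes (%d runs of %d, TR %g s)\n",
              d[1], d[2], d[3], d[4], d[4] / x$runLength, x$runLength, x$tr))
  cat(sprintf("  %d mask voxels; lead-in %d volumes/run flagged for discard\n",
              sum(x$mask), x$leadInVolumes))
  invisible(x)
}
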