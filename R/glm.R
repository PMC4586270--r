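# First-level GLM: slice-wise AR(10) noise estimation, pre-whitened
# (generalized least squares) fitting, and FIR-timepoint contrasts.

# Extract the analysis-ready data matrix from a synthetic session: lead-in
# volumes dropped per run, in-mask voxels as columns.
sessionDataMatrix <- function(session) {
  d <- dim(session$data)
  nRuns <- d[4] / session$runLength
  keepVol <- unlist(lapply(seq_len(nRuns), function(r)
    (r - 1) * session$runLength + (session$leadInVolumes + 1):session$runLength))
  flat <- matrix(session$data, prod(d[1:3]), d[4])
  vox <- which(session$mask)
  Y <- t(flat[vox, keepVol, drop = FALSE])
  zIdx <- arrayInd(vox, d[1:3])[, 3]
  list(Y = Y, voxels = vox, slice = zIdx, dims = d[1:3])
}

#' Pooled slice-wise residual autocorrelation
#'
#' Sample autocorrelations at lags 1..`maxLag`, computed within runs and
#' pooled (summed cross-products over voxels and runs, normalized by the
#' pooled lag-0 sum) for each functional slice, from the residuals of an
#' uncorrected initial fit.
#'
#' @param residuals Time x voxels residual matrix.
#' @param slice Integer slice index per voxel (column).
#' @param runIndex Run id per row; autocorrelation never crosses runs.
#' @param maxLag Number of lags (default 10).
#' @return Matrix maxLag x nSlices of autocorrelation coefficients.
#' @export
estimateAutocorrelation <- function(residuals, slice, runIndex, maxLag = 10) {
  runs <- unique(runIndex)
  nMin <- min(table(runIndex))
  if (nMin <= maxLag) stop("fewer volumes per run than requested lags")
  slices <- sort(unique(slice))
  num <- matrix(0, maxLag, length(slices), dimnames = list(NULL, slices))
  den <- stats::setNames(numeric(length(slices)), slices)
  for (r in runs) {
    R <- residuals[runIndex == r, , drop = FALSE]
    n <- nrow(R)
    d0 <- colSums(R^2)
    den <- den + rowsum(d0, slice)[as.character(slices), 1]
    for (k in seq_len(maxLag)) {
      ck <- colSums(R[1:(n - k), , drop = FALSE] * R[(k + 1):n, , drop = FALSE])
      num[k, ] <- num[k, ] + rowsum(ck, slice)[as.character(slices), 1]
    }
  }
  sweep(num, 2, pmax(den, .Machine$double.eps), "/")
}

# Levinson-Durbin recursion from autocorrelations rho[1..m] to AR
# coefficients, stabilized: the recursion stops before any reflection
# coefficient reaches 1 in magnitude (falling back to the reduced order).
levinsonDurbin <- function(rho, eps = 1e-6) {
  m <- length(rho)
  phi <- numeric(0)
  err <- 1
  for (k in seq_len(m)) {
    prev <- phi
    kk <- (rho[k] - if (k > 1) sum(prev * rho[(k - 1):1]) else 0) / err
    if (!is.finite(kk) || abs(kk) >= 1 - eps) break
    phi <- c(prev - kk * rev(prev), kk)
    err <- err * (1 - kk^2)
  }
  phi
}

#' Pre-whitened (generalized least squares) first-level fit
#'
#' Fits the FIR design per voxel under a slice-wise AR noise model. The
#' whitening transform is the inverse Cholesky factor of the AR model's
#' Toeplitz correlation matrix (AR coefficients from the pooled slice
#' autocorrelations via stabilized Levinson-Durbin), applied per run to both
#' data and design; weighted least squares on the whitened system gives the
#' autocorrelation-corrected betas. With an all-zero AR model the fit reduces
#' to ordinary least squares. Degrees of freedom are volumes minus the design
#' rank.
#'
#' @param Y Time x voxels data matrix (lead-in already discarded).
#' @param dm A `design_matrix`.
#' @param slice Slice index per voxel.
#' @param ar maxLag x nSlices matrix of autocorrelations (e.g. from
#'   [estimateAutocorrelation()]), or NULL for ordinary least squares.
#' @return List of class `first_level_fit`: `betas` (p x voxels), `sigma2`,
#'   `df`, per-slice `qform` environments for contrast variances, `ar`,
#'   `colnames`, `slice`, residuals of the whitened fit.
#' @export
prewhitenAndFit <- function(Y, dm, slice, ar = NULL) {
  X <- dm$X
  n <- nrow(X); p <- ncol(X)
  rk <- checkDesignIndependence(X)
  if (!rk$fullRank) {
    qrX <- qr(X)
    dep <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("singular design matrix; dependent columns: ", paste(dep, collapse = ", "))
  }
  slices <- sort(unique(slice))
  runs <- unique(dm$runIndex)
  nRun <- sum(dm$runIndex == runs[1])
  betas <- matrix(NA_real_, p, ncol(Y), dimnames = list(colnames(X), NULL))
  sigma2 <- numeric(ncol(Y))
  resid <- matrix(NA_real_, n, ncol(Y))
  XtXinv <- vector("list", length(slices))
  names(XtXinv) <- as.character(slices)

  for (si in seq_along(slices)) {
    s <- slices[si]
    cols <- which(slice == s)
    rho <- if (is.null(ar)) numeric(0) else ar[, as.character(s)]
    phi <- if (length(rho)) levinsonDurbin(rho) else numeric(0)
    if (length(phi)) {
      acf <- stats::ARMAacf(ar = phi, lag.max = nRun - 1)[-1]
      V <- stats::toeplitz(c(1, acf))
      U <- chol(V)                       # V = U'U; whitening = solve(t(U))
      wh <- function(M) {
        out <- M
        for (r in runs) {
          rows <- which(dm$runIndex == r)
          out[rows, ] <- forwardsolve(t(U), M[rows, , drop = FALSE])
        }
        out
      }
      Xw <- wh(X)
      Yw <- wh(Y[, cols, drop = FALSE])
    } else {
      Xw <- X
      Yw <- Y[, cols, drop = FALSE]
    }
    G <- crossprod(Xw)
    Ginv <- chol2inv(chol(G))
    B <- Ginv %*% crossprod(Xw, Yw)
    E <- Yw - Xw %*% B
    df <- n - p
    betas[, cols] <- B
    sigma2[cols] <- colSums(E^2) / df
    resid[, cols] <- E
    XtXinv[[si]] <- Ginv
  }
  structure(list(betas = betas, sigma2 = sigma2, df = n - p, XtXinv = XtXinv,
                 ar = ar, colnames = colnames(X), slice = slice,
                 residuals = resid, dm = dm),
            class = "first_level_fit")
}

#' Fit the first-level model to a synthetic session
#'
#' Convenience pipeline: build the FIR design, run the uncorrected initial
#' fit, estimate slice-wise autocorrelations from its residuals, then refit
#' with pre-whitening.
#'
#' @param session A `bold_session`.
#' @param errorOnsets Optional error-trial table passed to
#'   [buildDesignMatrix()].
#' @param maxLag AR lags to estimate (default 10).
#' @param prewhiten Set FALSE to stop after the ordinary fit.
#' @param includeMotion Include the session's motion-like nuisance tables.
#' @param design Optional design override (e.g. permuted labels); defaults to
#'   the session's own design.
#' @return A `first_level_fit` with voxel bookkeeping (`voxels`, `dims`,
#'   `mask`) attached.
#' @export
fitFirstLevel <- function(session, errorOnsets = NULL, maxLag = 10,
                          prewhiten = TRUE, includeMotion = TRUE,
                          design = NULL) {
  sdm <- sessionDataMatrix(session)
  dm <- buildDesignMatrix(design %||% session$design, tr = session$tr,
                          discardVolumes = session$leadInVolumes,
                          errorOnsets = errorOnsets,
                          nuisance = if (includeMotion) session$nuisance)
  fit0 <- prewhitenAndFit(sdm$Y, dm, sdm$slice, ar = NULL)
  if (prewhiten) {
    ar <- estimateAutocorrelation(fit0$residuals, sdm$slice, dm$runIndex, maxLag)
    fit <- prewhitenAndFit(sdm$Y, dm, sdm$slice, ar = ar)
  } else fit <- fit0
  fit$voxels <- sdm$voxels
  fit$dims <- sdm$dims
  fit$mask <- session$mask
  fit$voxelSize <- session$atlas$voxelSize
  fit
}

#' Built-in first-level contrast definitions
#'
#' Response inhibition: (aversive NoGo + neutral NoGo) - (aversive Go +
#' neutral Go). Emotional valence: (aversive NoGo + aversive Go) - (neutral
#' NoGo + neutral Go). Interaction: (aversive NoGo - aversive Go) - (neutral
#' NoGo - neutral Go). Effects are taken from the FIR betas at `timepoints`
#' (default the 3rd and 4th, 4 and 6 s from trial start), combined per type
#' by `combine`.
#'
#' @param timepoints FIR timepoints entering the contrast.
#' @param combine "mean" (default: effect stays in amplitude units) or "sum".
#' @return Named list of `contrast_def` objects.
#' @export
contrastDefs <- function(timepoints = c(3, 4), combine = "mean") {
  w <- function(ng, ag, nn, an)
    c("neutral-go" = ng, "aversive-go" = ag, "neutral-nogo" = nn, "aversive-nogo" = an)
  defs <- list(
    response_inhibition = w(-1, -1, +1, +1),
    emotional_valence = w(-1, +1, -1, +1),
    interaction = w(+1, -1, -1, +1)
  )
  lapply(names(defs), function(nm)
    structure(list(name = nm, weights = defs[[nm]], timepoints = timepoints,
                   combine = combine), class = "contrast_def")) |>
    stats::setNames(names(defs))
}

#' Compute a first-level contrast map
#'
#' Contrast effect = the per-type combination (mean or sum) of FIR betas at
#' the definition's timepoints, weighted by the definition's type weights;
#' the standard error comes from the whitened fit's covariance, and t =
#' effect / SE at the fit's df (two-tailed maps).
#'
#' @param fit A `first_level_fit`.
#' @param cdef A `contrast_def` (see [contrastDefs()]).
#' @return List of class `contrast_map`: `effect`, `se`, `t` (vectors over
#'   the fit's voxels), `df`, `name`, plus voxel bookkeeping.
#' @export
computeContrast <- function(fit, cdef) {
  stopifnot(inherits(cdef, "contrast_def"))
  used <- names(cdef$weights)[cdef$weights != 0]
  missing <- used[!vapply(used, function(t)
    sum(fit$dm$typeCounts[t]) > 0, TRUE)]
  if (length(missing))
    stop("no trials for type(s): ", paste(missing, collapse = ", "))
  cvec <- stats::setNames(numeric(length(fit$colnames)), fit$colnames)
  scl <- if (cdef$combine == "mean") 1 / length(cdef$timepoints) else 1
  for (t in used)
    for (l in cdef$timepoints) {
      col <- sprintf("fir[%s][%d]", t, l)
      if (!col %in% fit$colnames) stop("missing FIR column ", col)
      cvec[col] <- cdef$weights[t] * scl
    }
  effect <- drop(crossprod(cvec, fit$betas))
  q <- vapply(fit$XtXinv, function(G) drop(crossprod(cvec, G %*% cvec)), 0)
  se <- sqrt(fit$sigma2 * q[as.character(fit$slice)])
  structure(list(effect = effect, se = se, t = effect / se, df = fit$df,
                 name = cdef$name, voxels = fit$voxels, dims = fit$dims,
                 voxelSize = fit$voxelSize),
            class = "contrast_map")
}

#' Expand a masked statistic vector to a 3D array
#'
#' @param values Vector over mask voxels.
#' @param voxels Linear indices of those voxels.
#' @param dims Grid dimensions.
#' @param fill Value outside the mask.
#' @return 3D array.
#' @export
toVolume <- function(values, voxels, dims, fill = 0) {
  out <- array(fill, dims)
  out[voxels] <- values
  out
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("Contrast map '%s': %d voxels, df = %d, |t| max = %.2f\n",
              x$name, length(x$t), x$df, max(abs(x$t))))
  invisible(x)
}
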