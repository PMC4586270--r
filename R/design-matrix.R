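# First-level FIR design matrix construction.

#' Build the first-level FIR design matrix
#'
#' One set of `nFir` impulse predictors per trial type (impulse at the
#' trial's volume and the following `nFir - 1` volumes: FIR timepoint k spans
#' 2(k-1) seconds from trial start), an optional set for error trials
#' (collapsed across types; error trials are removed from their own type's
#' set), and per-run nuisance predictors: constant offset, linear drift,
#' cosine and sine with period twice the run length, plus any caller-supplied
#' columns (rigid-body motion parameters, noise-ROI mean timecourses, ...).
#' Nuisance columns are zero outside their run. The first `discardVolumes`
#' volumes of each run are dropped from the model's timeline.
#'
#' @param design A `session_design`.
#' @param tr Volume time, seconds.
#' @param discardVolumes Lead-in volumes discarded per run.
#' @param nFir FIR timepoints per trial type.
#' @param errorOnsets Optional data frame (`run`, `onset_s`) of error trials.
#' @param nuisance Optional list (one per run) of data frames of extra
#'   nuisance columns, with one row per volume (full run or post-discard).
#' @return List of class `design_matrix`: `X`, `colnames`, `taskCols`,
#'   `runIndex` (run of each kept row), `nKept` (rows per run), `typeCounts`,
#'   `tr`, `discardVolumes`, `nFir`.
#' @export
buildDesignMatrix <- function(design, tr = 2, discardVolumes = 6, nFir = 7,
                              errorOnsets = NULL, nuisance = NULL) {
  stopifnot(inherits(design, "session_design"))
  runs <- sort(unique(design$trials$run))
  nVolRun <- as.integer(round(design$runDuration / tr))
  nKept <- nVolRun - discardVolumes
  if (nKept <= nFir) stop("run too short after lead-in discard")
  types <- trialTypes()

  trials <- design$trials
  trials$is_error <- FALSE
  if (!is.null(errorOnsets) && nrow(errorOnsets)) {
    key <- paste(trials$run, trials$onset_s)
    ekey <- paste(errorOnsets$run, errorOnsets$onset_s)
    if (!all(ekey %in% key)) stop("error onsets do not match any trial")
    trials$is_error <- key %in% ekey
  }
  hasError <- any(trials$is_error)

  sets <- c(types, if (hasError) "error")
  nTask <- length(sets) * nFir
  X <- matrix(0, nKept * length(runs), nTask)
  labels <- as.vector(t(outer(sets, seq_len(nFir), function(s, l)
    sprintf("fir[%s][%d]", s, l))))
  colnames(X) <- labels

  for (i in seq_len(nrow(trials))) {
    r <- match(trials$run[i], runs)
    v0 <- trials$onset_s[i] / tr
    if (abs(v0 - round(v0)) > 1e-9)
      stop(sprintf("trial onset %.3f s (run %d) not aligned to the TR grid",
                   trials$onset_s[i], trials$run[i]))
    vk <- as.integer(round(v0)) + 1L - discardVolumes
    if (vk < 1L)
      stop(sprintf("trial onset %.1f s (run %d) falls in the discarded lead-in",
                   trials$onset_s[i], trials$run[i]))
    set <- if (trials$is_error[i]) "error" else trials$trial_type[i]
    for (l in seq_len(nFir)) {
      v <- vk + l - 1L
      if (v <= nKept)
        X[(r - 1L) * nKept + v, sprintf("fir[%s][%d]", set, l)] <- 1
    }
  }

  # Per-run nuisance block.
  nuisCols <- list()
  tKept <- (discardVolumes + seq_len(nKept) - 1) * tr
  for (r in seq_along(runs)) {
    rows <- (r - 1L) * nKept + seq_len(nKept)
    base <- cbind(offset = 1,
                  drift = scale(tKept)[, 1],
                  cosine = cos(2 * pi * tKept / (2 * design$runDuration)),
                  sine = sin(2 * pi * tKept / (2 * design$runDuration)))
    extra <- NULL
    if (!is.null(nuisance)) {
      nr <- as.matrix(nuisance[[r]])
      if (nrow(nr) == nVolRun) nr <- nr[discardVolumes + seq_len(nKept), , drop = FALSE]
      if (nrow(nr) != nKept) stop("nuisance table rows do not match run volumes")
      # All-zero columns (e.g. motion regressors of a motion-free synthetic
      # run) carry no information and would make the design singular.
      nr <- nr[, colSums(abs(nr)) > 0, drop = FALSE]
      if (ncol(nr)) extra <- nr
    }
    blk <- cbind(base, extra)
    colnames(blk) <- sprintf("run%d:%s", runs[r], colnames(blk))
    M <- matrix(0, nKept * length(runs), ncol(blk), dimnames = list(NULL, colnames(blk)))
    M[rows, ] <- blk
    nuisCols[[r]] <- M
  }
  Xn <- do.call(cbind, nuisCols)
  X <- cbind(X, Xn)
  if (anyDuplicated(colnames(X))) stop("duplicate design matrix column labels")

  structure(list(X = X, colnames = colnames(X), taskCols = seq_len(nTask),
                 runIndex = rep(runs, each = nKept), nKept = nKept,
                 typeCounts = table(factor(trials$trial_type[!trials$is_error],
                                           levels = types)),
                 tr = tr, discardVolumes = discardVolumes, nFir = nFir),
            class = "design_matrix")
}
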