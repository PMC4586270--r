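# Event-related timecourse quality assurance for surviving clusters.

#' QA a cluster by its event-related timecourses
#'
#' Averages the BOLD signal over the cluster's voxels for each participant,
#' refits the first-level FIR model to the mean timecourse, and extracts the
#' four trial types' 7-point event-related timecourses (2-s spacing,
#' timepoint k at 2(k-1) s from trial start), averaged across participants.
#' The QA score is the correlation of the across-type mean timecourse with
#' the canonical double-gamma response sampled at the FIR timepoints; the
#' verdict fails below `cutoff` (default 0: any positive resemblance passes)
#' and is "indeterminate" when the timecourses are flat.
#'
#' @param clusterVoxels Linear voxel indices of the cluster (must lie in the
#'   sessions' mask).
#' @param sessions List of `bold_session`s.
#' @param cutoff Minimum QA score to pass.
#' @param prewhiten Pre-whiten the timecourse refits.
#' @return List with `score`, `verdict` ("pass"/"fail"/"indeterminate"),
#'   `timecourses` (7 x 4 matrix, participant mean), `perParticipant`.
#' @export
qaClusterTimecourses <- function(clusterVoxels, sessions, cutoff = 0,
                                 prewhiten = FALSE) {
  if (!length(clusterVoxels)) stop("empty cluster")
  types <- trialTypes()
  proto <- sessions[[1]]
  if (!all(proto$mask[clusterVoxels])) stop("cluster extends outside the mask")
  nFir <- 7
  percp <- lapply(sessions, function(ses) {
    d <- dim(ses$data)
    flat <- matrix(ses$data, prod(d[1:3]), d[4])
    tc <- colMeans(flat[clusterVoxels, , drop = FALSE])
    # Re-use the session machinery on a single "voxel".
    one <- ses
    one$data <- array(rep(tc, each = 1), c(1, 1, 1, d[4]))
    one$mask <- array(TRUE, c(1, 1, 1))
    one$atlas <- list(labels = array(1L, c(1, 1, 1)), mask = one$mask,
                      regions = data.frame(id = 1), voxelSize = ses$atlas$voxelSize)
    class(one$atlas) <- "atlas"
    fit <- fitFirstLevel(one, prewhiten = prewhiten, maxLag = 10)
    vapply(types, function(tt)
      fit$betas[sprintf("fir[%s][%d]", tt, seq_len(nFir)), 1], numeric(nFir))
  })
  tcMean <- Reduce(`+`, percp) / length(percp)
  shape <- rowMeans(tcMean)
  canon <- hrf((seq_len(nFir) - 1) * proto$tr)
  if (stats::sd(shape) < 1e-10)
    return(list(score = NA_real_, verdict = "indeterminate",
                timecourses = tcMean, perParticipant = percp))
  score <- stats::cor(shape, canon)
  list(score = score, verdict = if (score >= cutoff) "pass" else "fail",
       timecourses = tcMean, perParticipant = percp)
}
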