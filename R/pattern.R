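# Correlation-pattern analysis: region-by-contrast correlation vectors for
# two instruments, the pattern-similarity statistic, and the stratified
# split-resampling test against the 0.3 / 0.7 cutoffs.

#' Region-by-contrast mean contrast values
#'
#' For every participant, every atlas region and every first-level contrast,
#' the arithmetic mean of the participant's contrast effect over the region's
#' voxels. With the default 26-region atlas and 3 contrasts this is a
#' participants x 78 matrix.
#'
#' @param firstLevel List over participants of named lists of `contrast_map`s.
#' @param atlas An `atlas` (labels on the maps' grid).
#' @return Matrix participants x (regions * contrasts), class
#'   `region_contrast_values`; columns named `region:contrast`.
#' @export
regionContrastValues <- function(firstLevel, atlas) {
  proto <- firstLevel[[1]][[1]]
  if (!identical(dim(atlas$labels), proto$dims))
    stop("atlas grid does not match contrast maps")
  lab <- atlas$labels[proto$voxels]
  regions <- atlas$regions$id
  empty <- regions[!regions %in% lab]
  if (length(empty))
    stop("region(s) empty within the mask: ",
         paste(atlas$regions$name[match(empty, atlas$regions$id)], collapse = ", "))
  contrasts <- names(firstLevel[[1]])
  cols <- as.vector(outer(atlas$regions$name, contrasts, paste, sep = ":"))
  out <- matrix(NA_real_, length(firstLevel), length(cols),
                dimnames = list(NULL, cols))
  grp <- factor(lab, levels = regions)
  for (i in seq_along(firstLevel))
    for (j in seq_along(contrasts)) {
      e <- firstLevel[[i]][[contrasts[j]]]$effect
      means <- tapply(e[lab > 0], grp[lab > 0], mean)
      out[i, (j - 1) * length(regions) + seq_along(regions)] <- means
    }
  structure(out, class = c("region_contrast_values", "matrix"),
            regions = atlas$regions$name, contrasts = contrasts)
}

#' Correlation pattern of an instrument
#'
#' Pearson correlation, across participants, between each region-by-contrast
#' column and the instrument's scores: with 26 regions and 3 contrasts, a set
#' of 78 correlation values.
#'
#' @param values A `region_contrast_values` matrix (or any participants x
#'   columns matrix).
#' @param scores Numeric per-participant instrument scores (non-constant).
#' @param instrument Name recorded on the pattern.
#' @return Numeric vector of correlations (class `correlation_pattern`) with
#'   attributes `instrument` and `n`.
#' @export
computePattern <- function(values, scores, instrument = "score") {
  n <- nrow(values)
  if (n < 3) stop("need at least 3 participants")
  if (length(scores) != n) stop("scores do not match rows of values")
  if (stats::sd(scores) == 0) stop("constant scores: correlation undefined")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant contrast-value column(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  r <- drop(stats::cor(scores, values))
  structure(r, class = "correlation_pattern", instrument = instrument, n = n)
}

#' Similarity between two correlation patterns
#'
#' `S = 1 - sum((a - b)^2) / L` (one minus the mean squared entrywise
#' difference; equivalently one minus squared Euclidean distance over the
#' pattern length). S is symmetric, equals 1 exactly when the patterns are
#' identical, and equals 0 when one pattern is all ones and the other all
#' zeros; for correlation-valued entries S lies in [-3, 1]. A literal
#' Euclidean-distance-over-L variant is available via `form = "euclidean"`
#' (it cannot reach 0 for the all-ones/all-zeros pair at L = 78 and is not
#' the default).
#'
#' @param a,b Equal-length numeric patterns.
#' @param form "msd" (default, mean squared difference) or "euclidean".
#' @return Scalar similarity S.
#' @export
patternSimilarity <- function(a, b, form = c("msd", "euclidean")) {
  form <- match.arg(form)
  if (length(a) != length(b)) stop("patterns have different lengths")
  d2 <- sum((as.numeric(a) - as.numeric(b))^2)
  if (form == "msd") 1 - d2 / length(a) else 1 - sqrt(d2) / length(a)
}

#' Stratified split-resampling similarity test
#'
#' On each iteration, participants are split at random into two near-equal
#' groups (sizes differ by at most one) with each risk stratum (low / mid /
#' high ARBS class) divided as evenly as possible between the groups, without
#' replacement. Instrument A's correlation pattern is computed from group 1
#' and instrument B's from group 2, and their similarity S is recorded. The
#' result reports the mean and SD of S and the proportion of iterations with
#' S below the "substantially different" cutoff and above the "very similar"
#' cutoff (defaults 0.3 and 0.7).
#'
#' @param values A `region_contrast_values` matrix.
#' @param scoresA,scoresB Per-participant scores of the two instruments.
#' @param riskClasses Character stratum labels (e.g. from [classifyRisk()]).
#' @param nIter Number of split iterations (study default 10,000).
#' @param cutoffs Low/high similarity cutoffs.
#' @param seed Integer seed.
#' @param form Similarity form, see [patternSimilarity()].
#' @param replace Resample group members with replacement (bootstrap variant)
#'   instead of plain splitting.
#' @return List of class `similarity_result`: `meanS`, `sdS`, `propBelow`,
#'   `propAbove`, `nIter`, `cutoffs`, `S` (all iteration values).
#' @export
splitSimilarityTest <- function(values, scoresA, scoresB, riskClasses,
                                nIter = 10000, cutoffs = c(0.3, 0.7),
                                seed = 1L, form = "msd", replace = FALSE) {
  n <- nrow(values)
  stopifnot(length(scoresA) == n, length(scoresB) == n, length(riskClasses) == n)
  strata <- split(seq_len(n), riskClasses)
  if (any(lengths(strata) < 2))
    stop("stratum too small to split: ",
         paste(names(strata)[lengths(strata) < 2], collapse = ", "))
  S <- withSeed(seed, vapply(seq_len(nIter), function(it) {
    g1 <- integer(0); g2 <- integer(0)
    for (st in strata) {
      st <- sample(st)
      k <- length(st) %/% 2
      take1 <- k
      if (length(st) %% 2 == 1) {
        # Give the odd member to whichever group is behind (coin flip on ties).
        if (length(g1) < length(g2)) take1 <- k + 1
        else if (length(g1) == length(g2) && stats::runif(1) < 0.5) take1 <- k + 1
      }
      g1 <- c(g1, st[seq_len(take1)])
      g2 <- c(g2, st[(take1 + 1):length(st)])
    }
    if (replace) {
      g1 <- sample(g1, replace = TRUE)
      g2 <- sample(g2, replace = TRUE)
    }
    pa <- computePattern(values[g1, , drop = FALSE], scoresA[g1], "A")
    pb <- computePattern(values[g2, , drop = FALSE], scoresB[g2], "B")
    patternSimilarity(pa, pb, form = form)
  }, numeric(1)))
  structure(list(meanS = mean(S), sdS = stats::sd(S),
                 propBelow = mean(S < cutoffs[1]), propAbove = mean(S > cutoffs[2]),
                 nIter = nIter, cutoffs = cutoffs, S = S),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Pattern similarity over %d stratified splits: S = %.2f +/- %.2f\n",
              x$nIter, x$meanS, x$sdS))
  cat(sprintf("  P(S < %.2g) = %.3g; P(S > %.2g) = %.3g\n",
              x$cutoffs[1], x$propBelow, x$cutoffs[2], x$propAbove))
  invisible(x)
}
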