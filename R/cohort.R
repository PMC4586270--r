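# Synthetic participant cohorts with the score structure the analysis
# assumes: correlated ARBS risk and BIS impulsivity totals, a bimodal ARBS
# break (no mid-range scores), and BIS subscale decompositions.

# Study-sample moments: ARBS 15.6 +/- 4.6 (10 of 21 >= 17), BIS 67.6 +/- 16.1,
# subscale means from the sample's subscale table.
defaultScoreMoments <- function() {
  list(arbs = c(mean = 15.6, sd = 4.6),
       bis = c(mean = 67.6, sd = 16.1),
       bisSubscaleMeans = c(attentional = 11.8, cognitive_instability = 7.0,
                            motor = 15.2, perseverance = 7.8,
                            self_control = 13.8, cognitive_complexity = 12.0))
}

# BIS-11 subscale item counts fix each subscale's feasible range
# [items, 4*items].
bisSubscaleItems <- function()
  c(attentional = 5, cognitive_instability = 3, motor = 7,
    perseverance = 4, self_control = 6, cognitive_complexity = 5)

#' Generate a synthetic participant cohort
#'
#' Draws latent (ARBS, BIS) pairs from a bivariate Gaussian whose sample
#' correlation is forced to `targetCorr` (empirical covariance matching),
#' assigns exactly `nHigh` participants to the high-risk stratum (ARBS >= 17,
#' the rest <= 13, mirroring the sample's natural break with no scores in
#' 14-16), rounds and clips scores to their instrument ranges, and decomposes
#' each BIS total into six subscale sums at the sample's subscale proportions.
#'
#' @param n Cohort size.
#' @param nHigh Number of high-risk participants (ARBS >= 17).
#' @param targetCorr Target ARBS-BIS correlation of the latent draw.
#' @param scoreMoments List with `arbs` and `bis` mean/sd vectors and
#'   `bisSubscaleMeans`; see `defaultScoreMoments`.
#' @param seed Integer seed.
#' @return Data frame (class `cohort`) with columns `id`, `arbs`, `bis`, six
#'   `bis_*` subscale columns and `risk_class`; attribute `achievedCorr`
#'   records the realized ARBS-BIS correlation after discretization.
#' @export
generateCohort <- function(n = 21, nHigh = 10, targetCorr = 0.78,
                           scoreMoments = defaultScoreMoments(), seed = 1L) {
  if (nHigh > n) stop("nHigh cannot exceed n")
  if (abs(targetCorr) > 1) stop("targetCorr must lie in [-1, 1]")
  am <- scoreMoments$arbs; bm <- scoreMoments$bis
  if (am["mean"] < 9 || am["mean"] > 30 || bm["mean"] < 30 || bm["mean"] > 120)
    stop("score means outside instrument ranges")
  Sigma <- matrix(c(1, targetCorr, targetCorr, 1), 2)
  z <- withSeed(seed, MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma,
                                    empirical = (n > 2)))
  arbsRaw <- am["mean"] + am["sd"] * z[, 1]
  bis <- pmin(120, pmax(30, round(bm["mean"] + bm["sd"] * z[, 2])))

  # Bimodal ARBS: the nHigh largest latent scores land in [17, 30], the rest
  # in [9, 13]; rank order is preserved so the latent correlation survives.
  arbs <- round(arbsRaw)
  hi <- rank(arbsRaw, ties.method = "first") > n - nHigh
  arbs[hi] <- pmin(30, pmax(17, arbs[hi]))
  arbs[!hi] <- pmin(13, pmax(9, arbs[!hi]))

  subs <- t(vapply(bis, decomposeBisTotal,
                   numeric(6), means = scoreMoments$bisSubscaleMeans))
  colnames(subs) <- paste0("bis_", names(bisSubscaleItems()))
  out <- data.frame(id = sprintf("sub-%02d", seq_len(n)),
                    arbs = as.integer(arbs), bis = as.integer(bis),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(subs))
  out$risk_class <- classifyRisk(out$arbs)
  attr(out, "achievedCorr") <- if (n >= 3) stats::cor(out$arbs, out$bis) else NA_real_
  attr(out, "seed") <- seed
  class(out) <- c("cohort", "data.frame")
  out
}

# Split a BIS total into six subscale sums proportional to the sample's
# subscale means, by largest remainder, respecting each subscale's item-count
# bounds [items, 4*items].
decomposeBisTotal <- function(total, means = defaultScoreMoments()$bisSubscaleMeans) {
  items <- bisSubscaleItems()
  means <- means[names(items)]
  alloc <- largestRemainder(total, means / sum(means))
  alloc <- pmin(4 * items, pmax(items, alloc))
  # Repair the sum after clipping, moving units where bounds allow.
  diff <- total - sum(alloc)
  while (diff != 0) {
    if (diff > 0) {
      k <- which(alloc < 4 * items)[which.max((4 * items - alloc)[alloc < 4 * items])]
      alloc[k] <- alloc[k] + 1
      diff <- diff - 1
    } else {
      k <- which(alloc > items)[which.max((alloc - items)[alloc > items])]
      alloc[k] <- alloc[k] - 1
      diff <- diff + 1
    }
  }
  alloc
}

#' Simulate Go/NoGo task performance for a cohort
#'
#' Produces a behavioral table with the study's summary structure: skewed
#' NoGo commission rates (zero-inflated), small Go omission rates, and Go
#' latencies slower under aversive distractors.
#'
#' @param cohort A `cohort` data frame.
#' @param seed Integer seed.
#' @param commissionMean Target mean NoGo commission rate in percent.
#' @param latencyMeans Mean Go latency (ms) for neutral and aversive trials.
#' @return Data frame with per-participant commission rates (overall and by
#'   distractor valence), omission rate, and mean latencies by valence.
#' @export
generateBehavior <- function(cohort, seed = 1L, commissionMean = 5.8,
                             latencyMeans = c(neutral = 772, aversive = 808)) {
  n <- nrow(cohort)
  withSeed(seed, {
    rate <- function(mu) {
      x <- stats::rexp(n, 1 / mu) * stats::rbinom(n, 1, 0.75)
      pmin(100, x)
    }
    commission_neutral <- rate(commissionMean)
    commission_aversive <- rate(commissionMean)
    lat_n <- stats::rnorm(n, latencyMeans["neutral"], 120)
    lat_a <- lat_n + stats::rnorm(n, latencyMeans["aversive"] - latencyMeans["neutral"], 30)
    data.frame(id = cohort$id,
               commission_pct = (commission_neutral + commission_aversive) / 2,
               commission_neutral_pct = commission_neutral,
               commission_aversive_pct = commission_aversive,
               omission_pct = pmin(100, stats::rexp(n, 1 / 0.8) *
                                     stats::rbinom(n, 1, 0.3)),
               latency_neutral_ms = pmax(200, lat_n),
               latency_aversive_ms = pmax(200, lat_a),
               stringsAsFactors = FALSE)
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d high-risk, %d low-risk)\n",
              nrow(x), sum(x$risk_class == "high"), sum(x$risk_class == "low")))
  cat(sprintf("  ARBS %.1f +/- %.1f; BIS %.1f +/- %.1f; r(ARBS, BIS) = %.3f\n",
              mean(x$arbs), stats::sd(x$arbs), mean(x$bis), stats::sd(x$bis),
              attr(x, "achievedCorr")))
  invisible(x)
}
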