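# Questionnaire scoring (BIS-11, ARBS risk classification) and the
# resampling statistics used for task-performance measures.

#' Load a BIS-11 scoring key
#'
#' The key (a YAML file) lists the reversed items (scored `5 - response`) and
#' the item partition defining the six first-order subscales: attentional,
#' cognitive instability, motor, perseverance, self-control and cognitive
#' complexity. The instrument's published key ships with the package.
#'
#' @param path Path to a key file; default is the packaged key.
#' @return List with `reversed` (integer item ids) and `subscales` (named list
#'   of integer item ids partitioning 1..30).
#' @export
bisKey <- function(path = system.file("extdata", "bis11_key.yaml",
                                      package = "emogonogo")) {
  key <- yaml::read_yaml(path)
  items <- sort(unlist(key$subscales, use.names = FALSE))
  if (!identical(as.integer(items), 1:30))
    stop("subscales must partition items 1..30")
  if (!all(key$reversed %in% 1:30)) stop("reversed items out of range")
  key
}

#' Score the Barratt Impulsiveness Scale (BIS-11)
#'
#' Applies the reversal map (reversed items score `5 - response`), sums the
#' six first-order subscales, and returns the total (the subscale sums add up
#' to the total by construction of the key).
#'
#' @param responses Integer vector of 30 raw item responses, each in 1-4,
#'   ordered by item number.
#' @param key Scoring key from [bisKey()].
#' @return List with `total` (30-120) and `subscales` (named numeric).
#' @export
scoreBis <- function(responses, key = bisKey()) {
  if (length(responses) != 30 || anyNA(responses))
    stop("need 30 non-missing item responses")
  if (any(responses < 1 | responses > 4 | responses != round(responses)))
    stop("item responses must be integers in 1..4")
  scored <- responses
  scored[key$reversed] <- 5 - scored[key$reversed]
  subs <- vapply(key$subscales, function(items) sum(scored[items]), 0)
  list(total = sum(subs), subscales = subs)
}

#' Classify clinical risk from an ARBS score
#'
#' The Adolescent Risk Behavior Screen spans 9 (lowest risk) to 30 (highest).
#' High risk is a score of 17 or more; 13 or less is low risk; 14-16 is mid
#' (the study sample had a natural break with no scores in 14-16).
#'
#' @param arbs Integer ARBS total(s) in 9..30.
#' @return Character vector in \{"low", "mid", "high"\}.
#' @export
classifyRisk <- function(arbs) {
  if (any(arbs < 9 | arbs > 30)) stop("ARBS scores must lie in 9..30")
  ifelse(arbs >= 17, "high", ifelse(arbs <= 13, "low", "mid"))
}

#' Bootstrap test of a mean against zero
#'
#' Percentile bootstrap of the sample mean; the one-sided p-value is the
#' fraction of resampled means at or below zero (rates cannot be negative, so
#' the vs-zero test is one-sided by default). P-values are floored at the
#' resolution `1/nIter` so a zero count is reported as a bound, not as 0.
#'
#' @param x Numeric per-participant values.
#' @param nIter Number of bootstrap resamples.
#' @param twoSided Double the one-sided p (capped at 1).
#' @param seed Integer seed.
#' @return List with `mean`, `p`, `nIter`.
#' @export
bootstrapMeanTest <- function(x, nIter = 10000, twoSided = FALSE, seed = NULL) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (nIter < 1000) stop("nIter must be >= 1000")
  if (all(x == 0)) return(list(mean = 0, p = 1, nIter = nIter))
  means <- withSeed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * nIter, replace = TRUE),
                  nrow = nIter)
    rowMeans(matrix(x[idx], nrow = nIter))
  })
  p <- max(mean(means <= 0), 1 / nIter)
  if (twoSided) p <- min(1, 2 * p)
  list(mean = mean(x), p = p, nIter = nIter)
}

#' Paired sign-flip permutation test
#'
#' Tests paired differences (e.g. aversive vs neutral NoGo commission rates)
#' by randomly flipping the sign of each participant's difference; the
#' two-sided p-value compares |mean difference| with its sign-flip null.
#'
#' @param a,b Paired numeric vectors.
#' @param nIter Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return List with `meanDiff`, `p`, `nIter`.
#' @export
permutationPairedTest <- function(a, b, nIter = 10000, seed = NULL) {
  if (!length(a) || length(a) != length(b)) stop("a and b must be equal-length, non-empty")
  if (nIter < 1000) stop("nIter must be >= 1000")
  d <- a - b
  obs <- abs(mean(d))
  nulls <- withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), length(d) * nIter, replace = TRUE), nrow = nIter)
    abs(signs %*% d / length(d))
  })
  p <- max((sum(nulls >= obs - 1e-12) + 1) / (nIter + 1), 1 / nIter)
  list(meanDiff = mean(d), p = min(p, 1), nIter = nIter)
}

#' Bootstrap regression by residual resampling
#'
#' Fits `y ~ x` by least squares, then refits on `fitted + resampled
#' residuals` (residuals drawn with replacement); the two-sided p-value is the
#' fraction of resampled slopes on the far side of zero from the observed
#' slope, doubled.
#'
#' @param y,x Numeric vectors.
#' @param nIter Number of residual-bootstrap refits.
#' @param seed Integer seed.
#' @return List with `slope`, `intercept`, `p`, `nIter`.
#' @export
bootstrapRegression <- function(y, x, nIter = 10000, seed = NULL) {
  if (length(y) < 3 || length(y) != length(x)) stop("need n >= 3 paired values")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  if (nIter < 1000) stop("nIter must be >= 1000")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  res <- fit$residuals
  fitted <- y - res
  slopes <- withSeed(seed, {
    X <- cbind(1, x)
    XtXinvXt <- solve(crossprod(X), t(X))
    ystar <- matrix(fitted, nrow = length(y), ncol = nIter) +
      matrix(sample(res, length(y) * nIter, replace = TRUE), nrow = length(y))
    (XtXinvXt %*% ystar)[2, ]
  })
  pOne <- if (slope >= 0) mean(slopes <= 0) else mean(slopes >= 0)
  p <- min(1, max(2 * pOne, 1 / nIter))
  list(slope = unname(slope), intercept = unname(fit$coefficients[1]),
       p = p, nIter = nIter)
}

#' Paired t-test of Go latencies (neutral vs aversive)
#'
#' Thin wrapper over [stats::t.test()] kept for pipeline completeness:
#' latencies, unlike error rates, are near-normal and are compared by t-test.
#'
#' @param neutral,aversive Paired latency vectors (ms).
#' @return `htest` object from [stats::t.test()].
#' @export
latencyPairedTest <- function(neutral, aversive) {
  stats::t.test(aversive, neutral, paired = TRUE)
}
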