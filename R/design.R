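# Emotional Go/NoGo task-design generation: trial-type sequencing with
# first-order counterbalancing, pseudo-random inter-trial intervals, and
# arousal/valence-based distractor stimulus selection.

#' Trial types of the emotional Go/NoGo task
#'
#' The task crosses the response facet (go / nogo, presented 4:1) with the
#' emotional valence of the task-irrelevant distractor picture (neutral /
#' aversive), giving four trial types.
#'
#' @return Character vector of the four trial-type labels.
#' @export
trialTypes <- function() c("neutral-go", "aversive-go", "neutral-nogo", "aversive-nogo")

#' Decompose trial-type labels into facets
#'
#' @param type Character vector of trial-type labels.
#' @return Data frame with columns `type`, `response` ("go"/"nogo") and
#'   `valence` ("neutral"/"aversive").
#' @export
trialTypeFacets <- function(type) {
  stopifnot(all(type %in% trialTypes()))
  parts <- strsplit(type, "-", fixed = TRUE)
  data.frame(
    type = type,
    response = vapply(parts, `[`, "", 2L),
    valence = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

#' Pseudo-randomized inter-trial interval sequence
#'
#' Allocates `n` inter-trial intervals (ITIs) over the durations named in
#' `proportions` by largest-remainder rounding, then randomizes the order.
#' The default 30/40/30 mix over \{2, 4, 6\} s has mean 4 s.
#'
#' @param n Number of ITIs.
#' @param proportions Named numeric vector of target fractions; names are ITI
#'   durations in seconds. Must be non-negative and sum to 1.
#' @param seed Integer seed for the order randomization.
#' @return Numeric vector of `n` ITI durations in seconds.
#' @export
generateItiSequence <- function(n, proportions = c("2" = 0.3, "4" = 0.4, "6" = 0.3),
                                seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  durations <- as.numeric(names(proportions))
  if (anyNA(durations)) stop("proportions must be named by duration in seconds")
  counts <- largestRemainder(n, proportions)
  pool <- rep(durations, counts)
  withSeed(seed, sample(pool))
}

# Per-type allocation of ITI durations: each trial type sees the same duration
# proportions as the overall mix (largest remainder within type, then
# reconciled so the column sums equal the session-level largest-remainder
# allocation while every cell stays within one trial of its proportional
# share).
itiCountsByType <- function(typeCounts, proportions) {
  nd <- length(proportions)
  tab <- t(vapply(typeCounts, function(nt) largestRemainder(nt, proportions),
                  integer(nd)))
  global <- largestRemainder(sum(typeCounts), proportions)
  target <- outer(as.numeric(typeCounts), proportions)
  for (it in seq_len(20L)) {
    colDev <- colSums(tab) - global
    if (all(colDev == 0)) break
    dP <- which(colDev > 0)[1]
    dM <- which(colDev < 0)[1]
    ok <- which(tab[, dP] > 0 &
                  abs(tab[, dP] - 1 - target[, dP]) <= 1 &
                  abs(tab[, dM] + 1 - target[, dM]) <= 1)
    if (!length(ok))
      stop("cannot reconcile ITI precedence balance with the session ITI mix")
    # Move the unit where it most reduces cell deviation.
    gain <- (abs(tab[ok, dP] - target[ok, dP]) + abs(tab[ok, dM] - target[ok, dM])) -
      (abs(tab[ok, dP] - 1 - target[ok, dP]) + abs(tab[ok, dM] + 1 - target[ok, dM]))
    t0 <- ok[which.max(gain)]
    tab[t0, dP] <- tab[t0, dP] - 1L
    tab[t0, dM] <- tab[t0, dM] + 1L
  }
  if (!all(colSums(tab) == global))
    stop("cannot reconcile ITI precedence balance with the session ITI mix")
  tab
}

#' Generate a counterbalanced Go/NoGo session design
#'
#' Builds an event-related session of `nRuns` runs. The session reproduces the
#' study design: 204 trials (84 neutral-go, 80 aversive-go, 20 neutral-nogo,
#' 20 aversive-nogo) over four 330-s runs at 2-s trials, the first trial of
#' every run a neutral-go, ITIs drawn from \{2, 4, 6\} s at 30/40/30 (mean
#' 4 s), each trial type preceded by the three ITI durations in the same
#' proportions (within one trial per cell), and trial-type transition counts
#' balanced toward their frequency-proportional targets by a randomized greedy
#' search keeping the best of `attempts` constructions.
#'
#' @param counts Named integer vector of session trial counts per type.
#' @param nRuns Number of runs; `counts` minus one leading neutral-go per run
#'   must split evenly-ish across runs.
#' @param runDuration Run length in seconds.
#' @param trialDuration Trial length in seconds (one volume).
#' @param itiProportions Named fractions over ITI durations (seconds).
#' @param attempts Number of greedy sequencing attempts; the transition table
#'   closest to its proportional target is kept.
#' @param padSplit Fraction of each run's slack fixation placed before the
#'   first trial (rounded down to the volume grid); the rest trails.
#' @param seed Integer seed; recorded in the design metadata.
#' @return A `session_design` object: list with `trials` (data frame: `run`,
#'   `onset_s`, `duration_s`, `trial_type`, `iti_before_s`), `runDuration`,
#'   `trialDuration`, `counts`, and `metadata` (seed, transition table and
#'   deviation, per-run pads).
#' @export
generateSessionDesign <- function(counts = c("neutral-go" = 84, "aversive-go" = 80,
                                             "neutral-nogo" = 20, "aversive-nogo" = 20),
                                  nRuns = 4, runDuration = 330, trialDuration = 2,
                                  itiProportions = c("2" = 0.3, "4" = 0.4, "6" = 0.3),
                                  attempts = 20, padSplit = 0.5, seed = 1L) {
  types <- trialTypes()
  stopifnot(all(names(counts) %in% types), all(counts >= 0))
  full <- stats::setNames(integer(length(types)), types)
  full[names(counts)] <- as.integer(counts)
  counts <- full
  if (counts["neutral-go"] < nRuns)
    stop("need at least one neutral-go trial per run (first-trial rule)")
  durations <- as.numeric(names(itiProportions))

  # Core counts exclude the forced leading neutral-go of each run.
  core <- counts
  core["neutral-go"] <- core["neutral-go"] - nRuns
  perRun <- matrix(vapply(core, function(n)
    largestRemainder(n, rep(1 / nRuns, nRuns)), integer(nRuns)),
    nrow = nRuns, dimnames = list(NULL, names(core)))   # runs x types
  perRun[, "neutral-go"] <- perRun[, "neutral-go"] + 1L
  nTrialsRun <- rowSums(perRun)

  # Feasibility: trials + mean ITI load must fit the run.
  itiTotal <- sum(largestRemainder(sum(counts), itiProportions) * durations)
  need <- sum(counts) * trialDuration + itiTotal
  if (need > nRuns * runDuration)
    stop(sprintf("infeasible design: %g s of trials+ITIs exceed %g s of run time",
                 need, nRuns * runDuration))

  best <- NULL
  for (a in seq_len(attempts)) {
    cand <- withSeed(childSeed(seed, a), buildSessionAttempt(
      perRun, counts, itiProportions, durations, runDuration, trialDuration, padSplit))
    if (is.null(best) || cand$score < best$score) best <- cand
  }

  out <- list(trials = best$trials, runDuration = runDuration,
              trialDuration = trialDuration, counts = counts,
              itiProportions = itiProportions,
              metadata = list(seed = seed, attempts = attempts,
                              transitions = best$transitions,
                              transition_deviation = best$score,
                              lead_pad_s = best$lead, trail_pad_s = best$trail))
  class(out) <- "session_design"
  chk <- checkSessionDesign(out)
  if (!chk$ok)
    stop("internal error: generated design failed its own checks: ",
         paste(names(Filter(isFALSE, chk$checks)), collapse = ", "))
  out
}

# One randomized construction: greedy transition-balanced type sequences per
# run, per-type ITI assignment, run-load rebalancing, onset computation.
buildSessionAttempt <- function(perRun, counts, itiProportions, durations,
                                runDuration, trialDuration, padSplit) {
  types <- colnames(perRun)
  nRuns <- nrow(perRun)
  nTot <- sum(perRun)
  # Frequency-proportional transition targets: uniform is unattainable when the
  # marginals are 84/80/20/20, so balance toward n_prev * n_next shares.
  nTrans <- nTot - nRuns
  target <- outer(counts, counts)
  target <- target / sum(target) * nTrans

  trans <- matrix(0, length(types), length(types), dimnames = list(types, types))
  seqs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    remaining <- perRun[r, ]
    sq <- character(sum(remaining))
    sq[1] <- "neutral-go"
    remaining["neutral-go"] <- remaining["neutral-go"] - 1L
    for (i in seq_len(length(sq) - 1L) + 1L) {
      prev <- sq[i - 1L]
      avail <- names(remaining)[remaining > 0]
      # Relative fill of the (prev -> t) cell vs its target, preferring types
      # with many trials left so the tail stays feasible.
      fill <- (trans[prev, avail] + 1) / pmax(target[prev, avail], 1e-9)
      cand <- avail[fill == min(fill)]
      if (length(cand) > 1) {
        cand <- cand[remaining[cand] == max(remaining[cand])]
        if (length(cand) > 1) cand <- sample(cand, 1L)
      }
      sq[i] <- cand
      trans[prev, cand] <- trans[prev, cand] + 1
      remaining[cand] <- remaining[cand] - 1L
    }
    seqs[[r]] <- sq
  }
  score <- sum((trans - target)^2)

  # ITI durations per type at the overall proportions, shuffled within type,
  # dealt to that type's trials in run order.
  typeCounts <- vapply(types, function(t) sum(perRun[, t]), integer(1))
  itiByType <- itiCountsByType(typeCounts, itiProportions)
  rownames(itiByType) <- types
  pools <- lapply(types, function(t) sample(rep(durations, itiByType[t, ])))
  names(pools) <- types
  used <- stats::setNames(integer(length(types)), types)
  runIti <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    sq <- seqs[[r]]
    iti <- numeric(length(sq))
    for (i in seq_along(sq)) {
      t <- sq[i]
      used[t] <- used[t] + 1L
      iti[i] <- pools[[t]][used[t]]
    }
    runIti[[r]] <- iti
  }

  # Rebalance run ITI loads toward the equal share so every run keeps enough
  # fixation slack; swaps stay within a trial type to preserve precedence
  # counterbalancing.
  targetLoad <- sum(unlist(runIti)) / nRuns
  for (it in seq_len(500)) {
    loads <- vapply(runIti, sum, 0)
    hi <- which.max(loads - targetLoad); lo <- which.min(loads - targetLoad)
    if (loads[hi] - targetLoad < 1 || hi == lo) break
    done <- FALSE
    for (t in types) {
      ihi <- which(seqs[[hi]] == t & runIti[[hi]] > 2)
      if (!length(ihi)) next
      dhi <- max(runIti[[hi]][ihi])
      ilo <- which(seqs[[lo]] == t & runIti[[lo]] < dhi)
      if (!length(ilo)) next
      i1 <- ihi[which.max(runIti[[hi]][ihi])]
      i2 <- ilo[which.min(runIti[[lo]][ilo])]
      tmp <- runIti[[hi]][i1]
      runIti[[hi]][i1] <- runIti[[lo]][i2]
      runIti[[lo]][i2] <- tmp
      done <- TRUE
      break
    }
    if (!done) break
  }

  # Onsets: leading fixation (padSplit of the slack, on the volume grid),
  # then ITI + trial alternation; remaining slack trails.
  rows <- list(); lead <- numeric(nRuns); trail <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    sq <- seqs[[r]]; iti <- runIti[[r]]
    slack <- runDuration - length(sq) * trialDuration - sum(iti)
    if (slack < 0) stop("infeasible run: ITI load exceeds run duration")
    lead[r] <- floor(slack * padSplit / trialDuration) * trialDuration
    cursor <- lead[r]
    onset <- numeric(length(sq))
    for (i in seq_along(sq)) {
      onset[i] <- cursor + iti[i]
      cursor <- onset[i] + trialDuration
    }
    trail[r] <- runDuration - cursor
    rows[[r]] <- data.frame(run = r, onset_s = onset, duration_s = trialDuration,
                            trial_type = sq, iti_before_s = iti,
                            stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, rows), transitions = trans, score = score,
       lead = lead, trail = trail)
}

#' Validate a session design against its construction constraints
#'
#' Re-derives every constraint the generator promises: session trial counts,
#' the neutral-go first-trial rule, the global ITI duration mix
#' (largest-remainder of the target proportions, mean 4 s under the default
#' mix), type-wise ITI precedence within one trial of the proportional share,
#' onsets on the volume grid and inside the run, and the transition table
#' matching the generator's recorded optimum.
#'
#' @param design A `session_design`.
#' @return List with `ok` (all checks passed) and `checks` (named logicals),
#'   plus the observed ITI counts and transition deviation.
#' @export
checkSessionDesign <- function(design) {
  stopifnot(inherits(design, "session_design"))
  tr <- design$trials
  types <- trialTypes()
  durations <- as.numeric(names(design$itiProportions))
  checks <- list()

  obsCounts <- table(factor(tr$trial_type, levels = types))
  checks$counts <- all(as.integer(obsCounts[names(design$counts)]) == design$counts)

  first <- tr[!duplicated(tr$run), "trial_type"]
  checks$first_trial_neutral_go <- all(first == "neutral-go")

  wantIti <- largestRemainder(nrow(tr), design$itiProportions)
  obsIti <- table(factor(tr$iti_before_s, levels = durations))
  checks$iti_mix <- all(as.integer(obsIti) == wantIti)

  prec <- table(factor(tr$trial_type, levels = types),
                factor(tr$iti_before_s, levels = durations))
  expectPrec <- outer(as.integer(obsCounts), design$itiProportions)
  checks$iti_precedence <- all(abs(prec - expectPrec) <= 1)

  onsetOk <- abs(tr$onset_s / design$trialDuration -
                   round(tr$onset_s / design$trialDuration)) < 1e-9
  fits <- (tr$onset_s + tr$duration_s) <= design$runDuration
  checks$onsets_on_grid <- all(onsetOk)
  checks$fits_run <- all(fits)

  trans <- sessionTransitions(design)
  checks$transitions_at_optimum <-
    !is.null(design$metadata$transitions) && all(trans == design$metadata$transitions)

  list(ok = all(unlist(checks)), checks = checks,
       iti_counts = obsIti, iti_precedence = prec,
       transition_deviation = design$metadata$transition_deviation)
}

# Within-run trial-type transition counts, pooled over runs.
sessionTransitions <- function(design) {
  types <- trialTypes()
  trans <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  for (r in unique(design$trials$run)) {
    sq <- design$trials$trial_type[design$trials$run == r]
    if (length(sq) > 1)
      for (i in seq_len(length(sq) - 1L))
        trans[sq[i], sq[i + 1L]] <- trans[sq[i], sq[i + 1L]] + 1L
  }
  trans
}

#' @export
print.session_design <- function(x, ...) {
  cat("Emotional Go/NoGo session design\n")
  cat(sprintf("  %d trials over %d runs of %g s (trial %g s)\n",
              nrow(x$trials), length(unique(x$trials$run)),
              x$runDuration, x$trialDuration))
  cnt <- table(factor(x$trials$trial_type, levels = trialTypes()))
  cat("  counts:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  cat(sprintf("  mean ITI %.3g s; seed %s\n", mean(x$trials$iti_before_s),
              format(x$metadata$seed)))
  invisible(x)
}

#' Numerical independence diagnostics for a design matrix
#'
#' Reports the numerical rank and 2-norm condition number of a design matrix
#' via its singular values. Event-related designs are accepted only when the
#' task columns are full rank.
#'
#' @param X Numeric matrix (volumes x predictors).
#' @param tol Relative singular-value tolerance for the rank.
#' @return List with `rank`, `conditionNumber`, `fullRank`.
#' @export
checkDesignIndependence <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (!length(X)) stop("empty design matrix")
  s <- svd(X, nu = 0, nv = 0)$d
  r <- sum(s > tol * max(s, 0))
  kappa <- if (r == 0) Inf else s[1] / s[min(ncol(X), r)]
  list(rank = r, conditionNumber = kappa, fullRank = r == ncol(X))
}

#' Select aversive and neutral distractor images in arousal/valence space
#'
#' Mirrors the study's IAPS selection rule: the `nAversive` images with
#' valence <= 3.6 closest (Euclidean) to the \[arousal, valence\] target
#' \[9, 1\] and the `nNeutral` images with 3.6 < valence < 6.4 closest to
#' \[1, 5\], creating two non-overlapping clusters. Ties are broken by id.
#'
#' @param ratings Data frame with columns `id`, `valence`, `arousal` (1-9).
#' @param nAversive,nNeutral Cluster sizes (study defaults 100 and 104).
#' @param aversiveMaxValence Valence cutoff for the aversive stratum.
#' @param neutralValence Open valence interval for the neutral stratum.
#' @param aversiveTarget,neutralTarget Target points as c(arousal, valence).
#' @return List with `aversive` and `neutral` data frames (id, valence,
#'   arousal, distance), ranked by distance.
#' @export
selectStimuli <- function(ratings, nAversive = 100, nNeutral = 104,
                          aversiveMaxValence = 3.6, neutralValence = c(3.6, 6.4),
                          aversiveTarget = c(9, 1), neutralTarget = c(1, 5)) {
  stopifnot(all(c("id", "valence", "arousal") %in% names(ratings)))
  if (any(ratings$valence < 1 | ratings$valence > 9 |
          ratings$arousal < 1 | ratings$arousal > 9))
    stop("ratings must lie in [1, 9]")
  pick <- function(sub, n, target, label) {
    if (nrow(sub) < n)
      stop(sprintf("insufficient qualifying images in %s stratum: %d < %d",
                   label, nrow(sub), n))
    d <- sqrt((sub$arousal - target[1])^2 + (sub$valence - target[2])^2)
    ord <- order(d, sub$id)
    out <- sub[ord[seq_len(n)], c("id", "valence", "arousal")]
    out$distance <- d[ord[seq_len(n)]]
    rownames(out) <- NULL
    out
  }
  aversive <- pick(ratings[ratings$valence <= aversiveMaxValence, , drop = FALSE],
                   nAversive, aversiveTarget, "aversive")
  neutral <- pick(ratings[ratings$valence > neutralValence[1] &
                            ratings$valence < neutralValence[2], , drop = FALSE],
                  nNeutral, neutralTarget, "neutral")
  stopifnot(!any(aversive$id %in% neutral$id))
  list(aversive = aversive, neutral = neutral)
}

#' Write / read a session design event table
#'
#' Event tables are plain TSV with columns `run`, `onset_s`, `duration_s`,
#' `trial_type`, `iti_before_s`, one row per trial.
#'
#' @param design A `session_design`.
#' @param path File path.
#' @rdname eventTable
#' @export
writeEventTable <- function(design, path) {
  utils::write.table(design$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param runDuration,trialDuration Session geometry to attach on read.
#' @param itiProportions ITI mix the design was built for.
#' @rdname eventTable
#' @export
readEventTable <- function(path, runDuration = 330, trialDuration = 2,
                           itiProportions = c("2" = 0.3, "4" = 0.4, "6" = 0.3)) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("run", "onset_s", "duration_s", "trial_type", "iti_before_s")
                %in% names(tr)))
  counts <- table(factor(tr$trial_type, levels = trialTypes()))
  out <- list(trials = tr, runDuration = runDuration, trialDuration = trialDuration,
              counts = stats::setNames(as.integer(counts), names(counts)),
              itiProportions = itiProportions,
              metadata = list(seed = NA, transitions = NULL,
                              transition_deviation = NA))
  class(out) <- "session_design"
  out
}
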