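# Task-design generation: ITI allocation, counterbalanced sequences,
# independence diagnostics, stimulus selection.

test_that("ITI allocation matches largest-remainder targets and the 4-s mean", {
  iti <- generateItiSequence(200, seed = 1)
  expect_equal(as.integer(table(iti)), c(60, 80, 60))
  expect_equal(mean(iti), 4.0)

  expect_equal(generateItiSequence(10, c("4" = 1), seed = 1), rep(4, 10))

  # Exhaustive allocation oracle at n = 7: largest remainder minimizes the
  # total absolute deviation from n * p over all integer splits.
  p <- c("2" = 0.3, "4" = 0.4, "6" = 0.3)
  iti7 <- generateItiSequence(7, p, seed = 3)
  got <- as.integer(table(factor(iti7, levels = c(2, 4, 6))))
  splits <- expand.grid(a = 0:7, b = 0:7, c = 0:7)
  splits <- splits[rowSums(splits) == 7, ]
  dev <- function(cnt) sum(abs(cnt - 7 * p))
  best <- min(apply(splits, 1, dev))
  expect_equal(dev(got), best)

  expect_error(generateItiSequence(10, c("2" = 0.5, "4" = 0.6)), "sum to 1")
  expect_error(generateItiSequence(0, p), ">= 1")
})

test_that("default session design satisfies all of its constraints", {
  d <- generateSessionDesign(seed = 7)
  expect_s3_class(d, "session_design")
  expect_equal(nrow(d$trials), 204)
  cnt <- table(factor(d$trials$trial_type, levels = trialTypes()))
  expect_equal(as.integer(cnt), c(84, 80, 20, 20))
  expect_true(all(d$trials$trial_type[!duplicated(d$trials$run)] == "neutral-go"))
  chk <- checkSessionDesign(d)
  expect_true(chk$ok)
  # ITI mix at the 30/40/30 largest-remainder split, mean exactly 4 s.
  expect_equal(as.integer(chk$iti_counts), c(61, 82, 61))
  expect_equal(mean(d$trials$iti_before_s), 4.0)
  # Precedence within one trial of each type's proportional share.
  exp_prec <- outer(c(84, 80, 20, 20), c(0.3, 0.4, 0.3))
  expect_true(all(abs(chk$iti_precedence - exp_prec) <= 1))
})

test_that("designs are seed-deterministic and vary across seeds", {
  a <- generateSessionDesign(seed = 21)
  b <- generateSessionDesign(seed = 21)
  c <- generateSessionDesign(seed = 22)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials$trial_type, c$trials$trial_type))
  expect_equal(table(c$trials$trial_type), table(a$trials$trial_type))
  expect_true(checkSessionDesign(c)$ok)
})

test_that("single-type and infeasible configs behave as specified", {
  d <- generateSessionDesign(counts = c("neutral-go" = 4), nRuns = 1, seed = 1)
  expect_equal(unique(d$trials$trial_type), "neutral-go")
  expect_error(
    generateSessionDesign(counts = c("neutral-go" = 200, "aversive-go" = 200,
                                     "neutral-nogo" = 50, "aversive-nogo" = 50),
                          nRuns = 1, seed = 1),
    "infeasible")
})

test_that("design independence diagnostics report rank and conditioning", {
  ident <- checkDesignIndependence(diag(5))
  expect_equal(ident$rank, 5)
  expect_equal(ident$conditionNumber, 1)
  dup <- cbind(1:6, 1:6, rnorm(6))
  res <- checkDesignIndependence(dup)
  expect_equal(res$rank, 2)
  expect_false(res$fullRank)
  # The default session's FIR matrix has full task-column rank.
  dm <- buildDesignMatrix(generateSessionDesign(seed = 30))
  expect_true(checkDesignIndependence(dm$X)$fullRank)
})

test_that("stimulus selection matches the exhaustive sort oracle", {
  set.seed(42)
  ratings <- data.frame(id = sprintf("img%03d", 1:40),
                        valence = runif(40, 1, 9), arousal = runif(40, 1, 9))
  ratings$valence[1] <- 1; ratings$arousal[1] <- 9   # exactly at the target
  sel <- selectStimuli(ratings, nAversive = 5, nNeutral = 5)
  expect_equal(sel$aversive$id[1], "img001")
  expect_equal(sel$aversive$distance[1], 0)
  expect_length(intersect(sel$aversive$id, sel$neutral$id), 0)

  # Brute-force oracle: rank within valence strata by distance, tie by id.
  av <- ratings[ratings$valence <= 3.6, ]
  av$d <- sqrt((av$arousal - 9)^2 + (av$valence - 1)^2)
  av <- av[order(av$d, av$id), ]
  expect_equal(sel$aversive$id, av$id[1:5])
  ne <- ratings[ratings$valence > 3.6 & ratings$valence < 6.4, ]
  ne$d <- sqrt((ne$arousal - 1)^2 + (ne$valence - 5)^2)
  ne <- ne[order(ne$d, ne$id), ]
  expect_equal(sel$neutral$id, ne$id[1:5])
})

test_that("valence 3.6 is aversive-eligible but neutral-ineligible", {
  ratings <- data.frame(id = c("a", "b", "c", "d"),
                        valence = c(3.6, 3.6, 5, 5), arousal = c(8, 7, 1, 2))
  sel <- selectStimuli(ratings, nAversive = 2, nNeutral = 2)
  expect_setequal(sel$aversive$id, c("a", "b"))
  expect_error(selectStimuli(ratings, nAversive = 3, nNeutral = 1),
               "aversive")
})
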