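# Shared fixtures, built in code and memoized for the test run.

.fx <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# One-run miniature of the session design (same per-run trial mix as the
# full session: 21/20/5/5).
miniDesign <- function() fixture("miniDesign", generateSessionDesign(
  counts = c("neutral-go" = 21, "aversive-go" = 20,
             "neutral-nogo" = 5, "aversive-nogo" = 5),
  nRuns = 1, seed = 11))

miniAtlas <- function() fixture("miniAtlas",
                                generateAtlasFixture(c(10, 10, 6), 4, seed = 12))

miniCohort <- function(n = 8) fixture(paste0("cohort", n),
                                      generateCohort(n = n, nHigh = ceiling(n / 2),
                                                     seed = 13))

# A noiseless session with distinct per-type amplitudes, and its first-level
# fit: amplitudes (ng, ag, nn, an) = (1, 1, 2, 2) in every region.
noiselessSession <- function() fixture("noiselessSession", {
  eff <- effectSpec(4, amplitudes = matrix(c(1, 1, 2, 2), 4, 4, byrow = TRUE))
  generateBoldSession(miniCohort()[1, ], miniDesign(), eff, noiseSpec(sd = 0),
                      miniAtlas(), seed = 14)
})

noiselessFit <- function() fixture("noiselessFit",
                                   fitFirstLevel(noiselessSession(),
                                                 prewhiten = FALSE,
                                                 includeMotion = FALSE))

# Independent flood fill (stack-based, test-side oracle) returning sorted
# cluster sizes of a binary volume under face connectivity.
oracleClusterSizes <- function(bin) {
  d <- dim(bin)
  seen <- array(FALSE, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  sizes <- integer(0)
  for (start in which(bin)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ijk <- arrayInd(v, d)[1, ]
      for (k in seq_len(nrow(offs))) {
        nb <- ijk + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (bin[li] && !seen[li]) {
          seen[li] <- TRUE
          stack <- c(stack, li)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}
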