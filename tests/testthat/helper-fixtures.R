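## Shared fixture builders. All randomness is driven by the calling test's
## set.seed(); helpers never reseed.

## random mining corpus over the first `alphabetSize` letters
randomCorpus <- function(nSeq = 5L, maxLen = 30L, alphabetSize = 10L) {
  ab <- letters[seq_len(alphabetSize)]
  vapply(seq_len(nSeq), function(i) {
    paste(sample(ab, sample.int(maxLen, 1L), replace = TRUE),
          collapse = "")
  }, character(1L))
}

## a MovementTrace with explicit kinematic channels on the 0.1 s grid
kinematicTrace <- function(velocity, acceleration = NULL,
                           turning = NULL, latitude = NULL,
                           longitude = NULL, playerId = "p1",
                           matchId = "m1", position = "hooker") {
  fixes <- data.frame(time_s = 0.1 * (seq_along(velocity) - 1L),
                      velocity = velocity)
  if (!is.null(acceleration)) fixes$acceleration <- acceleration
  if (!is.null(turning)) fixes$turning_angle <- turning
  if (!is.null(latitude)) {
    fixes$latitude <- latitude
    fixes$longitude <- longitude
  }
  movementTrace(playerId, matchId, position, fixes)
}

## a PatternSet built directly from an item vector (support 1 each unless
## given), for feature-matrix tests that do not need real mining
presenceSet <- function(items, playerId, matchId, position,
                        algorithm = "LCCspm", corpusSize = 1L,
                        support = rep(1L, length(items))) {
  new("PatternSet", algorithm = algorithm,
      kind = c(LCCspm = "contiguous", LCS = "subsequence",
               AprioriClose = "itemset")[[algorithm]],
      playerId = playerId, matchId = matchId, position = position,
      corpusSize = as.integer(corpusSize),
      patterns = data.frame(items = items,
                            support_count = as.integer(support),
                            relative_support = support / corpusSize,
                            stringsAsFactors = FALSE))
}

## set-equality of two PatternSets including supports
expect_same_patterns <- function(a, b) {
  ta <- patternTable(a)
  tb <- patternTable(b)
  ta <- ta[order(ta$items), c("items", "support_count")]
  tb <- tb[order(tb$items), c("items", "support_count")]
  rownames(ta) <- rownames(tb) <- NULL
  expect_equal(ta, tb)
}

## spherical initial bearing, hand-coded as an independent oracle
oracleBearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (th * 180 / pi) %% 360
}
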