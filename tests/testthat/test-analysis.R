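test_that("Jaccard similarity matches direct set arithmetic", {
  expect_equal(jaccardSimilarity(c("ab", "cd"), c("ab", "cd")), 1)
  expect_equal(jaccardSimilarity(c("ab"), c("cd")), 0)
  expect_equal(jaccardSimilarity(c("ab", "cd"), c("ab", "ef")), 1 / 3)
  expect_error(jaccardSimilarity(character(), character()), "undefined")
  ## random sets against an independent formula
  set.seed(21)
  for (rep in 1:50) {
    x <- unique(replicate(sample(1:30, 1),
                          paste(sample(letters[1:5], 3, TRUE),
                                collapse = "")))
    y <- unique(replicate(sample(1:30, 1),
                          paste(sample(letters[1:5], 3, TRUE),
                                collapse = "")))
    expected <- sum(x %in% y) / length(unique(c(x, y)))
    expect_equal(jaccardSimilarity(x, y), expected)
    expect_equal(jaccardSimilarity(x, y), jaccardSimilarity(y, x))
    expect_equal(jaccardSimilarity(x, x), 1)
    ## |union| * J = |intersection|
    expect_equal(jaccardSimilarity(x, y) * length(unique(c(x, y))),
                 length(intersect(x, y)))
  }
})

test_that("Jaccard scores from the study's printed cardinalities", {
  ## |X| = 3881, |Y| = 2513, |X n Y| = 1022 -> 0.19 at 2 dp
  shared <- sprintf("s%04d", 1:1022)
  lcc <- c(shared, sprintf("c%04d", 1:(3881 - 1022)))
  lcs <- c(shared, sprintf("q%04d", 1:(2513 - 1022)))
  expect_equal(roundHalfUp(jaccardSimilarity(lcc, lcs), 2), 0.19)
  apr <- c(shared[1:32], sprintf("i%03d", 1:(155 - 32)))
  expect_equal(roundHalfUp(jaccardSimilarity(lcc, apr), 3), 0.008)
  aprLcs <- c(shared[1:25], sprintf("i%03d", 1:(155 - 25)))
  expect_equal(roundHalfUp(jaccardSimilarity(lcs, aprLcs), 3), 0.009)
})

test_that("exact overlap matches pattern strings across algorithms", {
  expect_equal(exactOverlap(c("ab", "cd"), c("ab", "ef")), "ab")
  expect_equal(exactOverlap(c("ab", "cd"), c("ab", "cd", "ef")),
               c("ab", "cd"))  # X subset of Y gives X
  ## a contiguous "ab" and the itemset printed "ab" compare equal: this is
  ## what makes cross-algorithm overlap informative
  contig <- unionPatternSets(list(presenceSet(c("ab", "ba"), "p1", "m1",
                                              "hooker")))
  itemset <- unionPatternSets(list(
    presenceSet("ab", "p1", "m1", "hooker", algorithm = "AprioriClose")))
  expect_equal(exactOverlap(contig, itemset), "ab")
  expect_equal(exactOverlap(contig, contig), c("ab", "ba"))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  u1 <- unionPatternSets(list(presenceSet(c("ab", "cd"), "p1", "m1",
                                          "hooker")))
  u2 <- unionPatternSets(list(presenceSet(c("ab", "ef"), "p1", "m1",
                                          "hooker", algorithm = "LCS")))
  m <- similarityMatrix(list(u1, u2))
  expect_equal(diag(m), c(LCCspm = 1, LCS = 1))
  expect_equal(m, t(m))
  ## {ab, cd} vs {ab, ef}: one of three distinct strings is shared
  expect_equal(m["LCCspm", "LCS"], 1 / 3)
})

test_that("top/bottom-k overlap follows the frequency rankings", {
  mkUnion <- function(items, freqs, algorithm = "LCCspm") {
    sets <- lapply(seq_len(max(freqs)), function(i) {
      present <- items[freqs >= i]
      presenceSet(present, sprintf("p%02d", i), "m1", "hooker",
                  algorithm = algorithm)
    })
    unionPatternSets(sets)
  }
  x <- mkUnion(c("aa", "bb", "cc", "dd"), c(9, 7, 2, 1))
  y <- mkUnion(c("aa", "zz", "yy", "cc"), c(8, 6, 3, 1))
  ## identical ranked sets, k >= size: overlap is the whole set
  full <- topBottomOverlap(x, x, k = 10)
  expect_setequal(full$top, c("aa", "bb", "cc", "dd"))
  expect_setequal(full$bottom, c("aa", "bb", "cc", "dd"))
  ## only the single most frequent pattern is shared at k = 1
  r <- topBottomOverlap(x, y, k = 1)
  expect_equal(r$top, "aa")
  expect_length(r$bottom, 0L)  # bottom ranks differ: dd vs cc
  ## sets sharing only below-k patterns: empty top-k overlap
  x2 <- mkUnion(c("aa", "bb", "ss"), c(5, 4, 1))
  y2 <- mkUnion(c("cc", "dd", "ss"), c(5, 4, 1))
  r2 <- topBottomOverlap(x2, y2, k = 2)
  expect_length(r2$top, 0L)
  expect_equal(r2$bottom, "ss")
  expect_error(topBottomOverlap(x, y, k = 0), "positive")
})

test_that("position partition counts obey the subtraction identities", {
  ## printed counts: 2282 and 3174 with 1575 shared -> 707 and 1599
  shared <- sprintf("s%04d", 1:1575)
  hook <- c(shared, sprintf("h%04d", 1:(2282 - 1575)))
  wing <- c(shared, sprintf("w%04d", 1:(3174 - 1575)))
  pt <- positionPartition(list(hooker = hook, winger = wing))
  expect_equal(unname(pt$counts[c("onlyA", "onlyB")]), c(707, 1599))
  ## 142 and 136 with 123 shared -> 19 and 13
  shared <- sprintf("s%03d", 1:123)
  pt2 <- positionPartition(list(
    hooker = c(shared, sprintf("h%02d", 1:19)),
    winger = c(shared, sprintf("w%02d", 1:13))))
  expect_equal(unname(pt2$counts[c("onlyA", "onlyB")]), c(19, 13))
  ## disjoint inputs
  pt3 <- positionPartition(list(a = c("x", "y"), b = c("z")))
  expect_equal(unname(pt3$counts), c(2, 1, 0, 2, 1))
  ## identities hold on random inputs
  set.seed(31)
  for (rep in 1:20) {
    a <- unique(replicate(sample(1:40, 1),
                          paste(sample(letters[1:6], 2, TRUE),
                                collapse = "")))
    b <- unique(replicate(sample(1:40, 1),
                          paste(sample(letters[1:6], 2, TRUE),
                                collapse = "")))
    p <- positionPartition(list(a = a, b = b))
    expect_equal(p$counts[["onlyA"]], p$counts[["A"]] - p$counts[["shared"]])
    expect_equal(p$counts[["onlyB"]], p$counts[["B"]] - p$counts[["shared"]])
  }
  expect_error(positionPartition(list(a = "x")), "two positions")
})

test_that("patterns can be partitioned by provenance position", {
  sets <- list(presenceSet(c("ab", "uv"), "h1", "m1", "hooker"),
               presenceSet(c("uv", "GS"), "w1", "m1", "winger"))
  un <- unionPatternSets(sets)
  byPos <- patternsByPosition(un)
  expect_setequal(byPos$hooker, c("ab", "uv"))
  expect_setequal(byPos$winger, c("uv", "GS"))
  pt <- positionPartition(byPos)
  expect_equal(unname(pt$counts[c("shared", "onlyA", "onlyB")]),
               c(1, 1, 1))
})

test_that("half-up rounding matches the printed-score convention", {
  expect_equal(roundHalfUp(0.1902, 2), 0.19)
  expect_equal(roundHalfUp(0.185, 2), 0.19)   # half rounds up, not to even
  expect_equal(roundHalfUp(0.0079920, 3), 0.008)
  expect_equal(roundHalfUp(26.33, 0), 26)
  expect_equal(roundHalfUp(-0.185, 2), -0.19)
})
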