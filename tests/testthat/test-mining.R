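test_that("closed contiguous mining handles the worked examples", {
  ## only "ab" survives closure: "a" and "b" extend to it with equal support
  ps <- lccspmMine(c("abab", "abc"), minsup = 1, l = 2)
  expect_equal(patternTable(ps),
               data.frame(items = "ab", support_count = 2L,
                          relative_support = 1))
  ## single symbol: nothing extends it
  ps <- lccspmMine("e", minsup = 1, l = 20)
  expect_equal(patternTable(ps)$items, "e")
  ## every shorter substring extends to a trigram of equal support
  ps <- lccspmMine("ijfeikhddb", minsup = 1, l = 3)
  expect_setequal(patternTable(ps)$items,
                  c("ijf", "jfe", "fei", "eik", "ikh", "khd", "hdd", "ddb"))
  expect_true(all(patternTable(ps)$support_count == 1L))
  expect_error(lccspmMine(character()), "empty")
  expect_error(lccspmMine("ab", minsup = 0), "minsup")
  expect_error(lccspmMine("ab", minsup = 1.2), "minsup")
})

test_that("closed contiguous miner agrees with its brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    corpus <- randomCorpus(nSeq = sample(1:8, 1), maxLen = 25,
                           alphabetSize = sample(3:8, 1))
    minsup <- sample(c(0.2, 0.4, 0.6, 1.0), 1)
    l <- sample(2:8, 1)
    expect_same_patterns(lccspmMine(corpus, minsup, l),
                         lccspmOracle(corpus, minsup, l))
  }
  ## minsup above the top support: both empty
  expect_equal(nrow(patternTable(lccspmMine(c("ab", "cd"), 1, 5))), 0L)
  expect_equal(nrow(patternTable(lccspmOracle(c("ab", "cd"), 1, 5))), 0L)
  expect_error(lccspmOracle(strrep("a", 20000)), "too large")
})

test_that("closed contiguous output satisfies support and closure", {
  set.seed(202)
  for (rep in 1:20) {
    corpus <- randomCorpus(nSeq = 6, maxLen = 30, alphabetSize = 5)
    minsup <- 0.5
    ps <- patternTable(lccspmMine(corpus, minsup, l = 6))
    if (!nrow(ps)) next
    ## every pattern occurs contiguously in >= ceil(minsup * n) sequences
    occ <- vapply(ps$items, function(p) {
      sum(vapply(corpus, function(s) grepl(p, s, fixed = TRUE),
                 logical(1)))
    }, integer(1))
    expect_equal(unname(occ), ps$support_count)
    expect_true(all(ps$support_count >= ceiling(minsup * length(corpus))))
    ## no pattern is a substring of another with equal support
    for (i in seq_len(nrow(ps))) {
      super <- ps$items[ps$support_count == ps$support_count[i] &
                        ps$items != ps$items[i]]
      expect_false(any(vapply(super, function(q) {
        grepl(ps$items[i], q, fixed = TRUE)
      }, logical(1))))
    }
  }
})

test_that("raising minsup never adds closed contiguous patterns", {
  set.seed(303)
  for (rep in 1:10) {
    corpus <- randomCorpus(nSeq = 8, maxLen = 25, alphabetSize = 4)
    lo <- patternTable(lccspmMine(corpus, 0.25, l = 5))$items
    hi <- patternTable(lccspmMine(corpus, 0.75, l = 5))$items
    expect_true(all(hi %in% lo))
  }
})

test_that("lcsPair returns a true longest common subsequence", {
  expect_identical(lcsPair("abc", "abc"), "abc")
  expect_identical(lcsPair("abc", "xyz"), "")
  expect_equal(nchar(lcsPair("ABCBDAB", "BDCABA")), 4L)
  ## classic DP length oracle, independent cell-by-cell implementation
  dpLen <- function(s, t) {
    a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
    L <- matrix(0L, length(a) + 1L, length(b) + 1L)
    for (i in seq_along(a)) for (j in seq_along(b)) {
      L[i + 1, j + 1] <- if (a[i] == b[j]) L[i, j] + 1L else
        max(L[i, j + 1], L[i + 1, j])
    }
    L[length(a) + 1L, length(b) + 1L]
  }
  isSubseq <- function(p, s) {
    if (!nchar(p)) return(TRUE)
    pos <- 0L
    for (ch in strsplit(p, "")[[1]]) {
      hits <- which(strsplit(s, "")[[1]] == ch)
      hits <- hits[hits > pos]
      if (!length(hits)) return(FALSE)
      pos <- hits[1]
    }
    TRUE
  }
  set.seed(11)
  for (rep in 1:100) {
    s <- paste(sample(letters[1:4], sample(0:25, 1), TRUE), collapse = "")
    t <- paste(sample(letters[1:4], sample(0:25, 1), TRUE), collapse = "")
    out <- lcsPair(s, t)
    expect_equal(nchar(out), dpLen(s, t))
    expect_true(isSubseq(out, s))
    expect_true(isSubseq(out, t))
    expect_identical(lcsPair(s, s), s)
  }
})

test_that("LCS mining folds clusters deterministically", {
  ## two identical sequences, one cluster: the sequence itself
  ps <- smpLcsMine(c("ijfeik", "ijfeik"), nClusters = 1)
  expect_equal(patternTable(ps)$items, "ijfeik")
  expect_equal(patternTable(ps)$support_count, 2L)
  ## singleton corpus: the fold over one member is the member
  ps <- smpLcsMine("eeff", nClusters = 25)
  expect_equal(patternTable(ps)$items, "eeff")
  ## two-sequence corpus, one cluster: a pattern of the DP length
  ps <- smpLcsMine(c("ABCBDAB", "BDCABA"), nClusters = 1)
  expect_equal(nchar(patternTable(ps)$items), 4L)
  expect_equal(patternTable(ps)$support_count, 2L)
  expect_error(smpLcsMine(character()), "empty")
  expect_error(smpLcsMine("ab", nClusters = 0), "nClusters")
  ## deterministic across calls
  set.seed(5)
  corpus <- randomCorpus(nSeq = 12, maxLen = 20, alphabetSize = 6)
  expect_equal(patternTable(smpLcsMine(corpus, 4)),
               patternTable(smpLcsMine(corpus, 4)))
})

test_that("closed itemset mining handles the worked examples", {
  ps <- aprioriCloseMine(c("abc", "ab", "bc"), minsup = 2 / 3)
  tab <- patternTable(ps)
  expect_setequal(tab$items, c("b", "ab", "bc"))
  expect_equal(tab$support_count[match(c("b", "ab", "bc"), tab$items)],
               c(3L, 2L, 2L))
  expect_equal(patternTable(aprioriCloseMine("a", 1))$items, "a")
  ## no universal item at minsup 1
  expect_equal(nrow(patternTable(aprioriCloseMine(c("ab", "cd"), 1))), 0L)
  ## single-sequence corpus: exactly one closed set, all its items
  expect_equal(patternTable(aprioriCloseMine("cba", 1))$items, "abc")
  expect_error(aprioriCloseMine(character()), "empty")
})

test_that("closed itemset miner agrees with its powerset oracle", {
  set.seed(404)
  for (rep in 1:60) {
    corpus <- randomCorpus(nSeq = sample(1:8, 1), maxLen = 20,
                           alphabetSize = sample(3:8, 1))
    minsup <- sample(c(0.2, 0.4, 0.6, 1.0), 1)
    expect_same_patterns(aprioriCloseMine(corpus, minsup),
                         aprioriCloseOracle(corpus, minsup))
  }
  long <- paste(letters[1:21], collapse = "")
  expect_error(aprioriCloseOracle(long), "alphabet too large")
})

test_that("itemset outputs are sorted, duplicate-free and closed", {
  set.seed(505)
  for (rep in 1:20) {
    corpus <- randomCorpus(nSeq = 6, maxLen = 15, alphabetSize = 6)
    tab <- patternTable(aprioriCloseMine(corpus, 0.3))
    expect_false(anyDuplicated(tab$items) > 0)
    for (it in tab$items) {
      ch <- strsplit(it, "")[[1]]
      expect_false(is.unsorted(ch, strictly = TRUE))
    }
    ## closure under a containment oracle
    for (i in seq_len(nrow(tab))) {
      chI <- strsplit(tab$items[i], "")[[1]]
      for (j in seq_len(nrow(tab))[-i]) {
        chJ <- strsplit(tab$items[j], "")[[1]]
        if (all(chI %in% chJ) && length(chJ) > length(chI)) {
          expect_lt(tab$support_count[j], tab$support_count[i])
        }
      }
    }
  }
})

test_that("the item-count filter drops only oversized patterns", {
  ps <- presenceSet(c(strrep("a", 5), strrep("ab", 10), strrep("abc", 7)),
                    "p1", "m1", "hooker")
  kept <- patternTable(filterMaxItems(ps, 20))$items
  expect_setequal(nchar(kept), c(5L, 20L))
  empty <- presenceSet(character(), "p1", "m1", "hooker")
  expect_equal(nrow(patternTable(filterMaxItems(empty))), 0L)
  expect_equal(patternTable(filterMaxItems(ps, 21)), patternTable(ps))
})

test_that("pattern-set union is duplicate-free with per-corpus provenance", {
  a <- presenceSet(c("ab"), "p1", "m1", "hooker")
  b <- presenceSet(c("ab", "cd"), "p2", "m1", "winger")
  un <- unionPatternSets(list(a, b))
  tab <- patternTable(un)
  expect_setequal(tab$items, c("ab", "cd"))
  expect_equal(tab$n_corpora[match(c("ab", "cd"), tab$items)], c(2L, 1L))
  prov <- provenance(un)[[match("ab", tab$items)]]
  expect_setequal(prov$player_id, c("p1", "p2"))
  ## disjoint sets: union size is the sum of sizes
  c1 <- presenceSet(c("ef", "gh"), "p3", "m1", "hooker")
  un2 <- unionPatternSets(list(b, c1))
  expect_equal(nrow(patternTable(un2)), 4L)
  ## mixed algorithm tags are rejected
  d <- presenceSet("ab", "p1", "m1", "hooker", algorithm = "AprioriClose")
  expect_error(unionPatternSets(list(a, d)), "mix")
})
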