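## Pattern mining: length-capped closed contiguous patterns, clustered
## longest-common-subsequence patterns, and frequent closed itemsets, with
## brute-force reference miners for each closure-based algorithm.

## All miners use sequence-level support: the number of sequences in the
## player-match corpus containing at least one occurrence of the pattern.

.checkMiningCorpus <- function(corpus) {
  stopifnot(is(corpus, "MovementCorpus") || is.character(corpus))
  seqs <- if (is.character(corpus)) corpus else corpus@sequences
  if (!length(seqs)) stop("cannot mine an empty corpus")
  if (any(!nzchar(seqs))) stop("corpus contains empty sequences")
  seqs
}

.asCorpus <- function(corpus) {
  if (is(corpus, "MovementCorpus")) return(corpus)
  ## plain character vectors are wrapped for convenience in tests/examples
  new("MovementCorpus", playerId = "corpus", matchId = "corpus",
      position = "unknown", sequences = as.character(corpus))
}

.checkMinsup <- function(minsup) {
  if (!is.numeric(minsup) || length(minsup) != 1L || is.na(minsup) ||
      minsup <= 0 || minsup > 1) {
    stop("minsup must be a fraction in (0, 1]")
  }
  invisible(minsup)
}

## distinct substrings of s with length <= l
.substringsUpTo <- function(s, l) {
  n <- nchar(s)
  out <- vector("list", min(l, n))
  for (len in seq_len(min(l, n))) {
    out[[len]] <- unique(substring(s, 1:(n - len + 1L), len:n))
  }
  unique(unlist(out, use.names = FALSE))
}

.orderPatterns <- function(df) {
  df <- df[order(-df$support_count, df$items), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Mine length-capped closed contiguous patterns (LCCspm)
#'
#' Finds all contiguous patterns (substrings) of at most \code{l} movement
#' units whose sequence support in the corpus is at least \code{minsup}, and
#' keeps only the closed ones: a frequent pattern is discarded when some
#' frequent contiguous super-pattern of length at most \code{l} has an
#' identical support count. Patterns of exactly \code{l} units cannot be
#' extended within the cap and are therefore closed whenever frequent.
#'
#' Closure is decided by single-character extensions: any super-pattern with
#' equal support is reachable through a chain of one-character extensions
#' whose supports are sandwiched between the two, so checking the immediate
#' left/right extensions suffices.
#'
#' @param corpus a \linkS4class{MovementCorpus} (or plain character vector
#'   of sequences).
#' @param minsup minimum sequence support as a fraction in (0, 1]
#'   (default 0.05).
#' @param l maximum pattern length in movement units (default 20, i.e. a
#'   2 s window at 10 Hz).
#' @return A \linkS4class{PatternSet} with algorithm tag \code{"LCCspm"},
#'   ordered by decreasing support then items.
#' @examples
#' patternTable(lccspmMine(c("abab", "abc"), minsup = 1, l = 2))
#' @export
lccspmMine <- function(corpus, minsup = 0.05, l = 20L) {
  seqs <- .checkMiningCorpus(corpus)
  .checkMinsup(minsup)
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 1) {
    stop("l must be a positive integer")
  }
  l <- as.integer(l)
  n <- length(seqs)
  perSeq <- lapply(seqs, .substringsUpTo, l = l)
  tab <- table(unlist(perSeq, use.names = FALSE))
  cnt <- as.integer(tab)
  pats <- names(tab)
  frequent <- cnt / n >= minsup - 1e-12
  pats <- pats[frequent]
  cnt <- cnt[frequent]
  closed <- rep(TRUE, length(pats))
  if (length(pats)) {
    supp <- stats::setNames(cnt, pats)
    long <- pats[nchar(pats) >= 2L]
    if (length(long)) {
      extCnt <- supp[long]
      pre <- substr(long, 1L, nchar(long) - 1L)
      i <- match(pre, pats)
      hit <- !is.na(i) & cnt[i] == extCnt
      closed[i[hit]] <- FALSE
      suf <- substr(long, 2L, nchar(long))
      j <- match(suf, pats)
      hit <- !is.na(j) & cnt[j] == extCnt
      closed[j[hit]] <- FALSE
    }
  }
  df <- .orderPatterns(data.frame(items = pats[closed],
                                  support_count = cnt[closed],
                                  relative_support = cnt[closed] / n,
                                  stringsAsFactors = FALSE))
  .patternSet("LCCspm", .asCorpus(corpus), df)
}

#' Brute-force reference miner for closed contiguous patterns
#'
#' Exhaustive enumeration: every substring of every sequence (up to the
#' length cap) is support-counted against the whole corpus with
#' \code{grepl(fixed = TRUE)}, and closure is checked against every frequent
#' super-string, not just one-character extensions. Intentionally naive and
#' independent of [lccspmMine()]; guarded to small corpora.
#'
#' @inheritParams lccspmMine
#' @param maxSymbols refuse corpora with more total symbols than this.
#' @return A \linkS4class{PatternSet} with algorithm tag \code{"LCCspm"}.
#' @export
lccspmOracle <- function(corpus, minsup = 0.05, l = 20L,
                         maxSymbols = 10000L) {
  seqs <- .checkMiningCorpus(corpus)
  .checkMinsup(minsup)
  if (sum(nchar(seqs)) > maxSymbols) {
    stop("corpus too large for the brute-force reference miner")
  }
  n <- length(seqs)
  cand <- character()
  for (s in seqs) {
    ns <- nchar(s)
    for (i in seq_len(ns)) {
      for (j in i:min(ns, i + l - 1L)) {
        cand <- c(cand, substr(s, i, j))
      }
    }
  }
  cand <- unique(cand)
  supp <- vapply(cand, function(p) {
    sum(vapply(seqs, function(s) grepl(p, s, fixed = TRUE), logical(1L)))
  }, integer(1L))
  keep <- supp / n >= minsup - 1e-12
  cand <- cand[keep]
  supp <- supp[keep]
  closed <- vapply(seq_along(cand), function(k) {
    p <- cand[k]
    sup <- cand[nchar(cand) > nchar(p) & supp == supp[k]]
    !any(vapply(sup, function(q) grepl(p, q, fixed = TRUE), logical(1L)))
  }, logical(1L))
  df <- .orderPatterns(data.frame(items = cand[closed],
                                  support_count = unname(supp[closed]),
                                  relative_support = unname(supp[closed]) / n,
                                  stringsAsFactors = FALSE))
  .patternSet("LCCspm", .asCorpus(corpus), df)
}

#' Longest common subsequence of two strings
#'
#' Standard dynamic programme; ties during the backtrack are broken by a
#' fixed rule (skip a character of the first argument when both directions
#' give the same length), so the output is deterministic. Its length always
#' equals the DP table value.
#'
#' @param s,t character strings.
#' @return A longest common subsequence of \code{s} and \code{t} (possibly
#'   the empty string).
#' @examples
#' lcsPair("ABCBDAB", "BDCABA")  # length 4
#' @export
lcsPair <- function(s, t) {
  a <- .chars(s)
  b <- .chars(t)
  n <- length(a)
  m <- length(b)
  if (n == 0L || m == 0L) return("")
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    eq <- as.integer(a[i] == b)
    cand <- pmax(L[i, 2:(m + 1L)], L[i, 1:m] + eq)
    L[i + 1L, ] <- c(0L, cummax(cand))
  }
  out <- character(0L)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j]) {
      out <- c(a[i], out)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  paste(out, collapse = "")
}

## is p a (not necessarily contiguous) subsequence of s?
.isSubsequence <- function(p, s) {
  if (!nchar(p)) return(TRUE)
  pc <- .chars(p)
  sc <- .chars(s)
  k <- 1L
  for (ch in sc) {
    if (ch == pc[k]) {
      k <- k + 1L
      if (k > length(pc)) return(TRUE)
    }
  }
  FALSE
}

#' Mine longest-common-subsequence patterns (SMP-style)
#'
#' Clusters the corpus sequences into \code{min(nClusters, n)} groups by
#' complete-linkage agglomerative clustering on normalised edit distance
#' (Levenshtein distance divided by the longer length), then folds
#' [lcsPair()] progressively over each cluster's members in a deterministic
#' order (decreasing length, then lexicographic). Each cluster contributes
#' its common pattern; empty folds are dropped and duplicates merged.
#' Support is the number of corpus sequences containing the pattern as a
#' subsequence. Patterns longer than the downstream item cap are removed by
#' [filterMaxItems()], not here.
#'
#' @param corpus a \linkS4class{MovementCorpus} or character vector.
#' @param nClusters number of clusters (default 25).
#' @return A \linkS4class{PatternSet} with algorithm tag \code{"LCS"}.
#' @export
smpLcsMine <- function(corpus, nClusters = 25L) {
  seqs <- .checkMiningCorpus(corpus)
  if (!is.numeric(nClusters) || nClusters < 1) {
    stop("nClusters must be a positive integer")
  }
  n <- length(seqs)
  k <- min(as.integer(nClusters), n)
  cl <- if (n == 1L) {
    1L
  } else {
    d <- utils::adist(seqs) / outer(nchar(seqs), nchar(seqs), pmax)
    stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                  k = k)
  }
  pats <- character(0L)
  for (g in sort(unique(cl))) {
    members <- seqs[cl == g]
    members <- members[order(-nchar(members), members)]
    acc <- members[1L]
    for (s in members[-1L]) {
      acc <- lcsPair(acc, s)
      if (!nzchar(acc)) break
    }
    if (nzchar(acc)) pats <- c(pats, acc)
  }
  pats <- unique(pats)
  if (!length(pats)) {
    df <- data.frame(items = character(), support_count = integer(),
                     relative_support = numeric())
  } else {
    supp <- vapply(pats, function(p) {
      sum(vapply(seqs, function(s) .isSubsequence(p, s), logical(1L)))
    }, integer(1L))
    df <- .orderPatterns(data.frame(items = pats,
                                    support_count = unname(supp),
                                    relative_support = unname(supp) / n,
                                    stringsAsFactors = FALSE))
  }
  .patternSet("LCS", .asCorpus(corpus), df)
}

## transactions: list of strictly sorted character vectors, one per sequence
.transactions <- function(seqs) {
  lapply(strsplit(seqs, "", fixed = TRUE), function(ch) sort(unique(ch)))
}

.itemsetSupport <- function(sets, trans) {
  items <- sort(unique(unlist(trans, use.names = FALSE)))
  inc <- vapply(trans, function(tr) items %in% tr,
                logical(length(items)))  # items x transactions
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(items))
  vapply(sets, function(s) {
    idx <- match(s, items)
    if (anyNA(idx)) return(0L)
    sub <- inc[idx, , drop = FALSE]
    sum(colSums(sub) == length(idx))
  }, integer(1L))
}

#' Mine frequent closed itemsets (AprioriClose)
#'
#' Each sequence is reduced to its set of distinct movement-unit characters
#' (a transaction); the miner returns every itemset whose sequence support
#' is at least \code{minsup} and that is closed: no proper frequent superset
#' has the same support count. Items within a pattern are reported in
#' lexicographic order.
#'
#' The implementation enumerates closed itemsets directly as the
#' intersection-closure of the transaction family (every closed itemset is
#' an intersection of the transactions that contain it), then support-counts
#' and filters; this is exact and avoids the level-wise candidate sweep.
#'
#' @param corpus a \linkS4class{MovementCorpus} or character vector.
#' @param minsup minimum sequence support fraction in (0, 1] (default 0.05).
#' @param maxClosed safety cap on the closure family size.
#' @return A \linkS4class{PatternSet} with algorithm tag
#'   \code{"AprioriClose"}.
#' @examples
#' patternTable(aprioriCloseMine(c("abc", "ab", "bc"), minsup = 2 / 3))
#' @export
aprioriCloseMine <- function(corpus, minsup = 0.05, maxClosed = 50000L) {
  seqs <- .checkMiningCorpus(corpus)
  .checkMinsup(minsup)
  n <- length(seqs)
  trans <- .transactions(seqs)
  keys <- vapply(trans, paste, character(1L), collapse = "")
  fam <- trans[!duplicated(keys)]
  famKeys <- unique(keys)
  ## intersection fixpoint
  repeat {
    added <- FALSE
    nf <- length(fam)
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        x <- intersect(fam[[i]], fam[[j]])
        if (!length(x)) next
        kx <- paste(x, collapse = "")
        if (!(kx %in% famKeys)) {
          fam[[length(fam) + 1L]] <- x
          famKeys <- c(famKeys, kx)
          added <- TRUE
          if (length(fam) > maxClosed) {
            stop("closed-itemset family exceeds maxClosed; ",
                 "raise minsup or maxClosed")
          }
        }
      }
    }
    if (!added) break
  }
  supp <- .itemsetSupport(fam, trans)
  keep <- supp / n >= minsup - 1e-12
  fam <- fam[keep]
  supp <- supp[keep]
  items <- vapply(fam, paste, character(1L), collapse = "")
  df <- .orderPatterns(data.frame(items = items, support_count = supp,
                                  relative_support = supp / n,
                                  stringsAsFactors = FALSE))
  .patternSet("AprioriClose", .asCorpus(corpus), df)
}

#' Brute-force reference miner for frequent closed itemsets
#'
#' Enumerates the full powerset of the observed alphabet (bitmask
#' enumeration), support-counts every subset, keeps the frequent ones and
#' drops any with a proper frequent superset of identical support.
#' Independent of [aprioriCloseMine()]; refuses alphabets larger than
#' \code{maxAlphabet}.
#'
#' @inheritParams aprioriCloseMine
#' @param maxAlphabet refuse corpora whose observed alphabet exceeds this.
#' @return A \linkS4class{PatternSet} with algorithm tag
#'   \code{"AprioriClose"}.
#' @export
aprioriCloseOracle <- function(corpus, minsup = 0.05, maxAlphabet = 20L) {
  seqs <- .checkMiningCorpus(corpus)
  .checkMinsup(minsup)
  n <- length(seqs)
  trans <- .transactions(seqs)
  items <- sort(unique(unlist(trans, use.names = FALSE)))
  k <- length(items)
  if (k > maxAlphabet) {
    stop("observed alphabet too large for the powerset reference miner")
  }
  masks <- seq_len(2L^k - 1L)
  transMask <- vapply(trans, function(tr) {
    sum(2L^(match(tr, items) - 1L))
  }, numeric(1L))
  supp <- vapply(masks, function(m) {
    sum(bitwAnd(transMask, m) == m)
  }, integer(1L))
  keep <- supp / n >= minsup - 1e-12
  masks <- masks[keep]
  supp <- supp[keep]
  closed <- vapply(seq_along(masks), function(i) {
    m <- masks[i]
    super <- masks != m & bitwAnd(masks, m) == m
    !any(supp[super] == supp[i])
  }, logical(1L))
  itemStr <- vapply(masks[closed], function(m) {
    paste(items[bitwAnd(m, 2L^(seq_len(k) - 1L)) > 0L], collapse = "")
  }, character(1L))
  df <- .orderPatterns(data.frame(items = itemStr,
                                  support_count = supp[closed],
                                  relative_support = supp[closed] / n,
                                  stringsAsFactors = FALSE))
  .patternSet("AprioriClose", .asCorpus(corpus), df)
}

#' Drop patterns with more than a maximum number of items
#'
#' The study caps usable patterns at 20 items; the LCCspm length cap
#' enforces this during mining, while LCS and AprioriClose outputs are
#' filtered afterwards. Supports are untouched.
#'
#' @param ps a \linkS4class{PatternSet}.
#' @param maxItems maximum item count (default 20).
#' @return The filtered \linkS4class{PatternSet}.
#' @export
filterMaxItems <- function(ps, maxItems = 20L) {
  stopifnot(is(ps, "PatternSet"))
  p <- ps@patterns
  ps@patterns <- p[nchar(p$items) <= maxItems, , drop = FALSE]
  rownames(ps@patterns) <- NULL
  validObject(ps)
  ps
}

#' Union of pattern sets with per-corpus provenance
#'
#' The mathematical union of all per-corpus pattern sets of one algorithm:
#' a duplicate-free collection of unique patterns, each recording the
#' player-matches it was extracted from and its support there. Pattern
#' identity is (kind, items); supports vary by corpus and live in the
#' provenance.
#'
#' @param patternSets list of \linkS4class{PatternSet} objects sharing one
#'   algorithm tag.
#' @return A \linkS4class{PatternUnion}.
#' @export
unionPatternSets <- function(patternSets) {
  if (!length(patternSets)) stop("need at least one pattern set")
  stopifnot(all(vapply(patternSets, is, logical(1L), "PatternSet")))
  tags <- unique(vapply(patternSets, algorithmTag, character(1L)))
  if (length(tags) != 1L) {
    stop("pattern sets mix algorithm tags: ", paste(tags, collapse = ", "))
  }
  rows <- do.call(rbind, lapply(patternSets, function(ps) {
    p <- ps@patterns
    if (!nrow(p)) return(NULL)
    data.frame(items = p$items, support_count = p$support_count,
               relative_support = p$relative_support,
               player_id = ps@playerId, match_id = ps@matchId,
               position = ps@position, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(new("PatternUnion", algorithm = tags,
               kind = unname(.KIND_FOR_ALGORITHM[tags]),
               patterns = data.frame(items = character(),
                                     n_corpora = integer()),
               provenance = list()))
  }
  byPattern <- split(rows[c("player_id", "match_id", "position",
                            "support_count", "relative_support")],
                     rows$items)
  items <- names(byPattern)
  prov <- lapply(byPattern, function(d) {
    rownames(d) <- NULL
    d[c("player_id", "match_id", "position", "support_count",
        "relative_support")]
  })
  names(prov) <- NULL
  new("PatternUnion", algorithm = tags,
      kind = unname(.KIND_FOR_ALGORITHM[tags]),
      patterns = data.frame(items = items,
                            n_corpora = vapply(prov, nrow, integer(1L)),
                            stringsAsFactors = FALSE),
      provenance = prov)
}
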