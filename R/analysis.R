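## Pattern-set comparison: Jaccard similarity, exact-match overlap,
## most/least-frequent-k overlap, and per-position partitions.

## Cross-set comparison uses the exact-matching convention: a pattern is
## identified by its item string, so a contiguous "uv" and the itemset
## {u, v} (printed "uv") compare equal across algorithms. This is what
## makes cross-algorithm similarity and overlap informative at all;
## within one algorithm the kind is constant and the question never
## arises.
.identityKeys <- function(x) {
  if (is(x, "PatternUnion") || is(x, "PatternSet")) {
    x@patterns$items
  } else {
    as.character(x)
  }
}

#' Jaccard similarity of two pattern sets
#'
#' \eqn{J(X, Y) = |X \cap Y| / |X \cup Y|}: 0 means no shared pattern,
#' 1 an exact match. Inputs may be \linkS4class{PatternUnion}s (compared by
#' exact matching of pattern item strings) or plain character vectors.
#'
#' @param x,y pattern collections.
#' @return Jaccard score in \code{[0, 1]}.
#' @examples
#' jaccardSimilarity(c("ab", "cd"), c("ab", "ef"))  # 1/3
#' @export
jaccardSimilarity <- function(x, y) {
  kx <- unique(.identityKeys(x))
  ky <- unique(.identityKeys(y))
  u <- length(union(kx, ky))
  if (u == 0L) stop("Jaccard similarity is undefined for two empty sets")
  length(intersect(kx, ky)) / u
}

#' Pairwise Jaccard similarity matrix of pattern unions
#'
#' @param unions named list of \linkS4class{PatternUnion}s (names default to
#'   the algorithm tags).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarityMatrix <- function(unions) {
  if (is.null(names(unions))) {
    names(unions) <- vapply(unions, algorithmTag, character(1L))
  }
  k <- length(unions)
  m <- diag(1, k)
  dimnames(m) <- list(names(unions), names(unions))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        m[i, j] <- m[j, i] <- jaccardSimilarity(unions[[i]], unions[[j]])
      }
    }
  }
  m
}

#' Exact-match overlap of two pattern collections
#'
#' Set intersection of pattern item strings (the exact matching method), so
#' patterns of different structural kinds overlap whenever they print the
#' same string.
#'
#' @param x,y pattern collections (unions or character vectors).
#' @return Character vector of overlapping pattern items.
#' @export
exactOverlap <- function(x, y) {
  sort(intersect(unique(.identityKeys(x)), unique(.identityKeys(y))))
}

.rankedItems <- function(un, decreasing) {
  p <- un@patterns
  ## ties: frequency, then lexicographic item order
  if (decreasing) {
    p <- p[order(-p$n_corpora, p$items), , drop = FALSE]
  } else {
    p <- p[order(p$n_corpora, p$items), , drop = FALSE]
  }
  p
}

#' Overlap among the most and least frequent k patterns of two unions
#'
#' Each side is ranked by how many player-match corpora extracted the
#' pattern; overlaps are computed separately among the k most frequent and
#' the k least frequent patterns of each side. Frequency ties are broken
#' lexicographically.
#'
#' @param x,y \linkS4class{PatternUnion}s.
#' @param k patterns taken from each end of each ranking (default 50).
#' @return A list with elements \code{top} and \code{bottom} (overlapping
#'   items), \code{ranksX}, \code{ranksY} (full frequency rankings as
#'   data.frames with \code{items}, \code{n_corpora}, \code{rank}) and
#'   \code{k}.
#' @export
topBottomOverlap <- function(x, y, k = 50L) {
  stopifnot(is(x, "PatternUnion"), is(y, "PatternUnion"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("k must be a positive integer")
  }
  k <- as.integer(k)
  rx <- .rankedItems(x, decreasing = TRUE)
  ry <- .rankedItems(y, decreasing = TRUE)
  rx$rank <- seq_len(nrow(rx))
  ry$rank <- seq_len(nrow(ry))
  topX <- utils::head(rx$items, k)
  topY <- utils::head(ry$items, k)
  botX <- utils::head(.rankedItems(x, decreasing = FALSE)$items, k)
  botY <- utils::head(.rankedItems(y, decreasing = FALSE)$items, k)
  list(top = sort(intersect(topX, topY)),
       bottom = sort(intersect(botX, botY)),
       ranksX = rx, ranksY = ry, k = k)
}

#' Partition patterns by playing position
#'
#' Splits the patterns of one algorithm into those extracted for both
#' positions and those unique to each. The counts obey
#' \code{|A only| = |A| - |shared|} and \code{|B only| = |B| - |shared|}.
#'
#' @param patternsByPosition named list of exactly two pattern collections
#'   (character vectors of items, or \linkS4class{PatternUnion}s).
#' @return A list with \code{positions}, \code{shared}, \code{onlyA},
#'   \code{onlyB} (item vectors) and a \code{counts} named vector
#'   (\code{A}, \code{B}, \code{shared}, \code{onlyA}, \code{onlyB}).
#' @examples
#' positionPartition(list(hooker = c("ab", "uv"), winger = c("uv", "GS")))
#' @export
positionPartition <- function(patternsByPosition) {
  if (length(patternsByPosition) != 2L) {
    stop("exactly two positions are required")
  }
  if (is.null(names(patternsByPosition))) {
    names(patternsByPosition) <- c("A", "B")
  }
  a <- unique(.identityKeys(patternsByPosition[[1L]]))
  b <- unique(.identityKeys(patternsByPosition[[2L]]))
  shared <- intersect(a, b)
  onlyA <- setdiff(a, b)
  onlyB <- setdiff(b, a)
  list(positions = names(patternsByPosition),
       shared = sort(shared), onlyA = sort(onlyA), onlyB = sort(onlyB),
       counts = c(A = length(a), B = length(b), shared = length(shared),
                  onlyA = length(onlyA), onlyB = length(onlyB)))
}

#' Patterns of a union by the positions that performed them
#'
#' Uses the union's provenance to collect, per position label, the patterns
#' extracted from at least one corpus of that position.
#'
#' @param un a \linkS4class{PatternUnion} with full provenance.
#' @return Named list of item vectors, one per position label.
#' @export
patternsByPosition <- function(un) {
  stopifnot(is(un, "PatternUnion"))
  pos <- sort(unique(unlist(lapply(un@provenance, function(d) d$position))))
  out <- lapply(pos, function(p) {
    hit <- vapply(un@provenance, function(d) p %in% d$position, logical(1L))
    un@patterns$items[hit]
  })
  names(out) <- pos
  out
}

#' Round half-up to a fixed number of decimals
#'
#' Reporting helper matching the convention used for printed scores
#' (\code{roundHalfUp(0.1902, 2)} is 0.19, \code{roundHalfUp(0.0095, 3)} is
#' 0.01): exact halves round away from zero rather than to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
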