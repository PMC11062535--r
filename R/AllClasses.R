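## S4 classes for the movement-profiling pipeline.

#' @import methods
#' @importFrom stats runif rpois setNames sd predict as.dist hclust cutree
#' @importFrom utils read.csv write.csv head adist packageVersion
NULL

.ALGORITHM_TAGS <- c("LCCspm", "LCS", "AprioriClose")
.KIND_FOR_ALGORITHM <- c(
  LCCspm = "contiguous",
  LCS = "subsequence",
  AprioriClose = "itemset"
)

## ---------------------------------------------------------------- traces ----

#' MovementTrace: one player-match GPS recording
#'
#' Timestamped kinematic samples for one player in one match, on a strict
#' 0.1 s (10 Hz) grid. The \code{fixes} data.frame must contain \code{time_s}
#' and \code{velocity} (m/s); \code{acceleration} (m/s^2), \code{latitude}/
#' \code{longitude} (decimal degrees) and \code{turning_angle} (degrees,
#' 0--180) are optional, but discretization needs either a turning-angle
#' channel or coordinates, and either an acceleration channel or the
#' velocity-derived fallback.
#'
#' @slot playerId character scalar.
#' @slot matchId character scalar.
#' @slot position character scalar, e.g. \code{"hooker"} or \code{"winger"}.
#' @slot fixes data.frame of samples in time order.
#' @export
setClass("MovementTrace",
  slots = c(
    playerId = "character",
    matchId = "character",
    position = "character",
    fixes = "data.frame"
  )
)

setValidity("MovementTrace", function(object) {
  f <- object@fixes
  msg <- character()
  for (s in c("playerId", "matchId", "position")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      msg <- c(msg, sprintf("'%s' must be a non-empty scalar", s))
    }
  }
  if (!all(c("time_s", "velocity") %in% names(f))) {
    msg <- c(msg, "fixes must have columns 'time_s' and 'velocity'")
  } else if (nrow(f) == 0L) {
    msg <- c(msg, "fixes must be non-empty")
  } else {
    if (anyNA(f$velocity) || any(f$velocity < 0)) {
      msg <- c(msg, "velocity must be non-negative and non-missing")
    }
    if (nrow(f) > 1L) {
      dt <- diff(f$time_s)
      if (any(abs(dt - 0.1) > 1e-6)) {
        msg <- c(msg, "time_s must increase in constant 0.1 s steps")
      }
    }
    if ("turning_angle" %in% names(f)) {
      ta <- f$turning_angle[!is.na(f$turning_angle)]
      if (any(ta < 0 | ta > 180)) {
        msg <- c(msg, "turning_angle must lie in [0, 180]")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MovementTrace
#'
#' @param playerId,matchId,position identifiers for the player-match.
#' @param fixes data.frame of 10 Hz samples (see \linkS4class{MovementTrace}).
#' @return A \linkS4class{MovementTrace}.
#' @export
movementTrace <- function(playerId, matchId, position, fixes) {
  new("MovementTrace",
      playerId = as.character(playerId), matchId = as.character(matchId),
      position = as.character(position),
      fixes = as.data.frame(fixes, stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------- corpus ----

#' MovementCorpus: the discrete movement sequences of one player-match
#'
#' After discretization and inactive-period splitting, a player-match is
#' represented by an ordered set of movement sequences (character strings
#' over the 48-symbol alphabet). This is the unit over which patterns are
#' mined ("player-per-fixture" granularity).
#'
#' @slot playerId,matchId,position identifiers shared by all sequences.
#' @slot sequences character vector of movement sequences; element order is
#'   the segment order within the match. May be empty if the whole trace was
#'   inactive.
#' @export
setClass("MovementCorpus",
  slots = c(
    playerId = "character",
    matchId = "character",
    position = "character",
    sequences = "character"
  )
)

setValidity("MovementCorpus", function(object) {
  msg <- character()
  if (length(object@sequences)) {
    if (any(!nzchar(object@sequences))) {
      msg <- c(msg, "sequences must be non-empty strings")
    } else {
      ok <- tryCatch({.assertAlphabet(object@sequences); TRUE},
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) msg <- c(msg, ok)
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MovementCorpus
#'
#' @param playerId,matchId,position identifiers.
#' @param sequences character vector of movement sequences in segment order.
#' @return A \linkS4class{MovementCorpus}.
#' @export
movementCorpus <- function(playerId, matchId, position, sequences) {
  new("MovementCorpus",
      playerId = as.character(playerId), matchId = as.character(matchId),
      position = as.character(position), sequences = as.character(sequences))
}

## ------------------------------------------------------------- patterns ----

#' PatternSet: mined patterns of one algorithm on one corpus
#'
#' @slot algorithm one of \code{"LCCspm"}, \code{"LCS"},
#'   \code{"AprioriClose"}.
#' @slot kind pattern kind implied by the algorithm: \code{"contiguous"},
#'   \code{"subsequence"} or \code{"itemset"}.
#' @slot playerId,matchId,position corpus identifiers.
#' @slot corpusSize number of sequences in the mined corpus.
#' @slot patterns data.frame with columns \code{items} (pattern string;
#'   lexicographically sorted distinct characters for itemsets),
#'   \code{support_count} and \code{relative_support}.
#' @export
setClass("PatternSet",
  slots = c(
    algorithm = "character",
    kind = "character",
    playerId = "character",
    matchId = "character",
    position = "character",
    corpusSize = "integer",
    patterns = "data.frame"
  )
)

setValidity("PatternSet", function(object) {
  msg <- character()
  if (!(object@algorithm %in% .ALGORITHM_TAGS)) {
    msg <- c(msg, sprintf("algorithm must be one of: %s",
                          paste(.ALGORITHM_TAGS, collapse = ", ")))
  } else if (!identical(object@kind,
                        unname(.KIND_FOR_ALGORITHM[object@algorithm]))) {
    msg <- c(msg, "kind does not match algorithm")
  }
  p <- object@patterns
  req <- c("items", "support_count", "relative_support")
  if (!all(req %in% names(p))) {
    msg <- c(msg, sprintf("patterns must have columns: %s",
                          paste(req, collapse = ", ")))
  } else if (nrow(p)) {
    if (anyDuplicated(p$items)) msg <- c(msg, "duplicate patterns in set")
    if (any(p$support_count < 1L) ||
        any(p$support_count > object@corpusSize)) {
      msg <- c(msg, "support_count must lie in [1, corpusSize]")
    }
    if (any(abs(p$relative_support - p$support_count / object@corpusSize) >
            1e-9)) {
      msg <- c(msg, "relative_support must equal support_count / corpusSize")
    }
    if (object@kind == "itemset") {
      srt <- vapply(strsplit(p$items, "", fixed = TRUE), function(ch) {
        !anyDuplicated(ch) && !is.unsorted(ch, strictly = TRUE)
      }, logical(1L))
      if (!all(srt)) {
        msg <- c(msg, "itemset items must be strictly increasing characters")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

.patternSet <- function(algorithm, corpus, patterns) {
  patterns <- as.data.frame(patterns, stringsAsFactors = FALSE)
  rownames(patterns) <- NULL
  new("PatternSet",
      algorithm = algorithm,
      kind = unname(.KIND_FOR_ALGORITHM[algorithm]),
      playerId = corpus@playerId, matchId = corpus@matchId,
      position = corpus@position,
      corpusSize = length(corpus@sequences),
      patterns = patterns)
}

## --------------------------------------------------------------- unions ----

#' PatternUnion: duplicate-free union of pattern sets of one algorithm
#'
#' The mathematical union of all per-corpus pattern sets of one algorithm,
#' with per-corpus provenance: for every unique pattern, the player-matches
#' it was extracted from and its support there. The number of source corpora
#' (\code{n_corpora}) is the cross-corpus frequency used for ranking.
#'
#' @slot algorithm,kind as in \linkS4class{PatternSet}.
#' @slot patterns data.frame with columns \code{items}, \code{n_corpora}.
#' @slot provenance list parallel to \code{patterns} rows; each element a
#'   data.frame with columns \code{player_id}, \code{match_id},
#'   \code{position}, \code{support_count}, \code{relative_support}.
#' @export
setClass("PatternUnion",
  slots = c(
    algorithm = "character",
    kind = "character",
    patterns = "data.frame",
    provenance = "list"
  )
)

setValidity("PatternUnion", function(object) {
  msg <- character()
  p <- object@patterns
  if (!all(c("items", "n_corpora") %in% names(p))) {
    msg <- c(msg, "patterns must have columns 'items' and 'n_corpora'")
  } else {
    if (anyDuplicated(p$items)) msg <- c(msg, "duplicate patterns in union")
    if (nrow(p) != length(object@provenance)) {
      msg <- c(msg, "provenance must be parallel to patterns")
    } else if (nrow(p)) {
      n <- vapply(object@provenance, nrow, integer(1L))
      if (!identical(as.integer(p$n_corpora), n)) {
        msg <- c(msg, "n_corpora must equal provenance size")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

## ----------------------------------------------------------- archetypes ----

#' PositionArchetype: generative model for one playing position
#'
#' A first-order Markov chain over the 48 movement-unit characters plus a
#' list of motifs (short unit strings) inserted as atomic blocks at a given
#' rate, used by the synthetic cohort generator to emulate position-specific
#' movement styles.
#'
#' @slot label position label, e.g. \code{"hooker"}.
#' @slot transition 48 x 48 row-stochastic matrix, dimnames = alphabet.
#' @slot init initial state distribution over the 48 characters.
#' @slot motifs data.frame with columns \code{motif} (unit string) and
#'   \code{rate} (insertions per 100 emitted symbols); may have zero rows.
#' @export
setClass("PositionArchetype",
  slots = c(
    label = "character",
    transition = "matrix",
    init = "numeric",
    motifs = "data.frame"
  )
)

setValidity("PositionArchetype", function(object) {
  msg <- character()
  P <- object@transition
  ab <- .ALPHABET_CHARS
  if (!all(dim(P) == c(48L, 48L)) ||
      !identical(rownames(P), ab) || !identical(colnames(P), ab)) {
    msg <- c(msg, "transition must be 48x48 with alphabet dimnames")
  } else {
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
      msg <- c(msg, "transition rows must be non-negative and sum to 1")
    }
  }
  if (length(object@init) != 48L || any(object@init < 0) ||
      abs(sum(object@init) - 1) > 1e-9) {
    msg <- c(msg, "init must be a length-48 probability vector")
  }
  m <- object@motifs
  if (!all(c("motif", "rate") %in% names(m))) {
    msg <- c(msg, "motifs must have columns 'motif' and 'rate'")
  } else if (nrow(m)) {
    ok <- tryCatch({.assertAlphabet(m$motif); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (any(m$rate < 0)) msg <- c(msg, "motif rates must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PositionArchetype
#'
#' @param label position label.
#' @param transition 48 x 48 row-stochastic matrix over the alphabet.
#' @param init initial distribution; default uniform.
#' @param motifs data.frame(motif, rate); default none.
#' @return A \linkS4class{PositionArchetype}.
#' @export
positionArchetype <- function(label, transition,
                              init = rep(1 / 48, 48),
                              motifs = data.frame(motif = character(),
                                                  rate = numeric())) {
  if (is.null(dimnames(transition))) {
    dimnames(transition) <- list(.ALPHABET_CHARS, .ALPHABET_CHARS)
  }
  new("PositionArchetype", label = as.character(label),
      transition = transition, init = init,
      motifs = as.data.frame(motifs, stringsAsFactors = FALSE))
}

## ------------------------------------------------------------ accessors ----

#' @rdname accessors
#' @param object a MoveMiner S4 object.
#' @export
setGeneric("playerId", function(object) standardGeneric("playerId"))
#' @rdname accessors
#' @export
setGeneric("matchId", function(object) standardGeneric("matchId"))
#' @rdname accessors
#' @export
setGeneric("positionLabel", function(object) standardGeneric("positionLabel"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("gpsFixes", function(object) standardGeneric("gpsFixes"))
#' @rdname accessors
#' @export
setGeneric("algorithmTag", function(object) standardGeneric("algorithmTag"))
#' @rdname accessors
#' @export
setGeneric("patternKind", function(object) standardGeneric("patternKind"))
#' @rdname accessors
#' @export
setGeneric("patternTable", function(object) standardGeneric("patternTable"))
#' @rdname accessors
#' @export
setGeneric("patternItems", function(object) standardGeneric("patternItems"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Accessors for MoveMiner classes
#'
#' \code{playerId}, \code{matchId}, \code{positionLabel} return corpus/trace
#' identifiers; \code{sequences} the movement sequences of a corpus;
#' \code{gpsFixes} the fix table of a trace; \code{algorithmTag},
#' \code{patternKind}, \code{patternTable}, \code{patternItems} and
#' \code{provenance} the components of mined pattern sets and unions.
#'
#' @name accessors
#' @rdname accessors
NULL

setMethod("playerId", "MovementTrace", function(object) object@playerId)
setMethod("playerId", "MovementCorpus", function(object) object@playerId)
setMethod("playerId", "PatternSet", function(object) object@playerId)
setMethod("matchId", "MovementTrace", function(object) object@matchId)
setMethod("matchId", "MovementCorpus", function(object) object@matchId)
setMethod("matchId", "PatternSet", function(object) object@matchId)
setMethod("positionLabel", "MovementTrace", function(object) object@position)
setMethod("positionLabel", "MovementCorpus", function(object) object@position)
setMethod("positionLabel", "PatternSet", function(object) object@position)
setMethod("positionLabel", "PositionArchetype", function(object) object@label)
setMethod("sequences", "MovementCorpus", function(object) object@sequences)
setMethod("gpsFixes", "MovementTrace", function(object) object@fixes)
setMethod("algorithmTag", "PatternSet", function(object) object@algorithm)
setMethod("algorithmTag", "PatternUnion", function(object) object@algorithm)
setMethod("patternKind", "PatternSet", function(object) object@kind)
setMethod("patternKind", "PatternUnion", function(object) object@kind)
setMethod("patternTable", "PatternSet", function(object) object@patterns)
setMethod("patternTable", "PatternUnion", function(object) object@patterns)
setMethod("patternItems", "PatternSet", function(object) object@patterns$items)
setMethod("patternItems", "PatternUnion",
          function(object) object@patterns$items)
setMethod("provenance", "PatternUnion", function(object) object@provenance)

## ----------------------------------------------------------------- show ----

setMethod("show", "MovementTrace", function(object) {
  cat(sprintf("MovementTrace: player %s, match %s (%s)\n",
              object@playerId, object@matchId, object@position))
  cat(sprintf("  %d fixes at 10 Hz (%.1f s), channels: %s\n",
              nrow(object@fixes), nrow(object@fixes) / 10,
              paste(names(object@fixes), collapse = ", ")))
})

setMethod("show", "MovementCorpus", function(object) {
  n <- length(object@sequences)
  cat(sprintf("MovementCorpus: player %s, match %s (%s)\n",
              object@playerId, object@matchId, object@position))
  cat(sprintf("  %d discrete sequence(s), %d movement units in total\n",
              n, if (n) sum(nchar(object@sequences)) else 0L))
})

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet [%s, %s]: player %s, match %s (%s)\n",
              object@algorithm, object@kind,
              object@playerId, object@matchId, object@position))
  cat(sprintf("  %d pattern(s) over a corpus of %d sequence(s)\n",
              nrow(object@patterns), object@corpusSize))
  if (nrow(object@patterns)) {
    print(utils::head(object@patterns, 5L))
    if (nrow(object@patterns) > 5L) cat("  ...\n")
  }
})

setMethod("show", "PatternUnion", function(object) {
  cat(sprintf("PatternUnion [%s, %s]: %d unique pattern(s)\n",
              object@algorithm, object@kind, nrow(object@patterns)))
  if (nrow(object@patterns)) {
    print(utils::head(object@patterns[order(-object@patterns$n_corpora,
                                            object@patterns$items), ], 5L))
    if (nrow(object@patterns) > 5L) cat("  ...\n")
  }
})

setMethod("show", "PositionArchetype", function(object) {
  cat(sprintf("PositionArchetype '%s': 48-state movement-unit Markov chain\n",
              object@label))
  if (nrow(object@motifs)) {
    cat(sprintf("  motifs: %s\n",
                paste(sprintf("%s (%.3g/100 units)", object@motifs$motif,
                              object@motifs$rate), collapse = ", ")))
  } else {
    cat("  no planted motifs\n")
  }
})
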