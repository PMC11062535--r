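## File formats: GPS CSV, sequence TSV, pattern TSV.

.GPS_REQUIRED <- c("time_s", "velocity", "player_id", "match_id", "position")
.GPS_OPTIONAL <- c("acceleration", "latitude", "longitude", "turning_angle")

#' Read a GPS CSV into movement traces
#'
#' Expected dialect: UTF-8 CSV with header; required columns \code{time_s},
#' \code{velocity}, \code{player_id}, \code{match_id}, \code{position};
#' optional columns \code{acceleration}, \code{latitude}, \code{longitude},
#' \code{turning_angle}. Rows are grouped by player and match and ordered by
#' time within each group.
#'
#' @param path path to the CSV file.
#' @return Named list of \linkS4class{MovementTrace} objects
#'   (\code{"player.match"} keys).
#' @export
readGpsCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(.GPS_REQUIRED, names(df))
  if (length(missing)) {
    stop("GPS CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  keys <- paste(df$player_id, df$match_id, sep = ".")
  lapply(split(df, factor(keys, levels = unique(keys))), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    cols <- intersect(c("time_s", "velocity", .GPS_OPTIONAL), names(g))
    movementTrace(g$player_id[1L], g$match_id[1L], g$position[1L],
                  g[, cols, drop = FALSE])
  })
}

#' Write movement traces as a GPS CSV
#'
#' Inverse of [readGpsCsv()]: concatenates the fix tables of all traces with
#' their identifier columns into the documented CSV dialect.
#'
#' @param traces list of \linkS4class{MovementTrace} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGpsCsv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    f <- tr@fixes
    f$player_id <- tr@playerId
    f$match_id <- tr@matchId
    f$position <- tr@position
    f
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(f) {
    for (cl in setdiff(cols, names(f))) f[[cl]] <- NA
    f[, cols, drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write movement corpora to a sequence TSV
#'
#' One record per discrete movement sequence: tab-separated columns
#' \code{player_id}, \code{match_id}, \code{position}, \code{segment},
#' \code{symbols}.
#'
#' @param corpora list of \linkS4class{MovementCorpus} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSequenceTsv <- function(corpora, path) {
  rows <- lapply(corpora, function(cp) {
    if (!length(cp@sequences)) return(NULL)
    data.frame(player_id = cp@playerId, match_id = cp@matchId,
               position = cp@position,
               segment = seq_along(cp@sequences),
               symbols = cp@sequences, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(player_id = character(), match_id = character(),
                     position = character(), segment = integer(),
                     symbols = character())
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sequence TSV back into movement corpora
#'
#' @param path path written by [writeSequenceTsv()].
#' @return Named list of \linkS4class{MovementCorpus} objects.
#' @export
readSequenceTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(symbols = "character"))
  req <- c("player_id", "match_id", "position", "segment", "symbols")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("sequence TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  keys <- paste(df$player_id, df$match_id, sep = ".")
  lapply(split(df, factor(keys, levels = unique(keys))), function(g) {
    g <- g[order(g$segment), , drop = FALSE]
    movementCorpus(g$player_id[1L], g$match_id[1L], g$position[1L],
                   g$symbols)
  })
}

#' Write per-corpus pattern sets to a pattern TSV
#'
#' Columns: \code{algorithm}, \code{kind}, \code{items},
#' \code{support_count}, \code{relative_support}, \code{player_id},
#' \code{match_id}, \code{position}.
#'
#' @param patternSets list of \linkS4class{PatternSet} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePatternTsv <- function(patternSets, path) {
  rows <- lapply(patternSets, function(ps) {
    p <- ps@patterns
    if (!nrow(p)) return(NULL)
    data.frame(algorithm = ps@algorithm, kind = ps@kind, items = p$items,
               support_count = p$support_count,
               relative_support = p$relative_support,
               player_id = ps@playerId, match_id = ps@matchId,
               position = ps@position, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(algorithm = character(), kind = character(),
                     items = character(), support_count = integer(),
                     relative_support = numeric(), player_id = character(),
                     match_id = character(), position = character())
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pattern union to TSV
#'
#' Columns: \code{algorithm}, \code{kind}, \code{items}, \code{n_corpora}.
#'
#' @param un a \linkS4class{PatternUnion}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeUnionTsv <- function(un, path) {
  p <- un@patterns
  df <- data.frame(algorithm = rep(un@algorithm, nrow(p)),
                   kind = rep(un@kind, nrow(p)),
                   items = p$items, n_corpora = p$n_corpora,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_corpora, df$items), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pattern union TSV
#'
#' Rebuilds a \linkS4class{PatternUnion} from [writeUnionTsv()] output.
#' The TSV stores only the cross-corpus frequency, so the per-pattern
#' provenance tables come back with the right row counts but unidentified
#' (\code{NA}) corpora; ranking and set comparison work unchanged.
#'
#' @param path path written by [writeUnionTsv()].
#' @return A \linkS4class{PatternUnion} with frequency-only provenance.
#' @export
readUnionTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(items = "character"))
  req <- c("algorithm", "kind", "items", "n_corpora")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("union TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  alg <- unique(df$algorithm)
  if (length(alg) != 1L) stop("union TSV must hold exactly one algorithm")
  prov <- lapply(as.integer(df$n_corpora), function(n) {
    data.frame(player_id = rep(NA_character_, n),
               match_id = rep(NA_character_, n),
               position = rep(NA_character_, n),
               support_count = rep(NA_integer_, n),
               relative_support = rep(NA_real_, n))
  })
  new("PatternUnion",
      algorithm = alg,
      kind = unname(.KIND_FOR_ALGORITHM[alg]),
      patterns = data.frame(items = df$items,
                            n_corpora = as.integer(df$n_corpora),
                            stringsAsFactors = FALSE),
      provenance = prov)
}
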