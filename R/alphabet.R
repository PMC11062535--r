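## Movement-unit alphabet: 48 descriptor triples <-> single characters.

.VELOCITY_BANDS <- c("Walk", "Jog", "Run", "Sprint")
.ACCELERATION_BANDS <- c("Deceleration", "Neutral", "Acceleration")
.TURNING_BANDS <- c("Straight", "Acute-change", "Large-change", "Backwards")
.ALPHABET_CHARS <- c(letters, LETTERS[1:22])

#' The 48-symbol movement-unit alphabet
#'
#' Each 0.1 s GPS sample is summarised by a descriptor triple (velocity band,
#' acceleration band, turning-angle band) and encoded as a single character.
#' With 4 velocity, 3 acceleration and 4 turning bands there are 48 triples,
#' mapped bijectively onto \code{"a"}--\code{"z"} then \code{"A"}--\code{"V"}.
#' The enumeration is velocity-major (Walk < Jog < Run < Sprint), acceleration
#' in the middle (Deceleration < Neutral < Acceleration) and turning-angle
#' minor (Straight < Acute-change < Large-change < Backwards), so e.g.
#' \code{"a"} is Walk/Deceleration/Straight, \code{"e"} Walk/Neutral/Straight,
#' \code{"u"} Jog/Acceleration/Straight and \code{"S"}
#' Sprint/Acceleration/Straight.
#'
#' @return A data.frame with columns \code{char}, \code{velocity},
#'   \code{acceleration}, \code{turning}, one row per movement unit, in
#'   alphabet order.
#' @examples
#' ab <- movementAlphabet()
#' ab[ab$char == "i", ]  # Walk / Acceleration / Straight
#' @export
movementAlphabet <- function() {
  grid <- expand.grid(
    turning = .TURNING_BANDS,
    acceleration = .ACCELERATION_BANDS,
    velocity = .VELOCITY_BANDS,
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  data.frame(
    char = .ALPHABET_CHARS,
    velocity = grid$velocity,
    acceleration = grid$acceleration,
    turning = grid$turning,
    stringsAsFactors = FALSE
  )
}

#' Encode descriptor triples as movement-unit characters
#'
#' Vectorised over the three band vectors (recycled to a common length).
#'
#' @param velocity character vector of velocity bands
#'   (\code{"Walk"}, \code{"Jog"}, \code{"Run"}, \code{"Sprint"}).
#' @param acceleration character vector of acceleration bands
#'   (\code{"Deceleration"}, \code{"Neutral"}, \code{"Acceleration"}).
#' @param turning character vector of turning bands (\code{"Straight"},
#'   \code{"Acute-change"}, \code{"Large-change"}, \code{"Backwards"}).
#' @return Character vector of single movement-unit characters.
#' @examples
#' encodeUnit("Walk", "Acceleration", "Straight")   # "i"
#' encodeUnit("Sprint", "Acceleration", "Backwards") # "V"
#' @seealso [decodeUnit()], [movementAlphabet()]
#' @export
encodeUnit <- function(velocity, acceleration, turning) {
  vi <- match(velocity, .VELOCITY_BANDS)
  ai <- match(acceleration, .ACCELERATION_BANDS)
  ti <- match(turning, .TURNING_BANDS)
  if (anyNA(vi)) stop("unknown velocity band: ",
                      paste(unique(velocity[is.na(vi)]), collapse = ", "))
  if (anyNA(ai)) stop("unknown acceleration band: ",
                      paste(unique(acceleration[is.na(ai)]), collapse = ", "))
  if (anyNA(ti)) stop("unknown turning band: ",
                      paste(unique(turning[is.na(ti)]), collapse = ", "))
  .ALPHABET_CHARS[12L * (vi - 1L) + 4L * (ai - 1L) + ti]
}

#' Decode movement-unit characters back to descriptor triples
#'
#' @param char character vector of single alphabet characters.
#' @return data.frame with columns \code{char}, \code{velocity},
#'   \code{acceleration}, \code{turning}.
#' @export
decodeUnit <- function(char) {
  idx <- match(char, .ALPHABET_CHARS)
  if (anyNA(idx)) {
    stop("character(s) outside the movement-unit alphabet: ",
         paste(unique(char[is.na(idx)]), collapse = ", "))
  }
  k <- idx - 1L
  data.frame(
    char = char,
    velocity = .VELOCITY_BANDS[k %/% 12L + 1L],
    acceleration = .ACCELERATION_BANDS[(k %% 12L) %/% 4L + 1L],
    turning = .TURNING_BANDS[k %% 4L + 1L],
    stringsAsFactors = FALSE
  )
}

## split a sequence string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.assertAlphabet <- function(symbols) {
  bad <- setdiff(unique(unlist(strsplit(symbols, "", fixed = TRUE))),
                 .ALPHABET_CHARS)
  if (length(bad)) {
    stop("symbols outside the movement-unit alphabet: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
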