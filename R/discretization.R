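## Discretization of 10 Hz GPS kinematics into movement-unit sequences.

#' Velocity band of a speed sample
#'
#' Band thresholds (m/s): Walk \code{[0, 1.70)}, Jog \code{[1.70, 3.90]},
#' Run \code{(3.90, 5.00)}, Sprint \code{[5.00, Inf)}. Note the Jog band is
#' closed at 3.90 and the Run band open below it.
#'
#' @param v numeric vector of speeds in m/s, non-negative.
#' @return character vector of velocity bands.
#' @examples
#' bandVelocity(c(0, 1.7, 3.9, 3.95, 5))
#' @export
bandVelocity <- function(v) {
  if (anyNA(v) || any(!is.finite(v))) stop("velocity must be finite")
  if (any(v < 0)) stop("velocity must be non-negative")
  out <- character(length(v))
  out[v < 1.70] <- "Walk"
  out[v >= 1.70 & v <= 3.90] <- "Jog"
  out[v > 3.90 & v < 5.00] <- "Run"
  out[v >= 5.00] <- "Sprint"
  out
}

#' Acceleration band of an acceleration sample
#'
#' Thresholds (m/s^2): Deceleration \code{(-Inf, -0.20]}, Neutral
#' \code{(-0.20, 0.20)}, Acceleration \code{[0.20, Inf)}.
#'
#' @param a numeric vector of accelerations in m/s^2.
#' @return character vector of acceleration bands.
#' @examples
#' bandAcceleration(c(-0.2, 0, 0.2))
#' @export
bandAcceleration <- function(a) {
  if (anyNA(a) || any(!is.finite(a))) stop("acceleration must be finite")
  out <- character(length(a))
  out[a <= -0.20] <- "Deceleration"
  out[a > -0.20 & a < 0.20] <- "Neutral"
  out[a >= 0.20] <- "Acceleration"
  out
}

#' Turning-angle band of a heading change
#'
#' Thresholds (degrees): Straight \code{[0, 10)}, Acute-change
#' \code{[10, 45)}, Large-change \code{[45, 90)}, Backwards \code{[90, 180]}.
#'
#' @param theta numeric vector of absolute heading changes in degrees,
#'   in \code{[0, 180]}.
#' @return character vector of turning bands.
#' @examples
#' bandTurning(c(0, 10, 45, 90, 180))
#' @export
bandTurning <- function(theta) {
  if (anyNA(theta) || any(!is.finite(theta))) {
    stop("turning angle must be finite")
  }
  if (any(theta < 0 | theta > 180)) {
    stop("turning angle must lie in [0, 180] degrees")
  }
  out <- character(length(theta))
  out[theta < 10] <- "Straight"
  out[theta >= 10 & theta < 45] <- "Acute-change"
  out[theta >= 45 & theta < 90] <- "Large-change"
  out[theta >= 90] <- "Backwards"
  out
}

#' Turning angles along a coordinate track
#'
#' Absolute change in heading, in degrees folded into \code{[0, 180]}, at
#' every fix of a latitude/longitude track sampled at 10 Hz. The heading
#' into fix \eqn{k} is the initial great-circle bearing from fix
#' \eqn{k - 1} to fix \eqn{k}; the turning angle at fix \eqn{k} is the
#' absolute difference between the headings into and out of it. The first
#' and last fix cannot form a three-fix corner and get angle 0. When a
#' displacement is shorter than \code{motionEps} metres the previous moving
#' heading is carried over (angle 0 if the track has not yet moved).
#'
#' @param latitude,longitude numeric vectors of decimal degrees.
#' @param motionEps minimum displacement in metres counted as motion.
#' @return numeric vector of angles in \code{[0, 180]}, same length as the
#'   input.
#' @export
turningAngles <- function(latitude, longitude, motionEps = 0.01) {
  n <- length(latitude)
  if (length(longitude) != n) stop("latitude/longitude length mismatch")
  if (anyNA(latitude) || anyNA(longitude)) {
    stop("coordinates must be non-missing to derive turning angles")
  }
  if (n < 3L) return(numeric(n))
  p <- cbind(longitude, latitude)
  step <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
  brg <- geosphere::bearing(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
  ## carry the last moving heading across stationary steps
  heading <- rep(NA_real_, n - 1L)
  last <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (step[i] >= motionEps) last <- brg[i]
    heading[i] <- last
  }
  ang <- numeric(n)
  for (k in 2:(n - 1L)) {
    h1 <- heading[k - 1L]
    h2 <- heading[k]
    if (is.na(h1) || is.na(h2)) next  # never moved yet: angle 0
    d <- abs((h2 - h1 + 180) %% 360 - 180)
    ang[k] <- min(d, 180)
  }
  ang
}

#' Acceleration derived from the velocity channel
#'
#' Central finite difference of the 10 Hz velocity series; one-sided
#' differences at the endpoints. Used when the device acceleration channel
#' is absent.
#'
#' @param velocity numeric vector of speeds (m/s), length >= 2.
#' @param dt sampling interval in seconds (default 0.1).
#' @return numeric vector of accelerations (m/s^2), same length.
#' @export
deriveAcceleration <- function(velocity, dt = 0.1) {
  n <- length(velocity)
  if (n < 2L) stop("need at least two fixes to derive acceleration")
  a <- numeric(n)
  a[1L] <- (velocity[2L] - velocity[1L]) / dt
  a[n] <- (velocity[n] - velocity[n - 1L]) / dt
  if (n > 2L) {
    a[2:(n - 1L)] <- (velocity[3:n] - velocity[1:(n - 2L)]) / (2 * dt)
  }
  a
}

#' Encode aligned kinematic channels as a movement-unit string
#'
#' Low-level vectorised encoder: each sample's velocity, acceleration and
#' turning angle are banded and the descriptor triple mapped to its alphabet
#' character. Empty inputs give an empty string.
#'
#' @param velocity,acceleration numeric vectors (m/s, m/s^2).
#' @param turning numeric vector of turning angles in degrees.
#' @return A single character string, one symbol per sample.
#' @export
encodeMovement <- function(velocity, acceleration, turning) {
  n <- length(velocity)
  if (length(acceleration) != n || length(turning) != n) {
    stop("velocity, acceleration and turning must be aligned")
  }
  if (n == 0L) return("")
  units <- tryCatch(
    encodeUnit(bandVelocity(velocity), bandAcceleration(acceleration),
               bandTurning(turning)),
    error = function(e) stop("banding failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  paste(units, collapse = "")
}

#' Discretize a GPS trace into a continuous movement-unit string
#'
#' Each 0.1 s fix becomes one movement-unit character. The acceleration
#' channel is used when present, otherwise it is derived from velocity by
#' finite differences; the turning-angle channel is used when present,
#' otherwise it is derived from coordinates via [turningAngles()]. A trace
#' with neither turning angles nor coordinates cannot be discretized.
#'
#' @param trace a \linkS4class{MovementTrace}.
#' @param motionEps minimum displacement (m) treated as motion when turning
#'   angles are derived from coordinates.
#' @return A character string with one symbol per fix.
#' @examples
#' csv <- system.file("extdata", "worked_example_gps_synthetic.csv",
#'                    package = "MoveMiner")
#' tr <- readGpsCsv(csv)[[1]]
#' discretizeTrace(tr)  # "ijfeikhddb"
#' @export
discretizeTrace <- function(trace, motionEps = 0.01) {
  stopifnot(is(trace, "MovementTrace"))
  f <- trace@fixes
  v <- f$velocity
  a <- if (!is.null(f$acceleration) && !anyNA(f$acceleration)) {
    f$acceleration
  } else if (length(v) >= 2L) {
    deriveAcceleration(v)
  } else {
    0  # single fix, no velocity change observable
  }
  theta <- if (!is.null(f$turning_angle) && !anyNA(f$turning_angle)) {
    f$turning_angle
  } else if (!is.null(f$latitude) && !is.null(f$longitude)) {
    turningAngles(f$latitude, f$longitude, motionEps = motionEps)
  } else {
    stop("trace for player ", trace@playerId, ", match ", trace@matchId,
         " has neither a turning_angle channel nor coordinates")
  }
  encodeMovement(v, a, theta)
}

#' Split a movement-unit string at inactive periods
#'
#' Maximal runs in which velocity stays below \code{vMin} for at least
#' \code{tMin} seconds are treated as inactive and deleted; the remaining
#' maximal runs become the discrete movement sequences of the player-match.
#' Shorter sub-threshold dips are kept (they are ordinary slow movement).
#'
#' @param symbols movement-unit string, one character per fix.
#' @param velocity numeric vector aligned with \code{symbols}.
#' @param vMin inactivity velocity threshold in m/s (default 0.2).
#' @param tMin minimum sustained duration in seconds (default 2.0).
#' @param dt sampling interval in seconds (default 0.1).
#' @return Character vector of discrete sequences, in time order; may be
#'   empty when the whole trace is inactive.
#' @export
splitInactive <- function(symbols, velocity, vMin = 0.2, tMin = 2.0,
                          dt = 0.1) {
  n <- nchar(symbols)
  if (n != length(velocity)) {
    stop("symbols and velocity must be aligned")
  }
  if (n == 0L) return(character())
  minRun <- ceiling(tMin / dt)
  r <- rle(velocity < vMin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inactive <- r$values & r$lengths >= minRun
  keep <- rep(TRUE, n)
  for (i in which(inactive)) keep[starts[i]:ends[i]] <- FALSE
  if (!any(keep)) return(character())
  kr <- rle(keep)
  ke <- cumsum(kr$lengths)
  ks <- ke - kr$lengths + 1L
  idx <- which(kr$values)
  substring(symbols, ks[idx], ke[idx])
}

#' Discretize and split a trace into a movement corpus
#'
#' Convenience wrapper: [discretizeTrace()] followed by [splitInactive()],
#' yielding the player-per-fixture corpus over which patterns are mined.
#'
#' @inheritParams discretizeTrace
#' @inheritParams splitInactive
#' @return A \linkS4class{MovementCorpus}.
#' @export
makeCorpus <- function(trace, vMin = 0.2, tMin = 2.0, motionEps = 0.01) {
  symbols <- discretizeTrace(trace, motionEps = motionEps)
  segs <- splitInactive(symbols, trace@fixes$velocity,
                        vMin = vMin, tMin = tMin)
  movementCorpus(trace@playerId, trace@matchId, trace@position, segs)
}
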