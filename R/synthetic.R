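## Synthetic cohorts: position-specific Markov movement dynamics with
## planted motifs and inactive gaps, invertible back to GPS traces.

## Table of band intervals used when inverting symbols to numbers. Open
## bounds are shrunk by eps; unbounded ends are capped (9 m/s, +-4 m/s^2).
.bandInterval <- function(kind, band, eps, vmax = 9, amax = 4) {
  switch(kind,
    velocity = switch(band,
      Walk = c(0, 1.70 - eps), Jog = c(1.70, 3.90),
      Run = c(3.90 + eps, 5.00 - eps), Sprint = c(5.00, vmax)),
    acceleration = switch(band,
      Deceleration = c(-amax, -0.20), Neutral = c(-0.20 + eps, 0.20 - eps),
      Acceleration = c(0.20, amax)),
    turning = switch(band,
      Straight = c(0, 10 - eps), `Acute-change` = c(10, 45 - eps),
      `Large-change` = c(45, 90 - eps), Backwards = c(90, 180))
  )
}

## transition kernel: velocity changes smoothly, the acceleration band
## agrees with the sign of the velocity change, turning is mostly straight,
## and speedBias sets the long-run time in each velocity band
.buildTransition <- function(speedBias) {
  stopifnot(length(speedBias) == 4L, all(speedBias > 0))
  ab <- movementAlphabet()
  vi <- match(ab$velocity, .VELOCITY_BANDS)
  ai <- match(ab$acceleration, .ACCELERATION_BANDS)
  ti <- match(ab$turning, .TURNING_BANDS)
  wTurn <- c(0.55, 0.30, 0.10, 0.05)
  wVel <- c(1, 0.25, 0.03, 0.005)
  P <- matrix(0, 48L, 48L, dimnames = list(.ALPHABET_CHARS, .ALPHABET_CHARS))
  for (s in 1:48) {
    dv <- vi - vi[s]
    wa <- ifelse(dv > 0, c(0.05, 0.20, 0.75)[ai],
                 ifelse(dv < 0, c(0.75, 0.20, 0.05)[ai],
                        c(0.25, 0.50, 0.25)[ai]))
    w <- wVel[abs(dv) + 1L] * wa * wTurn[ti] * speedBias[vi]
    P[s, ] <- w / sum(w)
  }
  P
}

#' Default position archetypes for synthetic cohorts
#'
#' Two \linkS4class{PositionArchetype}s emulating the tactical contrast of
#' the study's positions: the hooker archetype spends most time in walk/jog
#' bands with jog-flavoured motifs (\code{"uuv"}, \code{"mnm"}), the winger
#' archetype carries substantial run/sprint time with sprint-flavoured
#' motifs (\code{"GSS"}, \code{"TST"}). The motif sets are disjoint.
#'
#' @param motifRate motif insertions per 100 emitted symbols (default 2).
#' @return Named list of two archetypes (\code{hooker}, \code{winger}).
#' @export
defaultArchetypes <- function(motifRate = 2) {
  hookerP <- .buildTransition(c(0.50, 0.38, 0.08, 0.04))
  wingerP <- .buildTransition(c(0.30, 0.28, 0.22, 0.20))
  init <- function(P) {
    ## approximate stationary distribution by power iteration
    p <- rep(1 / 48, 48)
    for (i in 1:50) p <- as.numeric(p %*% P)
    p / sum(p)
  }
  list(
    hooker = positionArchetype("hooker", hookerP, init(hookerP),
      motifs = data.frame(motif = c("uuv", "mnm"),
                          rate = motifRate, stringsAsFactors = FALSE)),
    winger = positionArchetype("winger", wingerP, init(wingerP),
      motifs = data.frame(motif = c("GSS", "TST"),
                          rate = motifRate, stringsAsFactors = FALSE))
  )
}

#' Sample a movement-unit sequence from an archetype
#'
#' Draws a first-order Markov sample of \code{length} symbols and then
#' inserts each motif as an atomic block at Poisson-distributed random
#' positions (expected \code{rate} insertions per 100 base symbols), so the
#' returned string is \code{length} plus the inserted motif symbols long.
#' Uses the global RNG; seed outside for reproducibility.
#'
#' @param archetype a \linkS4class{PositionArchetype}.
#' @param length number of base symbols to sample (>= 1).
#' @return A movement-unit character string.
#' @export
sampleUnitSequence <- function(archetype, length) {
  stopifnot(is(archetype, "PositionArchetype"))
  if (length < 1L) stop("length must be >= 1")
  validObject(archetype)
  P <- archetype@transition
  n <- as.integer(length)
  states <- integer(n)
  states[1L] <- sample.int(48L, 1L, prob = archetype@init)
  for (i in seq_len(n - 1L)) {
    states[i + 1L] <- sample.int(48L, 1L, prob = P[states[i], ])
  }
  out <- .ALPHABET_CHARS[states]
  m <- archetype@motifs
  if (nrow(m)) {
    ## positions drawn once over all motifs, inserted right-to-left so the
    ## earlier indices stay valid and blocks remain atomic
    ins <- do.call(rbind, lapply(seq_len(nrow(m)), function(k) {
      cnt <- stats::rpois(1L, m$rate[k] * n / 100)
      if (!cnt) return(NULL)
      data.frame(at = sample.int(n + 1L, cnt, replace = TRUE),
                 motif = m$motif[k], stringsAsFactors = FALSE)
    }))
    if (!is.null(ins) && nrow(ins)) {
      ins <- ins[order(-ins$at), , drop = FALSE]
      for (r in seq_len(nrow(ins))) {
        at <- ins$at[r]
        out <- append(out, .chars(ins$motif[r]), after = at - 1L)
      }
    }
  }
  paste(out, collapse = "")
}

#' Invert a movement-unit string to a GPS trace
#'
#' For each symbol, emits kinematic values drawn uniformly inside the
#' symbol's descriptor bands (open bounds shrunk by \code{eps}; the
#' unbounded velocity and acceleration ends capped at \code{vmax} and
#' \code{amax}). In \code{"angle"} mode the turning angle is written as a
#' device channel, so discretizing the trace returns exactly the input
#' string. In \code{"coordinate"} mode latitude/longitude are synthesised
#' to realise the turning angles as heading changes (turn direction chosen
#' at random); the first and last symbol's turning band should then be
#' Straight, since a three-fix corner cannot be formed there, and walking
#' speeds are floored at \code{vFloor} so every step is a measurable
#' displacement.
#'
#' @param symbols movement-unit string.
#' @param playerId,matchId,position trace identifiers.
#' @param mode \code{"angle"} (default) or \code{"coordinate"}.
#' @param eps shrink applied to open band bounds (default 1e-3).
#' @param vmax,amax caps for the unbounded bands.
#' @param vFloor minimum emitted speed in coordinate mode (default 0.3).
#' @param startTime time of the first fix in seconds.
#' @param origin latitude/longitude of the first fix in coordinate mode.
#' @return A \linkS4class{MovementTrace} (or NULL for an empty string).
#' @export
unitsToGps <- function(symbols, playerId = "sim", matchId = "m1",
                       position = "unknown", mode = c("angle", "coordinate"),
                       eps = 1e-3, vmax = 9, amax = 4, vFloor = 0.3,
                       startTime = 0, origin = c(53.8, -1.5)) {
  mode <- match.arg(mode)
  if (!nchar(symbols)) return(NULL)
  .assertAlphabet(symbols)
  tri <- decodeUnit(.chars(symbols))
  n <- nrow(tri)
  draw <- function(kind, bands, lo = NULL) {
    vapply(bands, function(b) {
      iv <- .bandInterval(kind, b, eps, vmax, amax)
      if (!is.null(lo)) iv[1L] <- max(iv[1L], min(lo, iv[2L]))
      stats::runif(1L, iv[1L], iv[2L])
    }, numeric(1L))
  }
  v <- draw("velocity", tri$velocity,
            lo = if (mode == "coordinate") vFloor else NULL)
  a <- draw("acceleration", tri$acceleration)
  th <- draw("turning", tri$turning)
  fixes <- data.frame(time_s = startTime + 0.1 * (seq_len(n) - 1L),
                      velocity = v, acceleration = a)
  if (mode == "angle") {
    fixes$turning_angle <- th
  } else {
    ## realise turning angles as heading changes along a local track
    heading <- numeric(max(n - 1L, 1L))  # degrees, segment i: fix i -> i+1
    if (n > 2L) {
      turnSign <- sample(c(-1, 1), n, replace = TRUE)
      for (i in 2:(n - 1L)) {
        heading[i] <- heading[i - 1L] + turnSign[i] * th[i]
      }
    }
    step <- v[-n] * 0.1
    dx <- c(0, cumsum(step * sin(heading * pi / 180)))
    dy <- c(0, cumsum(step * cos(heading * pi / 180)))
    fixes$latitude <- origin[1L] + dy / 111132.95
    fixes$longitude <- origin[2L] +
      dx / (111319.49 * cos(origin[1L] * pi / 180))
  }
  movementTrace(playerId, matchId, position, fixes)
}

#' Configuration for a synthetic cohort
#'
#' Defaults describe the package's reference cohort: 10 players per
#' position, 3 matches each, 60 s of active movement per player-match at
#' 10 Hz, with on average 8 inactive gaps per active minute lasting
#' 2.5--5 s.
#'
#' @param playersPerPosition players per position (>= 1).
#' @param matchesPerPlayer matches per player (>= 1).
#' @param activeDuration active movement per player-match, seconds.
#' @param samplingInterval sampling interval, seconds (0.1 = 10 Hz).
#' @param gapRate expected inactive gaps per minute of active play.
#' @param gapDurationRange min/max gap duration, seconds.
#' @param seed master seed for the whole cohort.
#' @return A validated configuration list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(playersPerPosition = 10L, matchesPerPlayer = 3L,
                         activeDuration = 60, samplingInterval = 0.1,
                         gapRate = 8, gapDurationRange = c(2.5, 5),
                         seed = 1L) {
  cfg <- list(playersPerPosition = as.integer(playersPerPosition),
              matchesPerPlayer = as.integer(matchesPerPlayer),
              activeDuration = activeDuration,
              samplingInterval = samplingInterval,
              gapRate = gapRate,
              gapDurationRange = as.numeric(gapDurationRange),
              seed = as.integer(seed))
  if (cfg$playersPerPosition < 1L || cfg$matchesPerPlayer < 1L) {
    stop("players and matches per player must be >= 1")
  }
  if (cfg$samplingInterval <= 0 ||
      abs(cfg$activeDuration / cfg$samplingInterval -
          round(cfg$activeDuration / cfg$samplingInterval)) > 1e-9) {
    stop("activeDuration must be a multiple of samplingInterval")
  }
  if (cfg$gapRate < 0) stop("gapRate must be >= 0")
  if (length(cfg$gapDurationRange) != 2L ||
      diff(cfg$gapDurationRange) < 0) {
    stop("gapDurationRange must be an increasing pair of durations")
  }
  class(cfg) <- "cohortConfig"
  cfg
}

#' Generate a synthetic two-position GPS cohort
#'
#' For every player-match, samples an active movement-unit stream from the
#' player's position archetype, cuts it into segments, and splices
#' sub-threshold-velocity gap blocks between them, so inactive-period
#' splitting is genuinely exercised downstream. Active fixes are emitted
#' with a device turning-angle channel and a velocity floor of 0.25 m/s so
#' active symbols never masquerade as inactivity. Bit-reproducible under
#' the master seed.
#'
#' @param config a [cohortConfig()].
#' @param archetypes named list of exactly two
#'   \linkS4class{PositionArchetype}s.
#' @return A list: \code{traces} (list of \linkS4class{MovementTrace}),
#'   \code{labels} (data.frame with \code{player_id}, \code{match_id},
#'   \code{position}), \code{truth} (per trace, the active unit stream,
#'   its segments, and the archetype's motifs) and \code{config}.
#' @export
generateCohort <- function(config = cohortConfig(),
                           archetypes = defaultArchetypes()) {
  stopifnot(inherits(config, "cohortConfig"))
  if (length(archetypes) != 2L) stop("exactly two archetypes are required")
  set.seed(config$seed)
  dt <- config$samplingInterval
  L <- as.integer(round(config$activeDuration / dt))
  traces <- list()
  truth <- list()
  labels <- NULL
  for (arch in archetypes) {
    pos <- arch@label
    for (p in seq_len(config$playersPerPosition)) {
      pid <- sprintf("%s_%02d", pos, p)
      for (mIdx in seq_len(config$matchesPerPlayer)) {
        mid <- sprintf("m%02d", mIdx)
        units <- sampleUnitSequence(arch, L)
        nu <- nchar(units)
        nGaps <- stats::rpois(1L, config$gapRate * config$activeDuration / 60)
        nGaps <- min(nGaps, nu - 1L)
        cuts <- if (nGaps > 0L) {
          sort(sample.int(nu - 1L, nGaps))
        } else {
          integer()
        }
        bounds <- c(0L, cuts, nu)
        segs <- substring(units, bounds[-length(bounds)] + 1L,
                          bounds[-1L])
        parts <- list()
        tcur <- 0
        for (si in seq_along(segs)) {
          tr <- unitsToGps(segs[si], pid, mid, pos, mode = "angle",
                           vFloor = 0, startTime = tcur)
          f <- tr@fixes
          f$velocity <- pmax(f$velocity, 0.25)  # active floor
          parts[[length(parts) + 1L]] <- f
          tcur <- tcur + nrow(f) * dt
          if (si < length(segs)) {
            gd <- stats::runif(1L, config$gapDurationRange[1L],
                               config$gapDurationRange[2L])
            k <- as.integer(ceiling(gd / dt))
            gap <- data.frame(
              time_s = tcur + dt * (seq_len(k) - 1L),
              velocity = stats::runif(k, 0.0, 0.15),
              acceleration = stats::runif(k, -0.05, 0.05),
              turning_angle = stats::runif(k, 0, 5))
            parts[[length(parts) + 1L]] <- gap
            tcur <- tcur + k * dt
          }
        }
        fixes <- do.call(rbind, parts)
        fixes$time_s <- dt * (seq_len(nrow(fixes)) - 1L)
        key <- sprintf("%s.%s", pid, mid)
        traces[[key]] <- movementTrace(pid, mid, pos, fixes)
        truth[[key]] <- list(units = units, segments = segs,
                             motifs = arch@motifs$motif)
        labels <- rbind(labels,
                        data.frame(player_id = pid, match_id = mid,
                                   position = pos,
                                   stringsAsFactors = FALSE))
      }
    }
  }
  list(traces = traces, labels = labels, truth = truth, config = config)
}
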