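test_that("band functions partition their domains at the stated boundaries", {
  expect_equal(bandVelocity(c(0, 1.69, 1.70, 3.90, 3.91, 4.99, 5.00, 8)),
               c("Walk", "Walk", "Jog", "Jog", "Run", "Run", "Sprint",
                 "Sprint"))
  expect_equal(bandAcceleration(c(-3, -0.20, -0.19, 0, 0.19, 0.20, 3)),
               c("Deceleration", "Deceleration", "Neutral", "Neutral",
                 "Neutral", "Acceleration", "Acceleration"))
  expect_equal(bandTurning(c(0, 9.99, 10, 44.99, 45, 89.99, 90, 180)),
               c("Straight", "Straight", "Acute-change", "Acute-change",
                 "Large-change", "Large-change", "Backwards", "Backwards"))
  ## every valid input gets exactly one band
  set.seed(1)
  expect_true(all(nzchar(bandVelocity(runif(200, 0, 12)))))
  expect_true(all(nzchar(bandAcceleration(runif(200, -6, 6)))))
  expect_true(all(nzchar(bandTurning(runif(200, 0, 180)))))
})

test_that("band functions reject invalid input", {
  expect_error(bandVelocity(-0.1), "non-negative")
  expect_error(bandVelocity(NA_real_), "finite")
  expect_error(bandAcceleration(Inf), "finite")
  expect_error(bandTurning(180.1), "0, 180")
  expect_error(bandTurning(-1), "0, 180")
})

test_that("turning angles match a hand-coded spherical bearing oracle", {
  lat0 <- 53.8
  mPerDegLat <- 111132.95
  mPerDegLon <- 111319.49 * cos(lat0 * pi / 180)
  ## local-metre waypoints -> degrees
  toLatLon <- function(xy) {
    cbind(lat0 + xy[, 2] / mPerDegLat, -1.5 + xy[, 1] / mPerDegLon)
  }
  ## collinear equally spaced points: no direction change
  ll <- toLatLon(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_lt(max(abs(turningAngles(ll[, 1], ll[, 2]))), 1e-3)
  ## exact path reversal
  ll <- toLatLon(cbind(c(0, 1, 0), c(0, 0, 0)))
  expect_equal(turningAngles(ll[, 1], ll[, 2])[2], 180, tolerance = 1e-6)
  ## right-angle corner, checked against the independent bearing formula
  ll <- toLatLon(cbind(c(0, 1, 1), c(0, 0, 1)))
  b1 <- oracleBearing(ll[1, 1], ll[1, 2], ll[2, 1], ll[2, 2])
  b2 <- oracleBearing(ll[2, 1], ll[2, 2], ll[3, 1], ll[3, 2])
  oracle <- abs((b2 - b1 + 180) %% 360 - 180)
  ang <- turningAngles(ll[, 1], ll[, 2])[2]
  expect_equal(ang, oracle, tolerance = 0.1)
  expect_equal(ang, 90, tolerance = 0.5)
  ## stationary fixes carry the previous heading instead of erroring
  ll <- toLatLon(cbind(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  expect_equal(turningAngles(ll[, 1], ll[, 2]), c(0, 0, 0, 0))
})

test_that("derived acceleration is a central finite difference", {
  expect_equal(deriveAcceleration(rep(2.5, 20)), rep(0, 20))
  ## linear ramp 0 -> 1 m/s over 1 s: slope 1 everywhere
  expect_equal(deriveAcceleration(seq(0, 1, by = 0.1)), rep(1, 11))
  ## random series against an index-by-index oracle
  set.seed(7)
  v <- runif(50, 0, 6)
  a <- deriveAcceleration(v)
  oracle <- numeric(50)
  for (i in 2:49) oracle[i] <- (v[i + 1] - v[i - 1]) / 0.2
  oracle[1] <- (v[2] - v[1]) / 0.1
  oracle[50] <- (v[50] - v[49]) / 0.1
  expect_equal(a, oracle)
  expect_error(deriveAcceleration(1.0), "two fixes")
})

test_that("the worked GPS example discretizes to ijfeikhddb", {
  csv <- system.file("extdata", "worked_example_gps_synthetic.csv",
                     package = "MoveMiner")
  traces <- readGpsCsv(csv)
  expect_length(traces, 1L)
  expect_identical(discretizeTrace(traces[[1]]), "ijfeikhddb")
  ## and the printed descriptor rows encode to the same string directly
  d <- read.csv(system.file("extdata", "worked_example_descriptors.csv",
                            package = "MoveMiner"))
  expect_identical(paste(encodeUnit(d$velocity_band, d$acceleration_band,
                                    d$turning_band), collapse = ""),
                   "ijfeikhddb")
})

test_that("discretization length equals trace length and channels fall back", {
  set.seed(3)
  n <- 40L
  tr <- kinematicTrace(runif(n, 0, 7), runif(n, -2, 2), runif(n, 0, 180))
  expect_equal(nchar(discretizeTrace(tr)), n)
  ## acceleration channel absent: derived from velocity
  tr2 <- kinematicTrace(runif(n, 0, 7), turning = runif(n, 0, 180))
  expect_equal(nchar(discretizeTrace(tr2)), n)
  ## neither turning channel nor coordinates: unsupported
  tr3 <- kinematicTrace(runif(n, 0, 7), runif(n, -2, 2))
  expect_error(discretizeTrace(tr3), "turning_angle")
  expect_identical(encodeMovement(numeric(), numeric(), numeric()), "")
  expect_identical(encodeMovement(rep(1, 5), rep(0, 5), rep(0, 5)), "eeeee")
})

test_that("inactive-period splitting removes sustained sub-threshold runs", {
  sym <- strrep("e", 100)
  v <- rep(1, 100)
  expect_identical(splitInactive(sym, v), sym)  # no gap: input unchanged
  expect_identical(splitInactive(sym, rep(0.05, 100)), character())
  ## 3 s planted gap (30 fixes) splits into two runs
  v2 <- rep(1, 100)
  v2[41:70] <- 0.1
  out <- splitInactive(sym, v2, vMin = 0.2, tMin = 2.0)
  expect_length(out, 2L)
  expect_equal(nchar(out), c(40L, 30L))
  expect_equal(sum(nchar(out)), 100L - 30L)
  ## a dip shorter than tMin is kept
  v3 <- rep(1, 100)
  v3[41:55] <- 0.1
  expect_identical(splitInactive(sym, v3, vMin = 0.2, tMin = 2.0), sym)
  expect_error(splitInactive("ee", rep(1, 3)), "aligned")
})

test_that("GPS CSV and sequence TSV round-trip through their readers", {
  csv <- system.file("extdata", "worked_example_gps_synthetic.csv",
                     package = "MoveMiner")
  tr <- readGpsCsv(csv)[[1]]
  expect_s4_class(tr, "MovementTrace")
  expect_identical(positionLabel(tr), "hooker")
  tmp <- tempfile(fileext = ".csv")
  writeGpsCsv(list(tr), tmp)
  tr2 <- readGpsCsv(tmp)[[1]]
  expect_equal(gpsFixes(tr2)$velocity, gpsFixes(tr)$velocity)
  ## missing required columns are reported
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 0, velocity = 1), bad, row.names = FALSE)
  expect_error(readGpsCsv(bad), "required column")
  ## corpus round trip, including symbols that look numeric-ish
  cp <- movementCorpus("p1", "m1", "winger", c("ijfeik", "eeee"))
  tsv <- tempfile(fileext = ".tsv")
  writeSequenceTsv(list(cp), tsv)
  back <- readSequenceTsv(tsv)[[1]]
  expect_identical(sequences(back), sequences(cp))
  expect_identical(positionLabel(back), "winger")
})
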