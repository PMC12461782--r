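# Binding-event detection, mechanism classification and exit geometry.

test_that("coordination series counts partners inside the cutoffs", {
  dN <- matrix(5, 10, 2)
  dO <- matrix(2.0, 10, 6)
  traj <- DistanceTrajectory(0.1, dN, dO)
  cs <- coordinationSeries(traj)
  expect_equal(cs$lig, rep(0L, 10))
  expect_equal(cs$wat, rep(6L, 10))
  # a single crossing changes the count exactly at the crossing frame
  dN2 <- matrix(c(rep(4, 5), rep(3.0, 5)), 10, 1)
  cs2 <- coordinationSeries(DistanceTrajectory(0.1, dN2, dO))
  expect_equal(cs2$lig, rep(c(0L, 1L), each = 5))
  expect_error(coordinationSeries(traj, cutoffLig = -1), "positive")
})

test_that("sub-residence dips are ignored and persistent entries detected", {
  dt <- 0.1
  n <- 2000                                     # 200 ps
  # nitrogen 1: 5 ps dip at 50 ps; nitrogen 2: clean entry at 100 ps
  dN <- matrix(6, n, 2)
  tt <- (seq_len(n) - 1) * dt
  dN[tt >= 50 & tt < 55, 1] <- 3.0
  dN[tt >= 100, 2] <- 2.3
  traj <- DistanceTrajectory(dt, dN, matrix(2.3, n, 4))
  ev <- detectBindingEvents(traj)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$nitrogen, 2L)
  expect_equal(ev$time, 100, tolerance = dt)
  expect_equal(ev$classFrom, 0L)
  expect_equal(ev$classTo, 1L)
  expect_error(detectBindingEvents(DistanceTrajectory(dt, dN[1:100, ],
                                                      matrix(2.3, 100, 4))),
               "shorter")
})

test_that("planted events are detected and spurious ones are not", {
  tr <- synthBindingTrajectory(c("dissociative", "associative"),
                               nEvents = 4, nSpurious = 3, seed = 5)
  gt <- attr(tr, "groundTruth")
  ev <- detectBindingEvents(tr)
  expect_equal(nrow(ev), 4L)
  expect_setequal(ev$nitrogen, gt$nitrogen[!gt$spurious])
  expect_true(all(abs(ev$time - gt$time[!gt$spurious]) <= 2 * tr@dt))
  # transition classes climb 0-1 through 3-4 as nitrogens accumulate
  expect_equal(sort(ev$classTo), 1:4)
})

test_that("event detection is stable under frame-rate refinement", {
  tr <- synthBindingTrajectory("dissociative", nEvents = 3, seed = 6,
                               dt = 0.05)
  evFine <- detectBindingEvents(tr)
  sub <- DistanceTrajectory(tr@dt * 2, tr@dN[seq(1, nrow(tr@dN), 2), ],
                            tr@dO[seq(1, nrow(tr@dO), 2), ])
  evCoarse <- detectBindingEvents(sub)
  expect_equal(nrow(evFine), nrow(evCoarse))
  expect_true(all(abs(evFine$time - evCoarse$time) <= 2 * sub@dt))
})

test_that("water-before-nitrogen ordering separates the two mechanisms", {
  tr <- synthBindingTrajectory(c("dissociative", "associative",
                                 "dissociative", "associative"),
                               nEvents = 4, seed = 7)
  ev <- classifyMechanism(tr, detectBindingEvents(tr))
  gt <- attr(tr, "groundTruth")
  expect_equal(as.character(ev$mechanism), gt$mechanism[!gt$spurious])
  # dissociative: the leaving water is out before entry
  expect_true(all(ev$waterExitTime[ev$mechanism == "dissociative"] < 0))
  expect_true(all(ev$waterExitTime[ev$mechanism == "associative"] > 0))
})

test_that("classification is perfect without noise and >= 90% at 0.2 A noise", {
  labels <- rep(c("dissociative", "associative"), 12)
  clean <- synthBindingTrajectory(labels, nEvents = 24, seed = 8)
  evC <- classifyMechanism(clean, detectBindingEvents(clean))
  gtC <- attr(clean, "groundTruth")
  expect_equal(as.character(evC$mechanism), gtC$mechanism[!gtC$spurious])

  noisy <- synthBindingTrajectory(labels, nEvents = 24, noiseSigma = 0.2,
                                  seed = 9, nSpurious = 3)
  gtN <- attr(noisy, "groundTruth")
  evN <- detectBindingEvents(noisy)
  # spurious sub-residence dips must never be reported
  expect_true(!any(evN$nitrogen %in% gtN$nitrogen[gtN$spurious]))
  evN <- classifyMechanism(noisy, evN)
  m <- merge(evN, gtN[!gtN$spurious, ], by = "nitrogen")
  expect_gte(mean(as.character(m$mechanism.x) == m$mechanism.y), 0.9)
})

test_that("single-frame exchanges are labelled ambiguous", {
  dt <- 0.1
  n <- 1200
  tt <- (seq_len(n) - 1) * dt
  dN <- matrix(6, n, 1); dO <- matrix(2.3, n, 6)
  dN[tt >= 60, 1] <- 2.3          # nitrogen enters at 60 ps
  dO[tt >= 60, 1] <- 6            # water leaves in the same frame
  traj <- DistanceTrajectory(dt, dN, dO)
  ev <- classifyMechanism(traj, detectBindingEvents(traj))
  expect_equal(as.character(ev$mechanism), "ambiguous")
})

test_that("events with truncated windows are skipped with a warning", {
  dt <- 0.1
  n <- 500                                        # 50 ps
  dN <- matrix(6, n, 1); dO <- matrix(2.3, n, 6)
  dN[(seq_len(n) - 1) * dt >= 10, 1] <- 2.3       # entry at 10 ps < window
  traj <- DistanceTrajectory(dt, dN, dO)
  ev <- detectBindingEvents(traj, minResidence = 20)
  expect_warning(out <- classifyMechanism(traj, ev), "truncated")
  expect_equal(nrow(out), 0L)
})

test_that("exit geometry recovers angles and preserves distances", {
  tr <- synthBindingTrajectory("dissociative", nEvents = 60,
                               coordinates = TRUE, seed = 10)
  ev <- classifyMechanism(tr, detectBindingEvents(tr))
  angles <- vapply(seq_len(nrow(ev)), function(i)
    mean(leavingWaterGeometry(tr, ev[i, ])$angle), numeric(1))
  # generator plants a 90 degree +/- 10 exit; the mean is within 3 degrees
  expect_lt(abs(mean(angles) - 90), 3)
  g <- leavingWaterGeometry(tr, ev[1, ])
  expect_true(all(g$angle >= 0 & g$angle <= 180))
  # |projected point| equals the full metal-oxygen distance (planar fixture)
  expect_equal(sqrt(rowSums(g$xy^2)), g$distance, tolerance = 1e-9)

  # orthogonal and collinear reference cases
  mk <- function(theta) {
    xyzN <- list(cbind(2.5, 0, 0))
    xyzO <- list(cbind(2.5 * cos(theta), 2.5 * sin(theta), 0))
    DistanceTrajectory(0.1, matrix(2.5, 1, 1), matrix(2.5, 1, 1),
                       xyzMetal = matrix(0, 1, 3), xyzN = xyzN, xyzO = xyzO)
  }
  evRow <- data.frame(frame = 1L, nitrogen = 1L, leavingWater = 1L)
  expect_equal(leavingWaterGeometry(mk(pi / 2), evRow, window = 0)$angle, 90)
  expect_equal(leavingWaterGeometry(mk(0), evRow, window = 0)$angle, 0)
})

test_that("the rigid transform preserves all pairwise distances", {
  set.seed(30)
  n <- 50
  xyzMetal <- matrix(rnorm(3 * n), n, 3)
  xyzN <- list(xyzMetal + matrix(rnorm(3 * n, 0, 2), n, 3))
  xyzO <- list(xyzMetal + matrix(rnorm(3 * n, 0, 2), n, 3))
  dN <- matrix(sqrt(rowSums((xyzN[[1]] - xyzMetal)^2)), n, 1)
  dO <- matrix(sqrt(rowSums((xyzO[[1]] - xyzMetal)^2)), n, 1)
  traj <- DistanceTrajectory(0.1, dN, dO, xyzMetal = xyzMetal,
                             xyzN = xyzN, xyzO = xyzO)
  ev <- data.frame(frame = 25L, nitrogen = 1L, leavingWater = 1L)
  g <- leavingWaterGeometry(traj, ev, window = 1)
  # the transformed metal-O distance is unchanged by the rotation
  frames <- 15:35
  expect_equal(g$distance, dO[frames, 1], tolerance = 1e-9)
})

test_that("mechanism summaries tabulate fractions with binomial intervals", {
  tr <- synthBindingTrajectory("dissociative", nEvents = 6, seed = 12)
  ev <- classifyMechanism(tr, detectBindingEvents(tr))
  s <- mechanismSummary(ev)
  expect_equal(s$fracDissociative, rep(1, nrow(s)))
  expect_true(all(s$ciLow <= 1 & s$ciHigh >= s$fracDissociative))

  mixed <- synthBindingTrajectory(rep(c("dissociative", "associative"), 8),
                                  nEvents = 16, seed = 13)
  evM <- classifyMechanism(mixed, detectBindingEvents(mixed))
  evM$classTo <- 1L                       # pool into one transition class
  sM <- mechanismSummary(evM)
  expect_true(sM$ciLow <= 0.5 && 0.5 <= sM$ciHigh)
  expect_error(mechanismSummary(evM[0, ]), "no events")
})
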