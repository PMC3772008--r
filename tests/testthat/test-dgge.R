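# on-grid band positions (samples = 2001 puts multiples of 5e-4 on the grid)
cleanLane <- function(positions, heights, laneId = "L") {
  detectBands(simulateLane(laneSpec(positions, heights, noiseSd = 0,
                                    samples = 2001L), laneId, seed = 1))
}

test_that("band calling recovers noise-free Gaussian mixtures exactly", {
  bs <- cleanLane(c(0.2, 0.5, 0.8), c(2, 1, 1))
  expect_equal(nBands(bs), 3L)
  expect_equal(bands(bs)$position, c(0.2, 0.5, 0.8), tolerance = 5e-4 / 2)
  expect_equal(bands(bs)$prob, c(0.5, 0.25, 0.25), tolerance = 1e-9)
  expect_equal(sum(bands(bs)$prob), 1, tolerance = 1e-12)
})

test_that("the 1% relative-peak-height rule drops sub-threshold bands", {
  # 4th band at ~0.5% of the summed peak height is excluded
  bs <- cleanLane(c(0.2, 0.4, 0.6, 0.8), c(10, 10, 10, 0.15))
  expect_equal(nBands(bs), 3L)
  expect_equal(sum(bands(bs)$prob), 1, tolerance = 1e-12)
  # at ~3% it is retained
  bs2 <- cleanLane(c(0.2, 0.4, 0.6, 0.8), c(10, 10, 10, 1))
  expect_equal(nBands(bs2), 4L)
})

test_that("flat and monotone profiles yield empty band sets with a warning", {
  x <- seq(0, 1, length.out = 200)
  expect_warning(b1 <- detectBands(laneProfile("flat", x, rep(1, 200))),
                 "no bands")
  expect_equal(nBands(b1), 0L)
  expect_warning(b2 <- detectBands(laneProfile("ramp", x, x)), "no bands")
  expect_equal(nBands(b2), 0L)
})

test_that("Shannon index matches the closed form and its bounds", {
  expect_equal(shannonIndex(bandSet("L", 0.5, 3)), 0)
  expect_equal(shannonIndex(bandSet("L", c(.2, .4, .6, .8), rep(2, 4))),
               log(4))
  expect_equal(shannonIndex(bandSet("L", c(.2, .5, .8), c(2, 1, 1))),
               -(0.5 * log(0.5) + 0.5 * log(0.25)))
  expect_equal(shannonIndex(bandSet("L", c(.2, .4), c(3, 1)), base = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  # agrees with the community-ecology implementation
  p <- c(5, 2, 1, 1, 1)
  expect_equal(shannonIndex(bandSet("L", seq(.1, .5, .1), p)),
               vegan::diversity(p, index = "shannon"))
  # 0 <= H <= log(n), equality iff equiprobable; adding a band increases H
  for (n in 2:6) {
    expect_equal(shannonIndex(bandSet("L", seq_len(n) / 10, rep(1, n))),
                 log(n))
    expect_lt(shannonIndex(bandSet("L", seq_len(n) / 10,
                                   c(2, rep(1, n - 1)))), log(n))
    expect_lt(log(n), log(n + 1))
  }
  expect_error(shannonIndex(suppressWarnings(
    detectBands(laneProfile("f", c(0, 1), c(1, 1))))), "undefined")
})

test_that("band matching is greedy within tolerance, each band used once", {
  A <- bandSet("A", c(0.20, 0.50), c(1, 1))
  B <- bandSet("B", c(0.205, 0.80), c(1, 1))
  m <- matchBands(A, B, 0.01)
  expect_equal(m$c, 1L)
  expect_equal(m$P, 3L)
  # identical sets: c = n, P = n
  m2 <- matchBands(A, A)
  expect_equal(m2$c, 2L)
  expect_equal(m2$P, 2L)
  # fully disjoint: c = 0, P = nA + nB
  C <- bandSet("C", c(0.35, 0.65), c(1, 1))
  m3 <- matchBands(A, C, 0.01)
  expect_equal(m3$c, 0L)
  expect_equal(m3$P, 4L)
  expect_error(matchBands(A, B, -0.1), ">= 0")
})

test_that("lane distance matches hand-evaluated cases", {
  A <- bandSet("A", c(0.2, 0.6), c(1, 1))
  expect_equal(laneDistance(A, A), 0)
  # fully disjoint, two bands of probability 0.5 each: (4 x 0.5) / 4
  B <- bandSet("B", c(0.35, 0.8), c(1, 1))
  expect_equal(laneDistance(A, B), 0.5)
  # single matched band, equal probability
  expect_equal(laneDistance(bandSet("a", 0.4, 2), bandSet("b", 0.4, 7)), 0)
  # dice strategy on presence/absence
  expect_equal(laneDistance(A, B, strategy = "dice"), 1)
  expect_equal(laneDistance(A, A, strategy = "dice"), 0)
  e1 <- suppressWarnings(detectBands(laneProfile("e1", c(0, 1), c(1, 1))))
  e2 <- suppressWarnings(detectBands(laneProfile("e2", c(0, 1), c(1, 1))))
  expect_warning(d0 <- laneDistance(e1, e2), "empty")
  expect_equal(d0, 0)
})

test_that("lane distances are symmetric, bounded and zero-diagonal", {
  set.seed(5)
  lanes <- lapply(1:10, function(i) {
    k <- sample(3:12, 1)
    bandSet(paste0("L", i), sort(runif(k, 0.05, 0.95)), runif(k, 0.5, 3))
  })
  d <- laneDistanceMatrix(lanes)
  v <- distValues(d)
  expect_equal(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_true(all(v >= 0 & v <= 1))
  for (i in c(2, 7))
    expect_identical(laneDistance(lanes[[1]], lanes[[i]]),
                     laneDistance(lanes[[i]], lanes[[1]]))
  # identical lanes give a zero matrix
  same <- lapply(c("a", "b", "c"), function(id)
    bandSet(id, c(0.2, 0.5), c(1, 2)))
  expect_true(all(distValues(laneDistanceMatrix(same)) == 0))
  expect_error(laneDistanceMatrix(list(lanes[[1]], lanes[[1]])), "duplicate")
})

test_that("lane profile CSV readers accept long and wide layouts", {
  x <- seq(0, 1, length.out = 50)
  long <- data.frame(lane_id = rep(c("A", "B"), each = 50),
                     position = c(x, x), intensity = runif(100))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  p1 <- readLaneProfilesCSV(f)
  expect_equal(names(p1), c("A", "B"))
  wide <- data.frame(position = x, A = runif(50), B = runif(50))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, f2, row.names = FALSE)
  p2 <- readLaneProfilesCSV(f2)
  expect_equal(names(p2), c("A", "B"))
  expect_s4_class(p2$A, "LaneProfile")
})
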