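test_that("binarization uses a strict threshold on normalized values", {
  m <- newMSM(matrix(0.5, 4, 6))
  expect_false(any(maskMatrix(binarize(m, 0.5))))
  expect_true(all(maskMatrix(binarize(m, 0.49))))

  r <- randomNormalizedMatrix(20, 30, density = 0.3, seed = 3)
  mk <- maskMatrix(binarize(r, 0.2))
  ref <- matrix(FALSE, 20, 30)
  for (i in 1:20) for (j in 1:30)
    ref[i, j] <- intensityMatrix(r)[i, j] > 0.2
  expect_identical(mk, ref)

  raw <- msimg:::newMassSpecMatrix(matrix(2, 2, 10),
    binningSpec(100, 101, 0.1), 1:2)
  expect_error(binarize(raw, 0.1), "normalized")
  expect_error(binarize(m, 1), "tauIntensity")
})

test_that("density map equals the nested-loop window sum with clipping", {
  ones <- new("SignalMask", mask = matrix(TRUE, 3, 3), tauIntensity = 0)
  D <- densityValues(densityMap(ones, 3))
  expect_identical(D[2, 2], 9L)
  expect_identical(D[1, 1], 4L)          # corner windows are clipped
  expect_identical(D[1, 2], 6L)

  zeros <- new("SignalMask", mask = matrix(FALSE, 5, 7), tauIntensity = 0)
  expect_true(all(densityValues(densityMap(zeros, 5)) == 0L))
  expect_error(densityMap(ones, 4), "odd")

  set.seed(11)
  for (w in c(3L, 5L, 9L)) {
    mk <- new("SignalMask", mask = matrix(runif(50 * 80) < 0.3, 50, 80),
              tauIntensity = 0)
    expect_identical(densityValues(densityMap(mk, w)),
                     oracleDensityMap(maskMatrix(mk), w))
  }
})

test_that("density map handles degenerate 1-row/1-column masks", {
  mk <- new("SignalMask", mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 1, 4),
            tauIntensity = 0)
  expect_identical(densityValues(densityMap(mk, 3)),
                   oracleDensityMap(maskMatrix(mk), 3))
  mkc <- new("SignalMask", mask = matrix(c(TRUE, TRUE, FALSE), 3, 1),
             tauIntensity = 0)
  expect_identical(densityValues(densityMap(mkc, 3)),
                   oracleDensityMap(maskMatrix(mkc), 3))
})

test_that("NMS extracts separated peaks in descending-density order", {
  D <- matrix(0L, 20, 20); D[5, 7] <- 6L
  dm <- new("DensityMap", density = D, window = 3L)
  pk <- nmsExtractPeaks(dm, tauDensity = 5, maxPeaks = 10,
                        suppressHeight = 5, suppressWidth = 5)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col, pk$density), c(5, 7, 6))

  D2 <- matrix(0L, 20, 20); D2[3, 3] <- 8L; D2[15, 15] <- 10L
  dm2 <- new("DensityMap", density = D2, window = 5L)
  pk2 <- nmsExtractPeaks(dm2, 5, 2, 5, 5)
  expect_equal(pk2$density, c(10L, 8L))      # higher density first
  expect_equal(pk2$row, c(15, 3))

  # below-threshold map: empty result is valid
  expect_equal(nrow(nmsExtractPeaks(dm, 7, 10, 5, 5)), 0)
})

test_that("NMS matches the naive rescan-argmax oracle on random maps", {
  set.seed(23)
  for (rep in 1:8) {
    D <- matrix(rpois(50 * 60, 3), 50, 60)
    storage.mode(D) <- "integer"
    dm <- new("DensityMap", density = pmin(D, 81L), window = 9L)
    sh <- sample(c(4L, 7L, 9L), 1); sw <- sample(c(5L, 8L), 1)
    tau <- sample(3:6, 1); mp <- sample(c(5L, 25L), 1)
    got <- nmsExtractPeaks(dm, tau, mp, sh, sw)
    ref <- oracleNms(densityValues(dm), tau, mp, sh, sw)
    expect_equal(cbind(got$row, got$col, got$density), unname(ref))
    # invariants: monotone density, threshold respect, and every later peak
    # lies outside the (possibly asymmetric, for even sizes) suppression
    # rectangle [-floor(s/2), +ceiling(s/2)-1] of every earlier one
    expect_true(all(diff(got$density) <= 0))
    expect_true(all(got$density >= tau))
    if (nrow(got) > 1)
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got)) {
        dr <- got$row[b] - got$row[a]; dc <- got$col[b] - got$col[a]
        inRect <- dr >= -(sh %/% 2) && dr <= (sh + 1) %/% 2 - 1 &&
                  dc >= -(sw %/% 2) && dc <= (sw + 1) %/% 2 - 1
        expect_false(inRect)
      }
  }
})

test_that("NMS recovers planted cluster cores from synthetic matrices", {
  cfg <- syntheticConfig(nSatellites = 0L)   # isolated Gaussian blobs
  s <- generateSample(cfg, "control", seed = 31)
  dm <- densityMap(binarize(s$matrix, 0.01), 9)
  pk <- nmsExtractPeaks(dm, tauDensity = 20, maxPeaks = 100,
                        suppressHeight = 32, suppressWidth = 32)
  expect_equal(nrow(pk), nrow(s$truth$centers))
  d <- apply(s$truth$centers, 1, function(p)
    min(sqrt((pk$row - p[1])^2 + (pk$col - p[2])^2)))
  expect_true(all(d <= ceiling(9 / 2)))
})
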