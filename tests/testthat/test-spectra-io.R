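test_that("m/z values map onto the documented bin grid", {
  b <- binningSpec(100, 200, 0.1)
  expect_identical(mzBinIndex(100.0, b), 0L)
  expect_identical(mzBinIndex(150.55, b), 505L)
  expect_identical(mzBinIndex(100.0999, b), 0L)
  expect_identical(mzBinIndex(c(100, 150.55, 100.0999), b),
                   c(0L, 505L, 0L))
  expect_error(mzBinIndex(99.9, b), "outside")
  expect_error(mzBinIndex(200.0, b), "outside")   # range is half-open
  expect_error(binningSpec(200, 100, 0.1), "greater")
  expect_error(binningSpec(100, 200, 0), "positive")
})

test_that("ion intensities falling in one bin are summed", {
  b <- binningSpec(100, 101, 0.1)
  sc <- makeScans(list(rt = 1, mz = c(100.01, 100.02), intensity = c(5, 7)))
  m <- buildMassSpecMatrix(sc, b)
  expect_equal(intensityMatrix(m)[1, 1], 12)
  expect_equal(sum(intensityMatrix(m)), 12)

  # no collisions: every intensity lands unchanged in its own cell
  sc2 <- makeScans(list(rt = 1, mz = c(100.05, 100.35, 100.95),
                        intensity = c(3, 1, 8)))
  m2 <- intensityMatrix(buildMassSpecMatrix(sc2, b))
  expect_equal(m2[1, c(1, 4, 10)], c(3, 1, 8))
  expect_equal(sum(m2 != 0), 3)
})

test_that("binning agrees with per-ion brute-force accumulation", {
  set.seed(42)
  b <- binningSpec(100, 110, 0.25)
  scans <- lapply(1:3, function(t)
    list(rt = t, mz = runif(50, 100, 110 - 1e-9), intensity = rexp(50)))
  m <- intensityMatrix(buildMassSpecMatrix(makeScans(
    scans[[1]], scans[[2]], scans[[3]]), b))
  ref <- matrix(0, 3, nBins(b))
  for (t in 1:3) for (k in 1:50) {
    i <- floor((scans[[t]]$mz[k] - 100) / 0.25) + 1
    ref[t, i] <- ref[t, i] + scans[[t]]$intensity[k]
  }
  expect_equal(m, ref)
  # conservation: binning neither creates nor destroys in-range intensity
  expect_equal(sum(m), sum(sapply(scans, function(s) sum(s$intensity))))
})

test_that("scan handling: RT ordering, empty scans, out-of-range drops", {
  b <- binningSpec(100, 101, 0.1)
  sc <- makeScans(
    list(rt = 5, mz = 100.05, intensity = 2),
    list(rt = 1, mz = 100.85, intensity = 4),
    list(rt = 3, mz = numeric(0), intensity = numeric(0)))
  m <- buildMassSpecMatrix(sc, b)
  expect_equal(rtAxis(m), c(1, 3, 5))          # re-sorted by RT
  expect_equal(intensityMatrix(m)[1, 9], 4)
  expect_true(all(intensityMatrix(m)[2, ] == 0))  # empty scan keeps its row
  expect_equal(intensityMatrix(m)[3, 1], 2)

  scOut <- makeScans(list(rt = 1, mz = c(100.05, 99.0, 101.5),
                          intensity = c(1, 10, 20)))
  expect_message(mOut <- buildMassSpecMatrix(scOut, b), "dropped 2")
  expect_equal(sum(intensityMatrix(mOut)), 1)   # out-of-range ions dropped
  expect_error(buildMassSpecMatrix(list(), b), "non-empty")
})

test_that("percentile normalization maps the scale value to exactly 1", {
  b <- binningSpec(100, 200, 0.1)
  # all non-zero values equal: every one of them is its own percentile
  v <- matrix(0, 10, 1000); v[1, ] <- 5
  m <- msimg:::newMassSpecMatrix(v, b, 1:10)
  n <- normalizeMatrix(m)
  expect_true(isNormalized(n))
  expect_equal(unique(intensityMatrix(n)[1, ]), 1.0)
  expect_true(all(intensityMatrix(n)[-1, ] == 0))  # zeros stay zero

  # random sparse matrix: values above the percentile clip to exactly 1,
  # and re-measuring the output percentile with a sort-based routine gives 1
  set.seed(7)
  v2 <- matrix(0, 40, 1000)
  v2[sample.int(length(v2), 5000)] <- rlnorm(5000)
  m2 <- msimg:::newMassSpecMatrix(v2, b, 1:40)
  n2 <- intensityMatrix(normalizeMatrix(m2, percentile = 99.9))
  expect_true(min(n2) >= 0 && max(n2) <= 1)
  nz <- n2[n2 > 0]
  expect_equal(oraclePercentile(nz, 99.9), 1.0, tolerance = 1e-12)
  expect_gt(sum(n2 == 1), 1)                    # the clipped tail
  expect_identical(v2 == 0, n2 == 0)

  expect_warning(normalizeMatrix(
    msimg:::newMassSpecMatrix(matrix(0, 2, 1000), b, 1:2)), "all-zero")
  expect_error(normalizeMatrix(n), "already normalized")
})

test_that("matrix TSV serialization round-trips exactly", {
  m <- randomNormalizedMatrix(12, 17, density = 0.2, seed = 5)
  f <- withr::local_tempfile(fileext = ".msm.tsv")
  writeMsMatrix(m, f)
  m2 <- readMsMatrix(f)
  expect_identical(intensityMatrix(m2), intensityMatrix(m))
  expect_equal(rtAxis(m2), rtAxis(m))
  expect_identical(sampleId(m2), sampleId(m))
  expect_identical(isNormalized(m2), TRUE)
})
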