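test_that("patch extraction slices interiors and pads borders", {
  m <- matrix(seq_len(100), 10, 10)
  # deep interior: pure submatrix
  expect_equal(extractPatch(m, c(5, 5), 3, 3), m[4:6, 4:6],
               ignore_attr = TRUE)
  # top-left corner with padding: out-of-matrix quadrant is the pad value
  p <- extractPatch(m, c(1, 1), 4, 4, padValue = 0)
  expect_identical(dim(p), c(4L, 4L))
  expect_true(all(p[1:2, 1:2] == 0))
  expect_equal(p[3:4, 3:4], m[1:2, 1:2], ignore_attr = TRUE)
  expect_error(extractPatch(m, c(0, 5), 3, 3), "outside")
  expect_error(extractPatch(m, c(5, 11), 3, 3), "outside")

  # random centers near all four borders vs a per-cell bounds-check loop
  set.seed(13)
  for (rep in 1:20) {
    h <- sample(2:7, 1); w <- sample(2:7, 1)
    ctr <- c(sample(c(1, 2, 9, 10, sample(10, 1)), 1),
             sample(c(1, 2, 9, 10, sample(10, 1)), 1))
    got <- extractPatch(m, ctr, h, w, padValue = -1)
    ref <- matrix(-1, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      sr <- ctr[1] - h %/% 2 + i - 1
      sc <- ctr[2] - w %/% 2 + j - 1
      if (sr >= 1 && sr <= 10 && sc >= 1 && sc <= 10) ref[i, j] <- m[sr, sc]
    }
    expect_identical(got, ref)
  }
})

test_that("patch entropy matches its closed forms exactly", {
  expect_equal(patchEntropy(matrix(0.37, 8, 8)), 0, tolerance = 1e-12)
  half <- matrix(c(0, 1), 16, 16)
  expect_equal(patchEntropy(half), 1, tolerance = 1e-12)
  allLevels <- matrix((0:255) / 255, 16, 16)
  expect_equal(patchEntropy(allLevels), 8, tolerance = 1e-12)
  expect_error(patchEntropy(matrix(1.2, 2, 2)), "0, 1")
  expect_error(patchEntropy(matrix(-0.1, 2, 2)), "0, 1")
})

test_that("golden-location ranking averages entropy across samples", {
  # two candidate locations with entropies ~0 and >0: argmax picks the busy one
  m <- matrix(0, 30, 30)
  m[10:14, 10:14] <- matrix(runif(25, 0.2, 1), 5, 5)
  msm <- newMSM(m)
  cand <- data.frame(row = c(12, 25), col = c(12, 25))
  g <- rankGoldenLocations(list(msm), cand, 5, 5, 1)
  expect_equal(unname(goldenCoords(g)[1, ]), c(12, 12))

  # identical samples: mean entropy equals the single-sample entropy
  g3 <- rankGoldenLocations(list(msm, msm, msm), cand, 5, 5, 2)
  expect_equal(meanEntropies(g3)[1], patchEntropy(m[10:14, 10:14]))

  expect_error(rankGoldenLocations(list(msm), cand, 5, 5, 3),
               "exceeds the 2 available")
})

test_that("ranking equals an independent recompute-and-sort oracle", {
  set.seed(37)
  mats <- lapply(1:5, function(s)
    randomNormalizedMatrix(40, 50, density = 0.3, seed = 100 + s))
  cand <- data.frame(row = sample(5:35, 10), col = sample(5:45, 10))
  g <- rankGoldenLocations(mats, cand, 7, 7, 10)
  ent <- sapply(seq_len(10), function(j)
    mean(sapply(mats, function(mm)
      patchEntropy(extractPatch(mm, c(cand$row[j], cand$col[j]), 7, 7)))))
  ord <- order(-ent, seq_len(10))
  expect_equal(goldenCoords(g)[, "row"], as.integer(cand$row[ord]))
  expect_equal(goldenCoords(g)[, "col"], as.integer(cand$col[ord]))
  expect_equal(meanEntropies(g), ent[ord])
  expect_true(all(diff(meanEntropies(g)) <= 1e-12))
})

test_that("multi-channel images stack patches in golden order", {
  mats <- lapply(1:3, function(s)
    randomNormalizedMatrix(40, 50, density = 0.3, seed = 200 + s))
  cand <- data.frame(row = c(10, 20, 30), col = c(10, 25, 40))
  g <- rankGoldenLocations(mats, cand, 9, 9, 3)
  im <- buildMultiChannelImage(mats[[1]], g)
  expect_identical(dim(im), c(3L, 9L, 9L))
  for (ch in 1:3)
    expect_equal(imageTensor(im)[ch, , ],
      extractPatch(mats[[1]], goldenCoords(g)[ch, ], 9, 9))
  # single location: tensor is the patch with a leading unit axis
  g1 <- rankGoldenLocations(mats, cand, 9, 9, 1)
  im1 <- buildMultiChannelImage(mats[[2]], g1)
  expect_equal(im1@tensor[1, , ],
               extractPatch(mats[[2]], goldenCoords(g1)[1, ], 9, 9))
  # wrong-shape sample is a provenance error
  expect_error(buildMultiChannelImage(randomNormalizedMatrix(20, 20), g),
               "derived on")
})

test_that("grid baseline enumerates fully contained windows row-major", {
  g1 <- gridCandidateLocations(224, 224, 224, 224)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$row, g1$col), c(113, 113))
  g2 <- gridCandidateLocations(448, 224, 224, 224)
  expect_equal(nrow(g2), 2)

  set.seed(41)
  for (rep in 1:15) {
    R <- sample(30:200, 1); C <- sample(30:200, 1)
    h <- sample(5:40, 1); w <- sample(5:40, 1); s <- sample(1:30, 1)
    g <- gridCandidateLocations(R, C, h, w, stride = s)
    expect_equal(nrow(g),
      (floor((R - h) / s) + 1) * (floor((C - w) / s) + 1))
    expect_true(all(g$row - h %/% 2 >= 1 & g$row + (h + 1) %/% 2 - 1 <= R))
  }
  expect_warning(g0 <- gridCandidateLocations(10, 10, 32, 32), "larger")
  expect_equal(nrow(g0), 0)
})

test_that("channel correlation matches the loop-based Pearson formula", {
  set.seed(43)
  mkImage <- function(tens, id) new("MultiChannelImage", tensor = tens,
    sampleId = id, label = NA_character_,
    locations = cbind(row = rep(1L, dim(tens)[1]),
                      col = rep(1L, dim(tens)[1])))
  imgs <- lapply(1:6, function(s)
    mkImage(array(runif(3 * 4 * 4), c(3, 4, 4)), paste0("s", s)))
  cc <- interChannelCorrelation(imgs)
  expect_equal(dim(cc), c(3L, 3L))
  expect_equal(diag(cc), rep(1, 3))
  expect_equal(cc, t(cc))
  v1 <- unlist(lapply(imgs, function(im) as.numeric(im@tensor[1, , ])))
  v2 <- unlist(lapply(imgs, function(im) as.numeric(im@tensor[2, , ])))
  expect_equal(cc[1, 2], oraclePearson(v1, v2))

  # duplicated channel: off-diagonal exactly 1
  dup <- lapply(imgs, function(im) {
    t <- im@tensor; t[2, , ] <- t[1, , ]
    mkImage(t, im@sampleId)
  })
  expect_equal(interChannelCorrelation(dup)[1, 2], 1.0)

  # constant channel: correlation undefined, reported as 0 with a warning
  con <- lapply(imgs, function(im) {
    t <- im@tensor; t[3, , ] <- 0.5
    mkImage(t, im@sampleId)
  })
  expect_warning(cc0 <- interChannelCorrelation(con), "constant")
  expect_equal(cc0[1, 3], 0)
  expect_error(interChannelCorrelation(imgs[1]), "at least 2")
})

test_that("PCA component counts follow the covariance spectrum", {
  mkImage <- function(tens, id) new("MultiChannelImage", tensor = tens,
    sampleId = id, label = NA_character_,
    locations = cbind(row = rep(1L, dim(tens)[1]),
                      col = rep(1L, dim(tens)[1])))
  # rank-1 data: one component explains everything
  set.seed(47)
  base <- matrix(runif(16), 4, 4)
  r1 <- lapply(1:5, function(s) {
    t <- array(0, c(2, 4, 4))
    t[1, , ] <- base * (s / 5); t[2, , ] <- base * (s / 10)
    mkImage(t, paste0("s", s))
  })
  expect_equal(pcaComponentsForVariance(r1, 0.95), 1L)

  # random low-rank data: equality with the explicit covariance eigenvalues
  k <- 3
  W <- matrix(rnorm(k * 25), k, 25)
  imgs <- lapply(1:8, function(s) {
    t <- array(0, c(2, 5, 5))
    for (ch in 1:2) {
      z <- (matrix(rnorm(k), 1, k) %*% W)
      t[ch, , ] <- matrix((z - min(z)) / (max(z) - min(z)), 5, 5)
    }
    mkImage(t, paste0("s", s))
  })
  X <- do.call(rbind, lapply(imgs, function(im)
    rbind(as.numeric(im@tensor[1, , ]), as.numeric(im@tensor[2, , ]))))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12 * max(ev)]
  refK <- which(cumsum(ev) / sum(ev) >= 0.9 - 1e-12)[1]
  expect_equal(pcaComponentsForVariance(imgs, 0.9), as.integer(refK))
  expect_error(pcaComponentsForVariance(imgs, 1.5), "0, 1")
})
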