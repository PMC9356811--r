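checkerboard <- function(n) {
  greyImage(outer(1:n, 1:n, "+") %% 2L, levels = 2L)
}

test_that("co-occurrence counts match hand enumeration on tiny images", {
  img <- greyImage(rbind(c(0L, 0L), c(1L, 1L)), levels = 2L)
  m <- cooccurrence(img, 1, 0, symmetric = TRUE)
  expect_equal(glcmCounts(m), rbind(c(2, 0), c(0, 2)))
  expect_equal(glcmProbs(m), rbind(c(0.5, 0), c(0, 0.5)))

  cb <- checkerboard(4)
  expect_equal(glcmProbs(cooccurrence(cb, 1, 0)),
               rbind(c(0, 0.5), c(0.5, 0)))

  const <- greyImage(matrix(2L, 5, 5), levels = 4L)
  for (ang in c(0, 45, 90, 135)) {
    pr <- glcmProbs(cooccurrence(const, 1, ang))
    expect_equal(pr[3, 3], 1)
    expect_equal(sum(pr), 1)
  }
})

test_that("co-occurrence equals exhaustive pair enumeration on random images", {
  set.seed(101)
  for (i in 1:40) {
    G <- sample(2:8, 1)
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    img <- randomGrey(nr, nc, G)
    sym <- i %% 2 == 0
    for (d in 1:2) {
      for (ang in c(0, 45, 90, 135)) {
        m <- cooccurrence(img, d, ang, symmetric = sym)
        expect_identical(glcmCounts(m),
                         glcmOracle(pixels(img), G, d, ang, sym))
        expect_equal(sum(glcmProbs(m)), 1, tolerance = 1e-12)
        if (sym) expect_equal(glcmCounts(m), t(glcmCounts(m)))
      }
    }
  }
})

test_that("unsupported angles and empty offsets error", {
  img <- greyImage(matrix(0:3, 2, 2), 4L)
  expect_error(cooccurrence(img, 1, 30), "angle")
  expect_error(cooccurrence(img, 5, 0), "pairs")
  expect_error(cooccurrence(img, 0, 0), "distance")
})

test_that("averageMatrix is the element-wise mean and keeps normalization", {
  set.seed(102)
  img <- randomGrey(10, 10, 6L)
  mats <- lapply(c(0, 45, 90, 135), function(a) cooccurrence(img, 1, a))
  avg <- averageMatrix(mats)
  manual <- (glcmProbs(mats[[1]]) + glcmProbs(mats[[2]]) +
               glcmProbs(mats[[3]]) + glcmProbs(mats[[4]])) / 4
  expect_equal(glcmProbs(avg), manual, tolerance = 1e-15)
  expect_equal(sum(glcmProbs(avg)), 1, tolerance = 1e-12)
  expect_identical(avg@angle, "avg")
  ## four identical matrices average to themselves
  same <- averageMatrix(mats[c(1, 1, 1, 1)])
  expect_equal(glcmProbs(same), glcmProbs(mats[[1]]))
  ## mismatched levels rejected
  other <- cooccurrence(randomGrey(10, 10, 4L), 1, 0)
  expect_error(averageMatrix(c(mats[1:3], list(other))), "levels")
})

test_that("marginal moments match direct evaluation", {
  img <- greyImage(rbind(c(0L, 0L), c(1L, 1L)), levels = 2L)
  ms <- marginalStats(cooccurrence(img, 1, 0))
  ## probs diag(0.5, 0.5): mean 0.5, var 0.25
  expect_equal(ms@meanRow, 0.5)
  expect_equal(ms@varRow, 0.25)
  expect_equal(ms@meanCol, 0.5)
  expect_equal(ms@varCol, 0.25)

  const <- greyImage(matrix(3L, 4, 4), levels = 8L)
  ms2 <- marginalStats(cooccurrence(const, 1, 0))
  expect_equal(ms2@meanRow, 3)
  expect_equal(ms2@varRow, 0)

  set.seed(103)
  m <- cooccurrence(randomGrey(12, 12, 5L), 1, 45, symmetric = TRUE)
  ms3 <- marginalStats(m)
  expect_equal(ms3@meanRow, ms3@meanCol)
  expect_equal(ms3@varRow, ms3@varCol)
})

test_that("closed-form feature values hold for degenerate and checkerboard matrices", {
  const <- greyImage(matrix(5L, 6, 6), levels = 8L)
  suppressWarnings(fv <- featureValues(textureFeatures(cooccurrence(const, 1, 0))))
  expect_identical(fv[["entropy"]], 0)
  expect_identical(fv[["energy"]], 1)
  expect_identical(fv[["contrast"]], 0)
  expect_identical(fv[["homogeneity"]], 1)
  expect_identical(fv[["maximum_probability"]], 1)
  expect_identical(fv[["dissimilarity"]], 0)

  cb <- checkerboard(4)
  fv2 <- featureValues(textureFeatures(cooccurrence(cb, 1, 0)))
  expect_equal(fv2[["contrast"]], 1, tolerance = 1e-12)
  expect_equal(fv2[["dissimilarity"]], 1, tolerance = 1e-12)
  expect_equal(fv2[["energy"]], 0.5, tolerance = 1e-12)
  expect_equal(fv2[["homogeneity"]], 0.5, tolerance = 1e-12)
  expect_equal(fv2[["entropy"]], log(2), tolerance = 1e-12)
})

test_that("all 14 features agree with the brute-force double-loop oracle", {
  set.seed(104)
  for (i in 1:15) {
    G <- sample(2:8, 1)
    img <- randomGrey(sample(5:12, 1), sample(5:12, 1), G)
    m <- cooccurrence(img, 1, sample(c(0, 45, 90, 135), 1))
    got <- featureValues(textureFeatures(m))
    want <- featureOracle(glcmProbs(m))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("entropy and contrast take their extremes where expected", {
  ## equal mass on k nonzero cells maximizes entropy at log(k)
  pr <- matrix(0, 4, 4)
  pr[cbind(1:4, c(2, 3, 4, 1))] <- 0.25
  m <- new("CooccurrenceMatrix", counts = pr * 8, probs = pr,
           offset = c(0L, 1L), distance = 1L, angle = "0",
           symmetric = FALSE, levels = 4L)
  expect_equal(featureValues(textureFeatures(m))[["entropy"]], log(4))
  ## all mass on the diagonal iff contrast is zero
  set.seed(105)
  img <- randomGrey(10, 10, 5L)
  fv <- featureValues(textureFeatures(cooccurrence(img, 1, 0)))
  expect_gt(fv[["contrast"]], 0)
})

test_that("entropy base is configurable", {
  cb <- checkerboard(4)
  m <- cooccurrence(cb, 1, 0)
  expect_equal(featureValues(textureFeatures(m, base = 2))[["entropy"]], 1)
})

test_that("zero marginal variance reports correlation 0 with a warning", {
  const <- greyImage(matrix(1L, 4, 4), levels = 4L)
  expect_warning(fv <- textureFeatures(cooccurrence(const, 1, 0)),
                 "correlation")
  expect_identical(featureValues(fv)[["correlation"]], 0)
})

test_that("extractFeatures produces the five-matrix contract", {
  set.seed(106)
  img <- randomGrey(16, 16, 256L)
  five <- extractFeatures(img, levels = 8, which = "all")
  expect_named(five, c("a0", "a45", "a90", "a135", "avg"))
  four <- extractFeatures(img, levels = 8, which = "per-orientation")
  expect_length(four, 4L)
  one <- extractFeatures(img, levels = 8, which = "averaged")
  expect_s4_class(one, "TextureFeatures")
  ## constant image: all five vectors identical
  const <- greyImage(matrix(40L, 8, 8), 256L)
  suppressWarnings(fc <- extractFeatures(const, levels = 8, which = "all"))
  for (nm in names(fc)[-1]) {
    expect_identical(featureValues(fc[[nm]]), featureValues(fc[[1]]))
  }
})

test_that("stripes give higher contrast across than along the stripe direction", {
  ## horizontal stripes: rows alternate dark/bright
  p <- matrix(rep(c(0L, 7L), length.out = 16), 16, 16)
  img <- greyImage(p, levels = 8L)
  f <- extractFeatures(img, levels = 8, which = "per-orientation")
  c0 <- featureValues(f$a0)[["contrast"]]    # along the stripes
  c90 <- featureValues(f$a90)[["contrast"]]  # across the stripes
  expect_lt(c0, c90)
})

test_that("symmetric features at 0 degrees are invariant to left-right flips", {
  set.seed(107)
  img <- randomGrey(12, 12, 6L)
  flipped <- greyImage(pixels(img)[, 12:1], 6L)
  f1 <- featureValues(textureFeatures(cooccurrence(img, 1, 0)))
  f2 <- featureValues(textureFeatures(cooccurrence(flipped, 1, 0)))
  for (nm in c("contrast", "dissimilarity", "homogeneity", "energy")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12)
  }
})
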