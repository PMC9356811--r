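test_that("Gaussian membership has its closed-form values and symmetry", {
  expect_identical(membership(2, 2, 0.5), 1)
  expect_equal(membership(3, 2, 1), exp(-1 / 2))
  for (d in c(0.1, 1, 2.7)) {
    expect_equal(membership(2 + d, 2, 0.8), membership(2 - d, 2, 0.8))
  }
  expect_error(membership(Inf, 0, 1), "finite")
  expect_error(membership(0, 0, 0), "width")
})

test_that("fuzzify returns per-MF degrees matching membership calls", {
  m <- tinyModel()
  x <- c(f1 = 0.3, f2 = -0.4)
  deg <- fuzzify(x, m)
  expect_length(deg, 2L)
  expect_length(deg[[1]], 2L)
  for (f in 1:2) {
    for (j in 1:2) {
      expect_equal(deg[[f]][j],
                   membership(x[[f]], m@centers[[f]][j], m@widths[[f]][j]))
    }
  }
  ## input at every centre gives all degrees 1
  m1 <- anfisModel("f1", centers = list(c(0.7)), widths = list(c(1)),
                   rules = matrix(1L, 1, 1),
                   consequents = matrix(c(1, 0, 0), 1, 3))
  expect_equal(fuzzify(0.7, m1)[[1]], 1)
  expect_error(fuzzify(c(1, 2, 3), m), "feature count")
})

test_that("rule strengths are antecedent products and normalize to one", {
  m <- tinyModel()
  x <- c(0.2, -1.1)
  deg <- fuzzify(x, m)
  rs <- ruleStrengths(deg, m)
  want <- c(deg[[1]][1] * deg[[2]][1], deg[[1]][2] * deg[[2]][2])
  expect_equal(rs$raw, want, tolerance = 1e-12)
  expect_equal(rs$normalized, want / sum(want), tolerance = 1e-12)
  expect_equal(sum(rs$normalized), 1)
  ## a single rule always has normalized strength 1
  m1 <- anfisModel("f1", centers = list(0), widths = list(1),
                   rules = matrix(1L, 1, 1),
                   consequents = matrix(c(1, 0, 0), 1, 3))
  expect_equal(ruleStrengths(fuzzify(5, m1), m1)$normalized, 1)
  ## identical antecedents share the strength equally
  m2 <- anfisModel("f1", centers = list(0), widths = list(1),
                   rules = matrix(1L, 3, 1),
                   consequents = diag(3))
  expect_equal(ruleStrengths(fuzzify(1.3, m2), m2)$normalized,
               rep(1 / 3, 3))
})

test_that("scores are normalized-strength-weighted consequents", {
  m <- tinyModel()
  set.seed(301)
  for (i in 1:10) {
    x <- rnorm(2)
    rs <- ruleStrengths(fuzzify(x, m), m)
    want <- drop(rs$normalized %*% m@consequents)
    expect_equal(drop(predictScores(x, m)), structure(want,
      names = m@classes), tolerance = 1e-12)
  }
  ## one rule: scores equal its consequent for any input
  m1 <- anfisModel("f1", centers = list(0), widths = list(1),
                   rules = matrix(1L, 1, 1),
                   consequents = matrix(c(1, 0, 0), 1, 3))
  expect_equal(drop(predictScores(99, m1)),
               c(normal = 1, benign = 0, malignant = 0))
  ## equal consequents give equal scores regardless of input
  m2 <- anfisModel("f1", centers = list(c(-1, 1)),
                   widths = list(c(1, 1)), rules = matrix(1:2, 2, 1),
                   consequents = matrix(0.4, 2, 3))
  expect_equal(unname(drop(predictScores(0.77, m2))), rep(0.4, 3))
})

test_that("scores stay within the consequent hull (convex combination)", {
  m <- tinyModel()
  set.seed(302)
  for (i in 1:20) {
    s <- drop(predictScores(rnorm(2, sd = 3), m))
    for (cc in 1:3) {
      expect_gte(s[cc], min(m@consequents[, cc]) - 1e-12)
      expect_lte(s[cc], max(m@consequents[, cc]) + 1e-12)
    }
  }
})

test_that("predictLabel is argmax with ties to the earlier class", {
  m <- tinyModel()
  set.seed(303)
  for (i in 1:20) {
    x <- rnorm(2)
    s <- drop(predictScores(x, m))
    expect_identical(predictLabel(x, m), m@classes[which.max(s)])
  }
  ## exact tie between the first two classes resolves to "normal"
  mt <- anfisModel("f1", centers = list(0), widths = list(1),
                   rules = matrix(1L, 1, 1),
                   consequents = matrix(c(0.5, 0.5, 0.1), 1, 3))
  expect_identical(predictLabel(0, mt), "normal")
  expect_identical(predict(mt, 0), "normal")
})

test_that("loss is weighted squared error", {
  expect_identical(anfisLoss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_identical(anfisLoss(c(1, 0, 0), c(0, 1, 0)), 2)
  set.seed(304)
  for (i in 1:10) {
    s <- rnorm(3); t <- rnorm(3); q <- runif(3)
    expect_equal(anfisLoss(s, t, q), sum(q * (s - t)^2))
  }
})

test_that("analytic gradients match central finite differences", {
  m <- tinyModel()
  set.seed(305)
  x <- matrix(rnorm(10), 5, 2)
  target <- tumortex:::.oneHot(sample(m@classes, 5, replace = TRUE),
                               m@classes)
  g <- tumortex:::.anfisGradient(m, x, target)
  n <- numericAnfisGradient(m, x, target)
  relErr <- function(a, b) {
    abs(a - b) / pmax(1e-8, abs(a) + abs(b))
  }
  for (f in 1:2) {
    expect_true(all(relErr(g$centers[[f]], n$centers[[f]]) < 1e-5))
    expect_true(all(relErr(g$widths[[f]], n$widths[[f]]) < 1e-5))
  }
  expect_true(all(relErr(g$consequents, n$consequents) < 1e-5))
})

test_that("momentum zero reduces to one plain gradient step", {
  m <- tinyModel()
  set.seed(306)
  x <- matrix(rnorm(8), 4, 2)
  labs <- sample(m@classes, 4, replace = TRUE)
  target <- tumortex:::.oneHot(labs, m@classes)
  g <- tumortex:::.anfisGradient(m, x, target)
  eta <- 0.01
  n <- nrow(x)  # the step uses the batch-averaged gradient
  fit <- trainAnfis(m, x, labs, epochs = 1, learningRate = eta,
                    momentum = 0)
  for (f in 1:2) {
    expect_equal(fit$model@centers[[f]],
                 m@centers[[f]] - eta * g$centers[[f]] / n,
                 tolerance = 1e-12)
    expect_equal(fit$model@widths[[f]],
                 pmax(1e-3, m@widths[[f]] - eta * g$widths[[f]] / n),
                 tolerance = 1e-12)
  }
  expect_equal(fit$model@consequents,
               m@consequents - eta * g$consequents / n, tolerance = 1e-12)
  expect_identical(traceErrors(fit$trace), g$loss)
})

test_that("training reduces the loss on data generated from the model", {
  m <- tinyModel()
  set.seed(307)
  x <- matrix(rnorm(60, sd = 1.5), 30, 2)
  labs <- predictLabel(x, m)
  fit <- trainAnfis(m, x, labs, epochs = 50, learningRate = 0.01,
                    momentum = 0.5)
  err <- traceErrors(fit$trace)
  expect_lte(err[length(err)], err[1])
  expect_true(all(err >= 0))
  expect_identical(fit$trace@finalEpoch, 50L)
})

test_that("training is deterministic and validates its inputs", {
  set.seed(308)
  cl <- makeFeatureClusters(10, separation = 6, dims = 3, seed = 9)
  m <- initAnfis(cl$x, cl$labels, seed = 9)
  f1 <- trainAnfis(m, cl$x, cl$labels, epochs = 20)
  f2 <- trainAnfis(m, cl$x, cl$labels, epochs = 20)
  expect_identical(f1$model@centers, f2$model@centers)
  expect_identical(f1$model@consequents, f2$model@consequents)
  expect_identical(traceErrors(f1$trace), traceErrors(f2$trace))
  expect_error(trainAnfis(m, cl$x[0, , drop = FALSE], character(0)),
               "empty")
  expect_error(trainAnfis(m, cl$x, rep("odd", nrow(cl$x))), "classes")
  expect_error(trainAnfis(m, cl$x, cl$labels, epochs = 0), "epochs")
})

test_that("well-separated clusters are classified almost perfectly", {
  cl <- makeFeatureClusters(50, separation = 10, dims = 14, seed = 42)
  m0 <- initAnfis(cl$x, cl$labels, seed = 42)
  fit <- trainAnfis(m0, cl$x, cl$labels, epochs = 200)
  acc <- mean(predictLabel(cl$x, fit$model) == cl$labels)
  expect_gte(acc, 0.95)
})

test_that("quantile initialization places centres and positive widths", {
  set.seed(309)
  x <- matrix(runif(400), 200, 2)
  m <- initAnfis(x, mfsPerFeature = 2L, seed = 1)
  ## standardized uniform sample: centres near the 1/3 and 2/3 quantiles
  z <- scale(x)
  for (f in 1:2) {
    qs <- unname(quantile(z[, f], c(1 / 3, 2 / 3)))
    expect_equal(m@centers[[f]], qs, tolerance = 1e-6)
    expect_true(all(m@widths[[f]] > 0))
  }
  expect_identical(nrow(m@rules), 4L)  # full 2x2 grid
  ## deterministic layout
  m2 <- initAnfis(x, mfsPerFeature = 2L, seed = 1)
  expect_identical(m@centers, m2@centers)
  expect_error(initAnfis(x, mfsPerFeature = 0L), "mfsPerFeature")
})

test_that("high-dimensional initialization falls back to per-class rules", {
  cl <- makeFeatureClusters(20, separation = 8, dims = 14, seed = 5)
  m <- initAnfis(cl$x, cl$labels, seed = 5)
  expect_identical(nrow(m@rules), 3L)
  expect_identical(m@consequents, diag(3))
  expect_true(all(unlist(m@widths) > 0))
})

test_that("a refit recovers generating membership centres up to permutation", {
  ## data from a known 1-feature, 2-rule model with centres -2 and 2
  gen <- anfisModel("f1", centers = list(c(-2, 2)),
                    widths = list(c(0.6, 0.6)),
                    rules = matrix(1:2, 2, 1),
                    consequents = rbind(c(1, 0, 0), c(0, 1, 0)))
  set.seed(310)
  x <- matrix(c(rnorm(100, -2, 0.5), rnorm(100, 2, 0.5)), ncol = 1)
  labs <- predictLabel(x, gen)
  m0 <- initAnfis(x, labs, mfsPerFeature = 2L, seed = 310,
                  learningRate = 0.002, momentum = 0.5)
  fit <- trainAnfis(m0, x, labs, epochs = 150)
  ## compare in raw units (undo the stored standardization)
  got <- sort(fit$model@centers[[1]] * fit$model@standardizeSd +
                fit$model@standardizeMean)
  expect_equal(got, c(-2, 2), tolerance = 0.35)
})

test_that("model JSON round trip reproduces predictions bit-identically", {
  cl <- makeFeatureClusters(15, separation = 8, dims = 14, seed = 77)
  m0 <- initAnfis(cl$x, cl$labels, seed = 77)
  fit <- trainAnfis(m0, cl$x, cl$labels, epochs = 30)
  path <- withr::local_tempfile(fileext = ".json")
  saveAnfisModel(fit$model, path)
  back <- loadAnfisModel(path)
  expect_identical(predictScores(cl$x, back),
                   predictScores(cl$x, fit$model))
  expect_identical(back@version, fit$model@version)
  ## missing field is a schema error
  obj <- jsonlite::read_json(path)
  obj$rules <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, digits = NA, auto_unbox = TRUE)
  expect_error(loadAnfisModel(path2), "missing fields")
})
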