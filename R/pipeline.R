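#' Seeded stratified train/test split
#'
#' Splits observation indices by class so both partitions keep the class
#' proportions; the number of training items per class is
#' `round(trainFrac * n_class)`.
#'
#' @param labels Character vector of class labels.
#' @param trainFrac Fraction assigned to the training set (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, trainFrac = 0.7, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1) {
    stop("'trainFrac' must lie strictly between 0 and 1")
  }
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- round(trainFrac * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Confusion matrix and summary statistics
#'
#' @param predicted,truth Character vectors of predicted and true class
#'   labels.
#' @param classes Ordered class labels fixing the matrix layout.
#' @return List with `confusion` (rows = truth, cols = predicted),
#'   `accuracy` (`trace / total`), per-class `precision` and `recall`
#'   (0/0 reported as 0 and listed in `undefined`), and `n`.
#' @export
evaluatePredictions <- function(predicted, truth,
                                classes = classLabels()) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have the same length")
  }
  conf <- table(factor(truth, levels = classes),
                factor(predicted, levels = classes))
  conf <- matrix(as.integer(conf), length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  total <- sum(conf)
  prec <- numeric(length(classes))
  rec <- numeric(length(classes))
  undef <- character(0)
  for (i in seq_along(classes)) {
    pc <- sum(conf[, i])
    tc <- sum(conf[i, ])
    prec[i] <- if (pc > 0) conf[i, i] / pc else 0
    rec[i] <- if (tc > 0) conf[i, i] / tc else 0
    if (pc == 0) undef <- c(undef, paste0("precision:", classes[i]))
    if (tc == 0) undef <- c(undef, paste0("recall:", classes[i]))
  }
  names(prec) <- classes
  names(rec) <- classes
  list(
    confusion = conf,
    accuracy = sum(diag(conf)) / total,
    precision = prec, recall = rec,
    undefined = undef, n = total
  )
}

#' Default end-to-end pipeline configuration
#'
#' @param nPerClass Synthetic images per class (default 30).
#' @param size Image side in pixels (default 64; see [syntheticSpec()]).
#' @param seed Global seed for simulation, split and training.
#' @param levels,distance GLCM quantization levels and pixel distance.
#' @param gaussianSigma,sharpenAmount Preprocessing parameters.
#' @param trainFrac Stratified train fraction.
#' @param epochs,learningRate,momentum ANFIS training parameters.
#' @return Named list of settings for [runPipeline()].
#' @export
pipelineConfig <- function(nPerClass = 30L, size = 64L, seed = 1L,
                           levels = 8L, distance = 1L,
                           gaussianSigma = 1.0, sharpenAmount = 0.5,
                           trainFrac = 0.7, epochs = 150L,
                           learningRate = 0.05, momentum = 0.9) {
  list(
    nPerClass = as.integer(nPerClass), size = as.integer(size),
    seed = as.integer(seed), levels = as.integer(levels),
    distance = as.integer(distance), gaussianSigma = gaussianSigma,
    sharpenAmount = sharpenAmount, trainFrac = trainFrac,
    epochs = as.integer(epochs), learningRate = learningRate,
    momentum = momentum
  )
}

#' Run the full synthetic-texture classification pipeline
#'
#' simulate -> preprocess -> GLCM features (averaged matrix) -> stratified
#' split -> ANFIS training -> classification -> evaluation. Fully
#' deterministic under the config's seed: repeated runs produce identical
#' reports.
#'
#' @param config Settings from [pipelineConfig()].
#' @param outDir Optional directory; when given, the feature table, model
#'   JSON, report JSON and a human-readable report are written there.
#' @return List with `report` (see [evaluatePredictions()] plus
#'   `trainAccuracy`), `model`, `trace`, `features` (matrix), `labels`,
#'   `split` and `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  spec <- syntheticSpec(size = config$size)
  data <- makeDataset(config$nPerClass, spec, seed = config$seed)
  if (!length(data)) stop("data error: empty synthetic dataset")
  labels <- vapply(data, `[[`, character(1L), "label")

  feats <- t(vapply(data, function(item) {
    img <- preprocessImage(item$image,
                           gaussianSigma = config$gaussianSigma,
                           sharpenAmount = config$sharpenAmount)
    featureValues(extractFeatures(img, levels = config$levels,
                                  distance = config$distance,
                                  which = "averaged"))
  }, numeric(length(.FEATURE_NAMES))))

  split <- stratifiedSplit(labels, trainFrac = config$trainFrac,
                           seed = config$seed)
  model0 <- initAnfis(feats[split$train, , drop = FALSE],
                      labels = labels[split$train],
                      seed = config$seed,
                      learningRate = config$learningRate,
                      momentum = config$momentum)
  fit <- trainAnfis(model0, feats[split$train, , drop = FALSE],
                    labels[split$train], epochs = config$epochs)

  predTrain <- predictLabel(feats[split$train, , drop = FALSE], fit$model)
  predTest <- predictLabel(feats[split$test, , drop = FALSE], fit$model)
  report <- evaluatePredictions(predTest, labels[split$test])
  report$trainAccuracy <-
    mean(predTrain == labels[split$train])

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(seq_along(labels), function(i) {
      list(id = sprintf("img%03d", i), label = labels[i],
           features = feats[i, ])
    })
    writeFeatureTable(rows, file.path(outDir, "features.csv"),
                      prefix = "avg_")
    saveAnfisModel(fit$model, file.path(outDir, "model.json"))
    jsonlite::write_json(
      list(config = config,
           confusion = report$confusion,
           accuracy = report$accuracy,
           precision = as.list(report$precision),
           recall = as.list(report$recall),
           train_accuracy = report$trainAccuracy,
           n_test = report$n),
      file.path(outDir, "report.json"), digits = NA, auto_unbox = TRUE
    )
    txt <- c(
      "Synthetic texture classification report",
      sprintf("seed=%d  images/class=%d  size=%dpx", config$seed,
              config$nPerClass, config$size),
      sprintf("held-out accuracy: %.4f (n=%d)", report$accuracy,
              report$n),
      "confusion (rows truth, cols predicted):",
      utils::capture.output(print(report$confusion))
    )
    writeLines(txt, file.path(outDir, "report.txt"))
  }
  list(report = report, model = fit$model, trace = fit$trace,
       features = feats, labels = labels, split = split,
       config = config)
}
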