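.ANFIS_SCHEMA <- "tumortex-anfis-1"

#' Construct an AnfisModel directly
#'
#' Low-level constructor used by [initAnfis()] and in tests; most users
#' should start from [initAnfis()].
#'
#' @param featureNames Ordered feature names.
#' @param centers,widths Lists (per feature) of membership centers and
#'   widths, in standardized feature units.
#' @param rules Integer matrix (rules x features) of antecedent membership
#'   indices.
#' @param consequents Numeric matrix (rules x classes).
#' @param classes Ordered class labels.
#' @param standardizeMean,standardizeSd Per-feature z-score statistics
#'   (defaults: mean 0, sd 1, i.e. no standardization).
#' @param learningRate Step size `eta > 0`.
#' @param momentum Momentum `rho` in `[0, 1)`.
#' @param seed Integer seed recorded in the model.
#' @return An [AnfisModel-class].
#' @export
anfisModel <- function(featureNames, centers, widths, rules, consequents,
                       classes = classLabels(),
                       standardizeMean = rep(0, length(featureNames)),
                       standardizeSd = rep(1, length(featureNames)),
                       learningRate = 0.05, momentum = 0.9,
                       seed = 1L) {
  if (!is.matrix(rules)) rules <- matrix(rules, ncol = length(featureNames))
  storage.mode(rules) <- "integer"
  new("AnfisModel",
    featureNames = featureNames, classes = classes,
    centers = lapply(centers, as.numeric),
    widths = lapply(widths, as.numeric),
    rules = rules, consequents = as.matrix(consequents),
    standardizeMean = as.numeric(standardizeMean),
    standardizeSd = as.numeric(standardizeSd),
    learningRate = learningRate, momentum = momentum,
    seed = as.integer(seed), version = .ANFIS_SCHEMA
  )
}

#' Gaussian membership value
#'
#' The degree to which a crisp input belongs to a fuzzy set with the given
#' centre and width: `exp(-(x - center)^2 / (2 width^2))`, in `(0, 1]` for
#' finite inputs and exactly 1 at the centre.
#'
#' @param x Numeric input (finite).
#' @param center Membership centre.
#' @param width Membership width `sigma > 0`.
#' @return Membership degree in `(0, 1]`.
#' @export
#' @examples
#' membership(0, 0, 1)        # 1
#' membership(1, 0, 1)        # exp(-1/2)
membership <- function(x, center, width) {
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (any(width <= 0)) stop("'width' must be positive")
  exp(-(x - center)^2 / (2 * width^2))
}

## Standardize a feature matrix (n x F) with the model's stored statistics.
.standardize <- function(model, x) {
  sweep(sweep(x, 2L, model@standardizeMean, "-"),
        2L, model@standardizeSd, "/")
}

## Coerce features to a 1 x F or n x F numeric matrix in model order.
.featureMatrix <- function(model, features) {
  if (is(features, "TextureFeatures")) features <- features@values
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != length(model@featureNames)) {
    stop("feature count does not match the model's feature_names")
  }
  features
}

#' Fuzzification: membership degrees of each feature
#'
#' Evaluates, for every input feature, its membership degree in each of
#' that feature's fuzzy sets.
#'
#' @param features A [TextureFeatures-class] or numeric vector in the
#'   model's feature order (raw units; standardization is applied
#'   internally).
#' @param model An [AnfisModel-class].
#' @return A list, one numeric vector of degrees per feature.
#' @export
fuzzify <- function(features, model) {
  stopifnot(is(model, "AnfisModel"))
  x <- .featureMatrix(model, features)
  if (nrow(x) != 1L) stop("fuzzify takes a single feature vector")
  z <- .standardize(model, x)
  lapply(seq_along(model@featureNames), function(f) {
    membership(z[1L, f], model@centers[[f]], model@widths[[f]])
  })
}

## Forward pass over an n x F raw feature matrix. Firing strengths are
## normalized through log-space (log-sum-exp), so products of many small
## Gaussian factors cannot underflow the normalization.
## Returns list(logW, What, scores).
.anfisForward <- function(model, x) {
  z <- .standardize(model, x)
  n <- nrow(z)
  R <- nrow(model@rules)
  Fd <- length(model@featureNames)
  logW <- matrix(0, n, R)
  for (f in seq_len(Fd)) {
    cen <- model@centers[[f]][model@rules[, f]]
    wid <- model@widths[[f]][model@rules[, f]]
    d <- outer(z[, f], cen, "-")
    logW <- logW - sweep(d^2, 2L, 2 * wid^2, "/")
  }
  mx <- apply(logW, 1L, max)
  W <- exp(logW - mx)
  What <- W / rowSums(W)
  list(logW = logW, What = What, scores = What %*% model@consequents)
}

#' Rule firing strengths
#'
#' The firing strength of a rule is the product (t-norm) over features of
#' the membership degree of the rule's antecedent fuzzy set; normalized
#' strengths sum to 1.
#'
#' @param degrees Output of [fuzzify()], or a raw feature vector /
#'   [TextureFeatures-class] (fuzzified internally).
#' @param model An [AnfisModel-class].
#' @return List with `raw` (product strengths) and `normalized` (summing
#'   to 1).
#' @export
ruleStrengths <- function(degrees, model) {
  stopifnot(is(model, "AnfisModel"))
  if (!is.list(degrees)) degrees <- fuzzify(degrees, model)
  R <- nrow(model@rules)
  raw <- vapply(seq_len(R), function(r) {
    prod(vapply(seq_along(degrees), function(f) {
      degrees[[f]][model@rules[r, f]]
    }, numeric(1L)))
  }, numeric(1L))
  logW <- vapply(seq_len(R), function(r) {
    sum(vapply(seq_along(degrees), function(f) {
      log(degrees[[f]][model@rules[r, f]])
    }, numeric(1L)))
  }, numeric(1L))
  if (all(!is.finite(logW))) {
    stop("degenerate input: all rule strengths vanished")
  }
  w <- exp(logW - max(logW))
  list(raw = raw, normalized = w / sum(w))
}

#' Per-class scores (defuzzification)
#'
#' `score_c = sum_r normalized_strength_r * consequent_{r,c}` — a convex
#' combination of the rule consequent weights.
#'
#' @param features A [TextureFeatures-class], numeric vector, or numeric
#'   matrix (one row per observation) in model feature order.
#' @param model An [AnfisModel-class].
#' @return Numeric matrix (observations x classes) of scores, with class
#'   column names.
#' @export
predictScores <- function(features, model) {
  stopifnot(is(model, "AnfisModel"))
  x <- .featureMatrix(model, features)
  s <- .anfisForward(model, x)$scores
  colnames(s) <- model@classes
  s
}

#' Predicted class labels
#'
#' Argmax of the per-class scores; exact ties break towards the earlier
#' class in the model's class order (normal before benign before
#' malignant).
#'
#' @inheritParams predictScores
#' @return Character vector of class labels.
#' @export
predictLabel <- function(features, model) {
  s <- predictScores(features, model)
  model@classes[apply(s, 1L, which.max)]
}

#' @describeIn AnfisModel-class predict class labels for new data (alias of
#'   [predictLabel()])
#' @param object an `AnfisModel`
#' @param features feature vector/matrix in model feature order
#' @export
setMethod("predict", "AnfisModel", function(object, features) {
  predictLabel(features, object)
})

#' Squared-error classification loss
#'
#' `sum_c q_c (score_c - target_c)^2`: non-negative, zero exactly at a
#' perfect match. The per-class weights `q` default to 1.
#'
#' @param scores Numeric score vector (one observation) or matrix.
#' @param target One-hot target vector or matrix of the same shape.
#' @param q Optional per-class weights (default all 1).
#' @return Total loss (summed over observations).
#' @export
anfisLoss <- function(scores, target, q = NULL) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  scores <- as.matrix(scores)
  target <- as.matrix(target)
  if (!all(dim(scores) == dim(target))) {
    ## allow a vector target against a 1-row score matrix and vice versa
    if (length(scores) == length(target)) {
      target <- matrix(as.numeric(target), nrow(scores), ncol(scores))
    } else {
      stop("scores and target must have the same shape")
    }
  }
  if (is.null(q)) q <- rep(1, ncol(scores))
  sum(sweep((scores - target)^2, 2L, q, "*"))
}

## One-hot encode labels against the model's class order.
.oneHot <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("label not among the model's classes")
  T <- matrix(0, length(labels), length(classes))
  T[cbind(seq_along(labels), idx)] <- 1
  T
}

## Analytic gradients of the total squared-error loss with respect to all
## trainable parameters (membership centers/widths per feature, rule
## consequents), plus the loss itself. x is n x F raw features, target is
## the n x C one-hot matrix.
.anfisGradient <- function(model, x, target) {
  z <- .standardize(model, x)
  fw <- .anfisForward(model, x)
  What <- fw$What
  Y <- fw$scores
  D <- 2 * (Y - target)                       # dE/dY
  gradQ <- t(What) %*% D                      # rules x classes
  ## dE/d logW_r through the softmax-style normalization:
  ## A[n, r] = What[n, r] * ( (D Q^T)[n, r] - sum_c D[n, c] Y[n, c] )
  A <- What * ((D %*% t(model@consequents)) - rowSums(D * Y))
  Fd <- length(model@featureNames)
  gradC <- vector("list", Fd)
  gradS <- vector("list", Fd)
  for (f in seq_len(Fd)) {
    nm <- length(model@centers[[f]])
    gc <- numeric(nm); gs <- numeric(nm)
    for (j in seq_len(nm)) {
      rr <- which(model@rules[, f] == j)
      if (!length(rr)) next
      cen <- model@centers[[f]][j]
      wid <- model@widths[[f]][j]
      dz <- z[, f] - cen
      Aj <- A[, rr, drop = FALSE]
      s <- rowSums(Aj)
      ## d logW / d center = (z - c) / sigma^2 ; d logW / d sigma = dz^2/s^3
      gc[j] <- sum(s * dz / wid^2)
      gs[j] <- sum(s * dz^2 / wid^3)
    }
    gradC[[f]] <- gc
    gradS[[f]] <- gs
  }
  list(loss = sum((Y - target)^2), centers = gradC, widths = gradS,
       consequents = gradQ)
}

#' Train an ANFIS model by gradient descent with momentum
#'
#' Full-batch gradient descent on the squared-error loss over all trainable
#' parameters (membership centres and widths, rule consequent weights).
#' Each update is `delta <- momentum * delta - eta * gradient;
#' theta <- theta + delta`, the classical momentum rule, where the
#' gradient is that of the per-observation mean loss (so the step size is
#' insensitive to the dataset size); with `momentum = 0` one epoch is a
#' single plain gradient step. Membership widths are clamped to a floor of
#' `1e-3` (standardized units) after every step. The recorded trace holds
#' the total (summed) loss per epoch, measured before each update.
#' Deterministic for a fixed seed, data and configuration.
#'
#' @param model An [AnfisModel-class] (see [initAnfis()]).
#' @param x Numeric matrix (observations x features), raw feature units.
#' @param labels Character vector of class labels, one per row of `x`.
#' @param epochs Number of full-batch epochs (`>= 1`).
#' @param learningRate,momentum Override the model's stored `eta` / `rho`.
#' @param widthFloor Lower clamp for membership widths.
#' @return List with components `model` (the trained [AnfisModel-class])
#'   and `trace` (a [TrainingTrace-class] of per-epoch losses, recorded
#'   before each update).
#' @export
trainAnfis <- function(model, x, labels, epochs = 200L,
                       learningRate = model@learningRate,
                       momentum = model@momentum,
                       widthFloor = 1e-3) {
  stopifnot(is(model, "AnfisModel"))
  x <- .featureMatrix(model, x)
  if (nrow(x) == 0L) stop("empty training dataset")
  if (length(labels) != nrow(x)) stop("one label per observation required")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("'epochs' must be >= 1")
  target <- .oneHot(labels, model@classes)

  velC <- lapply(model@centers, function(v) numeric(length(v)))
  velS <- lapply(model@widths, function(v) numeric(length(v)))
  velQ <- matrix(0, nrow(model@consequents), ncol(model@consequents))
  errors <- numeric(epochs)

  n <- nrow(x)
  for (e in seq_len(epochs)) {
    g <- .anfisGradient(model, x, target)
    if (!is.finite(g$loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", e))
    }
    errors[e] <- g$loss
    for (f in seq_along(model@centers)) {
      velC[[f]] <- momentum * velC[[f]] -
        learningRate * g$centers[[f]] / n
      velS[[f]] <- momentum * velS[[f]] -
        learningRate * g$widths[[f]] / n
      model@centers[[f]] <- model@centers[[f]] + velC[[f]]
      model@widths[[f]] <- pmax(widthFloor,
                                model@widths[[f]] + velS[[f]])
    }
    velQ <- momentum * velQ - learningRate * g$consequents / n
    model@consequents <- model@consequents + velQ
  }
  list(model = model,
       trace = new("TrainingTrace", errors = errors,
                   finalEpoch = epochs))
}

#' Initialize an ANFIS model from data
#'
#' Stores z-score statistics of the training features and lays out the
#' membership functions and rule base:
#' \itemize{
#'   \item When the full grid of membership combinations is small
#'     (`mfsPerFeature ^ nFeatures <= maxRules`), each feature gets
#'     `mfsPerFeature` membership functions centred at equally spaced
#'     quantiles of the standardized data (levels `k/(m+1)`), widths half
#'     the centre spacing (floored), and the rule base is the full grid;
#'     consequents start at the all-classes-equal value `1/C`.
#'   \item Otherwise one rule per class is seeded at the class medians:
#'     each feature gets one membership function per class centred at that
#'     class's median, width the feature's overall standard deviation
#'     (floored), and consequents are the class indicators.
#' }
#'
#' @param x Numeric matrix (observations x features).
#' @param labels Class labels, one per row (required for the per-class rule
#'   layout; may be `NULL` when the grid layout applies).
#' @param mfsPerFeature Membership functions per feature for the grid
#'   layout (default 2).
#' @param classes Ordered class labels.
#' @param featureNames Feature names (default: column names of `x` or the
#'   14 texture names).
#' @param seed Integer seed recorded in the model.
#' @param learningRate,momentum Training hyper-parameters stored in the
#'   model.
#' @param maxRules Grid layouts above this rule count fall back to
#'   per-class rules (default 64).
#' @return An [AnfisModel-class].
#' @export
initAnfis <- function(x, labels = NULL, mfsPerFeature = 2L,
                      classes = classLabels(), featureNames = NULL,
                      seed = 1L, learningRate = 0.05, momentum = 0.9,
                      maxRules = 64L) {
  x <- as.matrix(x)
  if (mfsPerFeature < 1L) stop("'mfsPerFeature' must be >= 1")
  Fd <- ncol(x)
  if (is.null(featureNames)) {
    featureNames <- if (!is.null(colnames(x))) colnames(x)
      else if (Fd == 14L) .FEATURE_NAMES else paste0("f", seq_len(Fd))
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  nC <- length(classes)
  gridSize <- mfsPerFeature^Fd
  widthFloor <- 1e-3

  if (gridSize <= maxRules) {
    centers <- vector("list", Fd)
    widths <- vector("list", Fd)
    for (f in seq_len(Fd)) {
      qs <- stats::quantile(z[, f],
                            probs = seq_len(mfsPerFeature) /
                              (mfsPerFeature + 1), names = FALSE,
                            type = 7)
      centers[[f]] <- qs
      spacing <- if (mfsPerFeature > 1L) diff(range(qs)) /
        (mfsPerFeature - 1L) else 2
      widths[[f]] <- rep(max(widthFloor, spacing / 2), mfsPerFeature)
    }
    rules <- as.matrix(expand.grid(rep(list(seq_len(mfsPerFeature)), Fd)))
    dimnames(rules) <- NULL
    consequents <- matrix(1 / nC, nrow(rules), nC)
  } else {
    if (is.null(labels)) {
      stop("labels are required for the per-class rule layout")
    }
    idx <- match(labels, classes)
    if (anyNA(idx)) stop("label not among 'classes'")
    centers <- vector("list", Fd)
    widths <- vector("list", Fd)
    for (f in seq_len(Fd)) {
      med <- vapply(seq_len(nC), function(cl) {
        stats::median(z[idx == cl, f])
      }, numeric(1L))
      med[!is.finite(med)] <- 0
      centers[[f]] <- med
      widths[[f]] <- rep(max(widthFloor, stats::sd(z[, f])), nC)
    }
    rules <- matrix(rep(seq_len(nC), Fd), nC, Fd)
    consequents <- diag(nC)
  }
  anfisModel(
    featureNames = featureNames, centers = centers, widths = widths,
    rules = rules, consequents = consequents, classes = classes,
    standardizeMean = mu, standardizeSd = sdv,
    learningRate = learningRate, momentum = momentum, seed = seed
  )
}

#' Save an ANFIS model to JSON
#'
#' Writes the versioned JSON schema; [loadAnfisModel()] reproduces the
#' model's predictions bit-identically.
#'
#' @param model An [AnfisModel-class].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
saveAnfisModel <- function(model, path) {
  stopifnot(is(model, "AnfisModel"))
  obj <- list(
    version = model@version,
    feature_names = model@featureNames,
    classes = model@classes,
    centers = model@centers,
    widths = model@widths,
    rules = model@rules,
    consequents = model@consequents,
    standardize_mean = model@standardizeMean,
    standardize_sd = model@standardizeSd,
    learning_rate = model@learningRate,
    momentum = model@momentum,
    seed = model@seed
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load an ANFIS model from JSON
#'
#' @param path Path to a file written by [saveAnfisModel()].
#' @return An [AnfisModel-class].
#' @export
loadAnfisModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("version", "feature_names", "classes", "centers", "widths",
            "rules", "consequents", "standardize_mean", "standardize_sd",
            "learning_rate", "momentum", "seed")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("model file is missing fields: ", paste(miss, collapse = ", "))
  }
  if (!identical(obj$version, .ANFIS_SCHEMA)) {
    stop("unsupported model schema version: ", obj$version)
  }
  cen <- obj$centers
  wid <- obj$widths
  if (is.matrix(cen)) cen <- asplit(cen, 1L)  # jsonlite may simplify
  if (is.matrix(wid)) wid <- asplit(wid, 1L)
  nf <- length(obj$feature_names)
  rules <- if (is.matrix(obj$rules)) obj$rules else
    matrix(obj$rules, ncol = nf)
  anfisModel(
    featureNames = obj$feature_names,
    centers = lapply(cen, as.numeric),
    widths = lapply(wid, as.numeric),
    rules = matrix(as.integer(rules), nrow = nrow(rules)),
    consequents = obj$consequents, classes = obj$classes,
    standardizeMean = obj$standardize_mean,
    standardizeSd = obj$standardize_sd,
    learningRate = obj$learning_rate, momentum = obj$momentum,
    seed = obj$seed
  )
}
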