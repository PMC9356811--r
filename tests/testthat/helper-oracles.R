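## Independent brute-force oracles the implementation is checked against.
## These deliberately use naive per-pixel loops and stay independent of the
## package's vectorized code paths.

## Exhaustive pair enumeration for the co-occurrence counts.
glcmOracle <- function(pix, G, d, angle, symmetric = TRUE) {
  off <- switch(as.character(angle),
    "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0, G, G)
  nr <- nrow(pix); nc <- ncol(pix)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- pix[r, c] + 1L; b <- pix[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1
        if (symmetric) counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts
}

## All 14 texture statistics from a normalized matrix by explicit loops.
featureOracle <- function(pr) {
  G <- nrow(pr)
  autoc <- 0; contrast <- 0; dissim <- 0; energy <- 0; ent <- 0
  homog <- 0
  prow <- rowSums(pr); pcol <- colSums(pr)
  lv <- 0:(G - 1)
  mr <- sum(lv * prow); mc <- sum(lv * pcol)
  vr <- sum((lv - mr)^2 * prow); vc <- sum((lv - mc)^2 * pcol)
  psum <- numeric(2 * G - 1); pdiff <- numeric(G)
  for (a in 0:(G - 1)) {
    for (b in 0:(G - 1)) {
      p <- pr[a + 1, b + 1]
      autoc <- autoc + a * b * p
      contrast <- contrast + (a - b)^2 * p
      dissim <- dissim + abs(a - b) * p
      energy <- energy + p^2
      if (p > 0) ent <- ent - p * log(p)
      homog <- homog + p / (1 + (a - b)^2)
      psum[a + b + 1] <- psum[a + b + 1] + p
      pdiff[abs(a - b) + 1] <- pdiff[abs(a - b) + 1] + p
    }
  }
  corr <- if (vr > 0 && vc > 0) (autoc - mr * mc) / sqrt(vr * vc) else 0
  sa <- sum((0:(2 * G - 2)) * psum)
  ent0 <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  c(autocorrelation = autoc, contrast = contrast, correlation = corr,
    dissimilarity = dissim, energy = energy, entropy = ent,
    homogeneity = homog, maximum_probability = max(pr), mean = mr,
    variance = vr, sum_average = sa,
    sum_variance = sum(((0:(2 * G - 2)) - sa)^2 * psum),
    sum_entropy = ent0(psum), difference_entropy = ent0(pdiff))
}

## Per-pixel morphology oracles (zero padding, reflected SE for dilation).
seOffsetsOracle <- function(se) {
  orow <- (nrow(se) + 1) %/% 2; ocol <- (ncol(se) + 1) %/% 2
  idx <- which(se != 0, arr.ind = TRUE)
  cbind(idx[, 1] - orow, idx[, 2] - ocol)
}

dilateOracle <- function(m, se = matrix(1, 3, 3)) {
  offs <- seOffsetsOracle(se)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      r2 <- r - offs[k, 1]; c2 <- c - offs[k, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2] == 1) {
        out[r, c] <- 1L
        break
      }
    }
  }
  out
}

erodeOracle <- function(m, se = matrix(1, 3, 3)) {
  offs <- seOffsetsOracle(se)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(1L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || m[r2, c2] != 1) {
        out[r, c] <- 0L
        break
      }
    }
  }
  out
}

## Flood fill from the border over background (4-connectivity); enclosed
## background becomes foreground.
fillOracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  reach <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r == 1 || r == nr || c == 1 || c == nc) && m[r, c] == 0) {
      queue[[length(queue) + 1]] <- c(r, c)
      reach[r, c] <- TRUE
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- p[1] + dd[1]; c2 <- p[2] + dd[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !reach[r2, c2] && m[r2, c2] == 0) {
        reach[r2, c2] <- TRUE
        queue[[length(queue) + 1]] <- c(r2, c2)
      }
    }
  }
  out <- m
  out[!reach & m == 0] <- 1L
  out
}

## Exhaustive between-class variance scan (independent Otsu oracle).
otsuOracle <- function(pix, G) {
  h <- tabulate(as.vector(pix) + 1L, nbins = G)
  n <- sum(h); lv <- 0:(G - 1)
  best <- -Inf; bt <- NA
  for (t in 0:(G - 2)) {
    w0 <- sum(h[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lv[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):G] * lv[(t + 2):G]) / w1
    b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (b > best + 1e-12) { best <- b; bt <- t }
  }
  bt
}

## Central finite-difference gradient of the ANFIS loss with respect to
## every trainable parameter, via direct slot perturbation.
numericAnfisGradient <- function(model, x, target, h = 1e-6) {
  lossAt <- function(m) {
    s <- predictScores(x, m)
    sum((s - target)^2)
  }
  gc <- lapply(model@centers, function(v) numeric(length(v)))
  gs <- lapply(model@widths, function(v) numeric(length(v)))
  for (f in seq_along(model@centers)) {
    for (j in seq_along(model@centers[[f]])) {
      mp <- model; mp@centers[[f]][j] <- mp@centers[[f]][j] + h
      mm <- model; mm@centers[[f]][j] <- mm@centers[[f]][j] - h
      gc[[f]][j] <- (lossAt(mp) - lossAt(mm)) / (2 * h)
      mp <- model; mp@widths[[f]][j] <- mp@widths[[f]][j] + h
      mm <- model; mm@widths[[f]][j] <- mm@widths[[f]][j] - h
      gs[[f]][j] <- (lossAt(mp) - lossAt(mm)) / (2 * h)
    }
  }
  gq <- matrix(0, nrow(model@consequents), ncol(model@consequents))
  for (r in seq_len(nrow(gq))) for (cc in seq_len(ncol(gq))) {
    mp <- model; mp@consequents[r, cc] <- mp@consequents[r, cc] + h
    mm <- model; mm@consequents[r, cc] <- mm@consequents[r, cc] - h
    gq[r, cc] <- (lossAt(mp) - lossAt(mm)) / (2 * h)
  }
  list(centers = gc, widths = gs, consequents = gq)
}

## Random binary mask and random grey image generators for property tests.
randomMask <- function(nr = 8, nc = 8, p = 0.5) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

randomGrey <- function(nr, nc, G) {
  greyImage(matrix(sample.int(G, nr * nc, replace = TRUE) - 1L, nr, nc),
            levels = G)
}

## A tiny two-feature, two-rule model used by several gradient tests.
tinyModel <- function() {
  anfisModel(
    featureNames = c("f1", "f2"),
    centers = list(c(-1, 1), c(-0.5, 0.8)),
    widths = list(c(0.8, 1.2), c(1.0, 0.6)),
    rules = rbind(c(1L, 1L), c(2L, 2L)),
    consequents = rbind(c(0.9, 0.1, 0.2), c(0.1, 0.8, 0.3)),
    learningRate = 0.01, momentum = 0.0, seed = 7L
  )
}
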