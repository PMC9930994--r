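#' @include imaging.R
NULL

#' Fixture convolutional backbone
#'
#' A small convolutional stack (7x7/stride-4 conv, ReLU, 2x2 max-pool,
#' 3x3/stride-2 conv, ReLU, 6x6 average pooling) whose weights are drawn
#' once from a seed-fixed He-scaled normal distribution and never trained.
#' Used as a deterministic random-projection feature extractor, so the
#' pipeline builds and tests without downloading pretrained weights.
#' Pretrained backbones can be plugged in through the same
#' \linkS4class{BackboneSpec} interface.
#'
#' @param seed weight seed; default 101.
#' @param inputSize square input edge in pixels; default 224.
#' @return a \linkS4class{BackboneSpec}.
#' @export
fixtureBackbone <- function(seed = 101, inputSize = 224L) {
  inputSize <- as.integer(inputSize)
  w <- withSeed(seed, list(
    W1 = matrix(rnorm(7 * 7 * 3 * 8, sd = sqrt(2 / (7 * 7 * 3))),
                7 * 7 * 3, 8),
    W2 = matrix(rnorm(3 * 3 * 8 * 16, sd = sqrt(2 / (3 * 3 * 8))),
                3 * 3 * 8, 16)))
  new("BackboneSpec", name = "fixture", inputSize = inputSize,
      featureDim = 6L * 6L * 16L, source = "fixture", weights = w)
}

# im2col: extract k x k x C patches at the given stride into a matrix with
# one row per output position (row-major over output rows then columns)
im2col <- function(img, k, stride) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  oh <- (H - k) %/% stride + 1L
  ow <- (W - k) %/% stride + 1L
  ys <- (seq_len(oh) - 1L) * stride
  xs <- (seq_len(ow) - 1L) * stride
  out <- matrix(0, oh * ow, k * k * C)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    out[, j] <- as.numeric(img[ys + dy, xs + dx, c])
  }
  attr(out, "oh") <- oh; attr(out, "ow") <- ow
  out
}

maxPool2 <- function(a) {
  H <- dim(a)[1]; W <- dim(a)[2]
  oh <- H %/% 2L; ow <- W %/% 2L
  i1 <- seq_len(oh) * 2L - 1L; j1 <- seq_len(ow) * 2L - 1L
  pmax(a[i1, j1, , drop = FALSE], a[i1 + 1L, j1, , drop = FALSE],
       a[i1, j1 + 1L, , drop = FALSE], a[i1 + 1L, j1 + 1L, , drop = FALSE])
}

avgPoolGrid <- function(a, g) {
  H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
  ri <- ceiling(seq_len(H) / (H / g)); ci <- ceiling(seq_len(W) / (W / g))
  out <- array(0, c(g, g, C))
  for (c in seq_len(C))
    out[, , c] <- tapply(a[, , c], list(ri[row(a[, , c])], ci[col(a[, , c])]),
                         mean)
  out
}

#' Extract backbone features from a tiled image
#'
#' @param image a \linkS4class{TiledImage} matching the backbone input
#'   size.
#' @param backbone a \linkS4class{BackboneSpec}.
#' @return numeric feature vector of length \code{featureDim}.
#' @export
extractFeatures <- function(image, backbone) {
  px <- image@pixels
  stopIfNot(all(dim(px)[1:2] == backbone@inputSize),
            "image size does not match the backbone input size")
  a <- conv2d(px, backbone@weights$W1, k = 7L, stride = 4L)
  a[a < 0] <- 0
  a <- maxPool2(a)
  a <- conv2d(a, backbone@weights$W2, k = 3L, stride = 2L)
  a[a < 0] <- 0
  as.numeric(avgPoolGrid(a, 6L))
}

conv2d <- function(img, Wmat, k, stride) {
  X <- im2col(img, k, stride)
  Y <- X %*% Wmat
  array(Y, c(attr(X, "oh"), attr(X, "ow"), ncol(Wmat)))
}

#' Train a linear SVM on z-scored features
#'
#' Linear kernel, C = 1; the z-scoring parameters are fit on the training
#' data only and reapplied at prediction.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels factor or character with exactly two classes present.
#' @return an object of class \code{vhitSvm} with a \code{predict} method.
#' @export
trainSvm <- function(features, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("single-class input: both classes must be present", call. = FALSE)
  center <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(features, 2, center), 2, scl, "/")
  model <- e1071::svm(z, factor(labels), kernel = "linear", cost = 1,
                      scale = FALSE)
  structure(list(model = model, center = center, scale = scl),
            class = "vhitSvm")
}

#' @rdname trainSvm
#' @param object a \code{vhitSvm}.
#' @param newdata numeric feature matrix.
#' @param ... ignored.
#' @export
predict.vhitSvm <- function(object, newdata, ...) {
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.character(predict(object$model, z))
}

#' Construct cross-validation settings
#'
#' @param k folds; default 5.
#' @param repeats repetitions; default 10.
#' @param seed seed; default 1.
#' @param placement "within-folds" (default: augmentation applied inside
#'   each training fold only, so held-out scoring uses only original
#'   samples) or "paper-mode" (augmentation before splitting).
#' @return a \linkS4class{CVConfig}.
#' @export
cvConfig <- function(k = 5, repeats = 10, seed = 1,
                     placement = c("within-folds", "paper-mode")) {
  new("CVConfig", k = as.integer(k), repeats = as.integer(repeats),
      stratified = TRUE, seed = seed, placement = match.arg(placement))
}

# stratified fold assignment: per class, shuffle then deal round-robin;
# fold sizes per class differ by at most one sample
stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("class '", cls, "' has fewer members than folds", call. = FALSE)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' For every repeat, samples are stratified by label and partitioned into k
#' folds; each fold in turn is held out, the remaining folds are (optionally
#' augmented and) featurized and used to fit the classifier, and the
#' held-out fold is scored. With \code{placement = "within-folds"}
#' augmentation sees training samples only and held-out scoring uses only
#' original-provenance samples; with \code{"paper-mode"} the whole set is
#' augmented once before any splitting (the replication order), so
#' synthetic samples can land in test folds.
#'
#' @param samples list of samples; each needs an \code{id}. Pre-extracted
#'   features may be supplied as \code{sample$features}.
#' @param labels character/factor label per sample.
#' @param pipeline list with \code{featurize} (sample -> numeric vector),
#'   optional \code{augment} (function(samples, labels, seed) returning
#'   list(samples, labels)), optional \code{classify}/\code{predictFn}
#'   (defaults: \code{\link{trainSvm}} / its predict method).
#' @param config a \linkS4class{CVConfig}.
#' @return a \linkS4class{CVResult}.
#' @export
repeatedStratifiedCV <- function(samples, labels, pipeline, config) {
  validObject(config)
  labels <- as.character(labels)
  stopIfNot(length(samples) == length(labels),
            "one label per sample required")
  featurize <- pipeline$featurize %||% function(s) s$features
  classify <- pipeline$classify %||% trainSvm
  predictFn <- pipeline$predictFn %||% function(fit, X) predict(fit, X)
  seeds <- childSeeds(config@seed, config@repeats + 1L)
  isOriginal <- rep(TRUE, length(samples))
  if (!is.null(pipeline$augment) && config@placement == "paper-mode") {
    aug <- pipeline$augment(samples, labels, seeds[config@repeats + 1L])
    isOriginal <- c(isOriginal, rep(FALSE, length(aug$samples) - length(samples)))
    samples <- aug$samples
    labels <- as.character(aug$labels)
  }
  featCache <- new.env(parent = emptyenv())
  cachedFeaturize <- function(s) {
    key <- s$id %||% NA_character_
    if (!is.na(key) && !is.null(featCache[[key]])) return(featCache[[key]])
    f <- featurize(s)
    if (!is.na(key)) featCache[[key]] <- f
    f
  }
  p <- length(cachedFeaturize(samples[[1]]))
  getFeatures <- function(ss) t(vapply(ss, cachedFeaturize, numeric(p)))
  acc <- matrix(NA_real_, config@repeats, config@k)
  conf <- NULL
  for (rep_i in seq_len(config@repeats)) {
    fold <- withSeed(seeds[rep_i], stratifiedFolds(labels, config@k))
    foldSeeds <- childSeeds(seeds[rep_i], config@k)
    for (f in seq_len(config@k)) {
      testIdx <- which(fold == f)
      trainIdx <- which(fold != f)
      trS <- samples[trainIdx]; trL <- labels[trainIdx]
      if (!is.null(pipeline$augment) && config@placement == "within-folds") {
        aug <- pipeline$augment(trS, trL, foldSeeds[f])
        trS <- aug$samples; trL <- as.character(aug$labels)
      }
      fit <- classify(getFeatures(trS), trL)
      pred <- predictFn(fit, getFeatures(samples[testIdx]))
      truth <- labels[testIdx]
      acc[rep_i, f] <- 100 * mean(pred == truth)
      tb <- table(truth = truth, prediction = pred)
      conf <- if (is.null(conf)) tb else addTables(conf, tb)
    }
  }
  new("CVResult", foldAccuracy = acc, meanAccuracy = mean(acc),
      sdAccuracy = sd(as.numeric(acc)), confusion = as.table(conf),
      config = config)
}

addTables <- function(a, b) {
  rows <- union(rownames(a), rownames(b))
  cols <- union(colnames(a), colnames(b))
  out <- matrix(0L, length(rows), length(cols),
                dimnames = list(truth = rows, prediction = cols))
  out[rownames(a), colnames(a)] <- out[rownames(a), colnames(a)] + a
  out[rownames(b), colnames(b)] <- out[rownames(b), colnames(b)] + b
  as.table(out)
}

#' Summarize cross-validation results as a comparison table
#'
#' @param results list of \linkS4class{CVResult}.
#' @param variant dataset variant per result (raw / OS / EDE / ITS).
#' @param style cropping style per result.
#' @param backbone backbone name per result.
#' @return data.frame with columns style, variant, backbone,
#'   mean_accuracy, sd_accuracy and a formatted \code{accuracy} column
#'   ("mean [STD]"), sorted by (style, variant, backbone).
#' @export
summarizeCV <- function(results, variant, style = "horizontal",
                        backbone = "fixture") {
  stopIfNot(length(results) > 0, "no results to summarize")
  n <- length(results)
  out <- data.frame(style = rep_len(style, n), variant = rep_len(variant, n),
                    backbone = rep_len(backbone, n),
                    mean_accuracy = vapply(results, meanAccuracy, numeric(1)),
                    sd_accuracy = vapply(results, sdAccuracy, numeric(1)),
                    stringsAsFactors = FALSE)
  out$accuracy <- sprintf("%.1f [%.1f]", out$mean_accuracy, out$sd_accuracy)
  out[order(out$style, out$variant, out$backbone), , drop = FALSE]
}

#' Tiled image of one classification sample
#'
#' Computes the MSWC map of each SCC trace of the sample and renders the
#' cropped, tiled patient image.
#'
#' @param sample a sample (list with \code{traces} per SCC).
#' @param style a \linkS4class{CropStyle} or preset name.
#' @param grid optional shared \linkS4class{WaveletGrid}.
#' @param outputSize final image edge; default 224.
#' @return a \linkS4class{TiledImage}.
#' @export
sampleTiledImage <- function(sample, style, grid = NULL, outputSize = 224L) {
  maps <- lapply(sample$traces, function(tr)
    mswc(tr@headVelocity, tr@eyeVelocity, tr@samplingRate, grid = grid))
  cropAndTile(maps, style, outputSize = outputSize,
              patientId = sample$id %||% "")
}
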