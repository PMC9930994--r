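test_that("fixture backbone is deterministic, sized and sensitive", {
  bb <- fixtureBackbone()
  expect_equal(bb@featureDim, 576L)
  bb2 <- fixtureBackbone()
  expect_identical(bb@weights, bb2@weights)
  maps <- list(horizontal = constantMap(0.3), anterior = constantMap(0.6),
               posterior = constantMap(0.8))
  img <- cropAndTile(maps, "horizontal")
  f1 <- extractFeatures(img, bb)
  expect_length(f1, 576)
  expect_identical(f1, extractFeatures(img, bb))
  # changing one tile changes the features
  maps2 <- maps; maps2$posterior <- constantMap(0.2)
  f2 <- extractFeatures(cropAndTile(maps2, "horizontal"), bb)
  expect_false(identical(f1, f2))
  small <- new("TiledImage", pixels = array(0, c(32, 32, 3)),
               style = cropStyle("horizontal"), patientId = "x",
               sccOrder = c("horizontal", "anterior", "posterior"))
  expect_error(extractFeatures(small, bb), "size")
})

test_that("linear SVM separates toys and matches the max-margin oracle", {
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  y <- c("A", "A", "B", "B")
  fit <- trainSvm(X, y)
  expect_equal(predict(fit, X), y)
  # analytic maximum-margin boundary for these 4 points is x1 = 1;
  # probe symmetric points on both sides
  probes <- rbind(c(0.6, 0.5), c(1.4, 0.5))
  expect_equal(predict(fit, probes), c("A", "B"))
  # decision values vanish on the boundary by symmetry
  z <- sweep(sweep(rbind(c(1, 0.5)), 2, fit$center), 2, fit$scale, "/")
  dv <- attr(predict(fit$model, z, decision.values = TRUE),
             "decision.values")
  expect_lt(abs(dv), 0.05)
  # duplicated contradictory points cannot both be fit
  Xc <- rbind(c(1, 1), c(1, 1)); yc <- c("A", "B")
  fitc <- trainSvm(rbind(Xc, c(0, 0), c(2, 2)), c(yc, "A", "B"))
  expect_lte(mean(predict(fitc, Xc) == yc), 0.5)
  expect_error(trainSvm(X, rep("A", 4)), "single-class")
})

test_that("stratified folds deviate by at most one sample per class", {
  labels <- c(rep("CR", 20), rep("PRNR", 44))
  for (k in c(3, 5)) {
    fold <- { set.seed(7); vhitwca:::stratifiedFolds(labels, k) }
    for (cls in unique(labels)) {
      per <- table(factor(fold[labels == cls], levels = seq_len(k)))
      expect_lte(max(per) - min(per), 1)
    }
  }
  expect_error(vhitwca:::stratifiedFolds(c("A", rep("B", 10)), 5), "fewer")
})

test_that("repeated CV is exact on separable features and reproducible", {
  set.seed(71)
  n <- 30
  feats <- rbind(matrix(rnorm(n * 4, mean = 0), n, 4),
                 matrix(rnorm(n * 4, mean = 4), n, 4))
  samples <- lapply(seq_len(2 * n), function(i)
    featureSample(paste0("s", i), feats[i, ], c("A", "B")[1 + (i > n)]))
  labels <- vapply(samples, `[[`, character(1), "label")
  res <- repeatedStratifiedCV(samples, labels, list(),
                              cvConfig(k = 5, repeats = 3, seed = 2))
  expect_equal(meanAccuracy(res), 100)
  expect_equal(dim(foldAccuracies(res)), c(3L, 5L))
  res2 <- repeatedStratifiedCV(samples, labels, list(),
                               cvConfig(k = 5, repeats = 3, seed = 2))
  expect_identical(foldAccuracies(res), foldAccuracies(res2))
  # mean and sd recomputed from the stored folds
  expect_equal(meanAccuracy(res), mean(foldAccuracies(res)))
  expect_equal(sdAccuracy(res), sd(as.numeric(foldAccuracies(res))))
  few <- c(1:3, 31:33)                       # both classes, but 3 < k
  expect_error(repeatedStratifiedCV(samples[few], labels[few], list(),
                                    cvConfig(k = 5, repeats = 1)),
               "fewer")
})

test_that("within-folds augmentation never reaches the held-out fold", {
  set.seed(72)
  feats <- matrix(rnorm(40 * 3), 40, 3)
  samples <- lapply(seq_len(40), function(i)
    featureSample(paste0("s", i), feats[i, ],
                  c("A", "B")[1 + (i %% 2)]))
  labels <- vapply(samples, `[[`, character(1), "label")
  seenTrainIds <- new.env(parent = emptyenv())
  recordingAugment <- function(ss, ll, seed) {
    ids <- vapply(ss, `[[`, character(1), "id")
    seenTrainIds[[as.character(length(ls(seenTrainIds)))]] <- ids
    extra <- lapply(seq_len(4), function(j) {
      s <- ss[[j]]; s$id <- paste0("aug", j, "_", seed); s
    })
    list(samples = c(ss, extra),
         labels = c(ll, vapply(extra, `[[`, character(1), "label")))
  }
  cfg <- cvConfig(k = 4, repeats = 2, seed = 5)
  res <- repeatedStratifiedCV(samples, labels,
                              list(augment = recordingAugment), cfg)
  expect_s4_class(res, "CVResult")
  # each augment call saw a strict subset of the originals (one fold out)
  for (key in ls(seenTrainIds)) {
    ids <- seenTrainIds[[key]]
    expect_lt(length(ids), 40)
    expect_true(all(ids %in% vapply(samples, `[[`, character(1), "id")))
  }
  expect_equal(length(ls(seenTrainIds)), 8)  # one call per fold per repeat
})

test_that("summary table is sorted and echoes fold statistics", {
  mk <- function(m) {
    fa <- matrix(c(m, m + 2, m - 2, m), 2, 2)
    new("CVResult", foldAccuracy = fa, meanAccuracy = mean(fa),
        sdAccuracy = sd(as.numeric(fa)),
        confusion = table(truth = c("A", "B"), prediction = c("A", "B")),
        config = cvConfig())
  }
  res <- list(mk(80), mk(90), mk(85), mk(88))
  tab <- summarizeCV(res, variant = c("raw", "OS", "EDE", "ITS"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$variant, sort(c("raw", "OS", "EDE", "ITS")))
  expect_equal(tab$accuracy[tab$variant == "raw"], "80.0 [1.6]")
})
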