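test_that("binary cross-entropy matches closed forms", {
    expect_equal(bceLoss(1, 0.5), log(2), tolerance = 1e-12)
    expect_equal(bceLoss(c(1, 0), c(0.9, 0.2)),
                 (-log(0.9) - log(0.8)) / 2, tolerance = 1e-12)
    expect_equal(bceLoss(c(1, 0), c(0.9, 0.2)), 0.164252, tolerance = 1e-6)
    ## clipped-perfect reconstruction is zero up to the clipping constant
    y <- c(0, 1, 1, 0, 1)
    expect_lt(bceLoss(y, y), 1e-6)
    expect_error(bceLoss(c(1, 0), 0.5), "different lengths")
    ## non-negativity on random pairs
    set.seed(1)
    for (i in 1:20)
        expect_gte(bceLoss(runif(8), runif(8)), 0)
})

test_that("min-max scaling maps features to [0, 1] and inverts", {
    s <- scaleFeatures(cbind(a = c(0, 5, 10), b = c(2, 2, 2)))
    expect_equal(s$scaled[, "a"], c(0, 0.5, 1))
    expect_equal(s$scaled[, "b"], c(0, 0, 0))
    expect_true(s$scaler$constant[["b"]])
    expect_false(s$scaler$constant[["a"]])

    set.seed(2)
    x <- matrix(rnorm(60, 100, 25), 10, 6)
    sc <- scaleFeatures(x)
    expect_true(all(sc$scaled >= 0 & sc$scaled <= 1))
    expect_equal(unscaleFeatures(sc$scaled, sc$scaler), x,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(applyScaler(x, sc$scaler), sc$scaled, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(scaleFeatures(matrix(0, 0, 3)), "empty")
    expect_error(scaleFeatures(matrix(1, 1, 3)), ">= 2 rows")
})

test_that("default architecture compresses 2048 to 16 (128x)", {
    sp <- autoencoderSpec()
    expect_identical(sp@dims, c(2048L, 1024L, 256L, 64L, 16L))
    expect_identical(bottleneckDim(sp), 16L)
    expect_equal(compressionFactor(sp), 128)
    expect_equal(sp@l1Weight, 1e-5)
    expect_error(autoencoderSpec(dims = c(64, 64, 16)), "decreasing")
})

test_that("a repeated vector is reconstructed to its entropy floor", {
    set.seed(21)
    v <- runif(32, 0.05, 0.95)
    x <- matrix(v, 500, 32, byrow = TRUE)
    floor <- -mean(v * log(v) + (1 - v) * log(1 - v))
    m <- trainAutoencoder(x, autoencoderSpec(dims = c(32, 16, 8), seed = 3,
                                             l1Weight = 0),
                          epochs = 200, batchSize = 128)
    final <- bceLoss(x, reconstructFeatures(m, x))
    expect_lt(abs(final - floor) / floor, 0.05)
})

test_that("training loss decreases and runs are reproducible", {
    tc <- twoClusterFeatures(n = 60, width = 24, seed = 5)
    sp <- autoencoderSpec(dims = c(24L, 12L, 6L), seed = 4, l1Weight = 1e-5)
    m1 <- trainAutoencoder(tc$x, sp, epochs = 80, batchSize = 16)
    m2 <- trainAutoencoder(tc$x, sp, epochs = 80, batchSize = 16)
    expect_equal(lossHistory(m1)$train, lossHistory(m2)$train,
                 tolerance = 1e-10)
    ## 10-epoch moving average of the training loss is non-increasing
    ma <- stats::filter(lossHistory(m1)$train, rep(0.1, 10), sides = 1)
    ma <- ma[!is.na(ma)]
    expect_true(all(diff(ma) <= 1e-4))
    expect_lt(tail(lossHistory(m1)$train, 1), lossHistory(m1)$train[1])
})

test_that("latent codes are deterministic and preserve cluster structure", {
    skip_if_not_installed("cluster")
    tc <- twoClusterFeatures(n = 50, width = 24, seed = 6)
    m <- trainAutoencoder(tc$x,
                          autoencoderSpec(dims = c(24L, 12L, 6L), seed = 2),
                          epochs = 120, batchSize = 16)
    codes <- latentCodes(m)
    expect_identical(dim(codes), c(50L, 6L))
    expect_identical(encodeFeatures(m, tc$x), codes)
    live <- codes[, apply(codes, 2, sd) > 0, drop = FALSE]
    sil <- cluster::silhouette(tc$labels + 1L, dist(live))
    expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("the l1 activity penalty shrinks the first-layer code", {
    tc <- twoClusterFeatures(n = 40, width = 24, seed = 7)
    h1norm <- vapply(c(0, 0.01, 0.1, 1), function(lam) {
        m <- trainAutoencoder(tc$x,
                              autoencoderSpec(dims = c(24L, 12L, 6L),
                                              seed = 5, l1Weight = lam),
                              epochs = 120, batchSize = 16)
        w <- m@weights
        h1 <- pmax(sweep(tc$x %*% w$W[[1]], 2, w$b[[1]], `+`), 0)
        mean(rowSums(abs(h1)))
    }, numeric(1))
    expect_true(all(diff(h1norm) <= 0.02 * h1norm[-length(h1norm)] + 1e-8))
    expect_lt(h1norm[4], h1norm[1])
})

test_that("contract violations fail fast", {
    tc <- twoClusterFeatures(n = 10, width = 24, seed = 8)
    sp <- autoencoderSpec(dims = c(32L, 8L), seed = 1)
    expect_error(trainAutoencoder(tc$x, sp), "does not match the spec")
    expect_error(trainAutoencoder(tc$x * 5,
                                  autoencoderSpec(dims = c(24L, 8L))),
                 "scaled to \\[0, 1\\]")
    m <- new("AutoencoderModel", spec = sp, weights = list(),
             trained = FALSE, lossHistory = data.frame(),
             codes = matrix(0, 0, 0))
    expect_error(encodeFeatures(m, tc$x), "not been trained")
})
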