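## Independent SVD oracle: eigen-decomposition of the small Gram matrix
## X'X, never touching svd() or the package's decomposition path.
gramSvdOracle <- function(X) {
    ev <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(ev$values, 0))
    U <- X %*% ev$vectors
    U <- sweep(U, 2, pmax(d, 1e-300), `/`)
    list(d = d, U = U)
}

absColErr <- function(A, B) {
    max(vapply(seq_len(ncol(A)), function(i)
        min(max(abs(A[, i] - B[, i])), max(abs(A[, i] + B[, i]))),
        numeric(1)))
}

basesMatrix <- function(bs) {
    vapply(bases(bs), function(b) as.vector(t(b)),
           numeric(length(bases(bs)[[1]])))
}

test_that("pct recovers a planted rank-1 structure exactly", {
    u <- c(1, -2, 3, 0.5, -1, 2)
    v <- c(1, -1, 2, -2); v <- v - mean(v)      # centred time profile
    hm <- toyHeatMatrix(u %*% t(v))
    bs <- pct(hm, k = 4)
    d <- singularValues(bs)
    expect_equal(d[1], sqrt(sum(u^2) * sum(v^2)), tolerance = 1e-10)
    expect_lt(max(d[-1]), 1e-10)
    b1 <- as.vector(t(bases(bs)[[1]]))
    expect_lt(min(max(abs(b1 - u / sqrt(sum(u^2)))),
                  max(abs(b1 + u / sqrt(sum(u^2))))), 1e-10)
    ## exact rank-1 reconstruction
    rec <- d[1] * b1 %*% t(bs@coefficients[, 1])
    expect_lt(max(abs(rec - heatValues(hm))), 1e-10)
})

test_that("pct matches the Gram-matrix SVD oracle on random matrices", {
    ## row-centering puts the all-ones time vector in the null space, so a
    ## centred 6x4 matrix has rank 3: the oracle comparison covers the three
    ## informative components and checks the last singular value is null.
    for (seed in 1:5) {
        set.seed(seed)
        hm <- toyHeatMatrix(matrix(rnorm(24), 6, 4))
        bs <- pct(hm, k = 4)
        oracle <- gramSvdOracle(heatValues(hm))
        expect_equal(singularValues(bs)[1:3], oracle$d[1:3],
                     tolerance = 1e-10)
        expect_lt(max(singularValues(bs)[4], oracle$d[4]), 1e-6)
        expect_lt(absColErr(basesMatrix(bs)[, 1:3], oracle$U[, 1:3]),
                  1e-10)
    }
})

test_that("pct spectrum carries the total variance and ranks truncations", {
    set.seed(7)
    hm <- toyHeatMatrix(matrix(rnorm(40), 10, 4))
    bs <- pct(hm, k = 4)
    X <- heatValues(hm)
    expect_equal(sum(singularValues(bs)^2), sum(X^2), tolerance = 1e-8)
    U <- basesMatrix(bs)
    errs <- vapply(1:4, function(k) {
        Uk <- U[, 1:k, drop = FALSE]
        rec <- Uk %*% diag(singularValues(bs)[1:k], k) %*%
            t(bs@coefficients[, 1:k, drop = FALSE])
        sqrt(sum((X - rec)^2))
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-9))
    expect_lt(errs[4], 1e-8)                   # zero at full rank
    expect_error(pct(hm, k = 5), "1 <= k <= n")
})

test_that("sign convention makes decompositions deterministic", {
    set.seed(2)
    hm <- toyHeatMatrix(matrix(rnorm(36), 9, 4))
    for (fn in list(function() pct(hm, 3),
                    function() sparsePct(hm, 3, lambda1 = 0.1))) {
        a <- fn(); b <- fn()
        expect_identical(bases(a), bases(b))
        m <- basesMatrix(a)
        expect_true(all(apply(m, 2, function(col)
            col[which.max(abs(col))] > 0)))
    }
})

test_that("sparse PCT with zero penalties equals PCT", {
    set.seed(4)
    hm <- toyHeatMatrix(matrix(rnorm(50), 10, 5))
    a <- pct(hm, k = 3)
    b <- sparsePct(hm, k = 3, lambda1 = 0, lambda2 = 0)
    expect_lt(absColErr(basesMatrix(a), basesMatrix(b)), 1e-8)
    expect_equal(singularValues(a)[1:3], singularValues(b)[1:3],
                 tolerance = 1e-8)
})

test_that("cardinality-capped component matches exhaustive enumeration", {
    set.seed(6)
    u <- c(0, 0, 3, 0, -2, 0)                  # planted 2-sparse direction
    X <- u %*% t(c(1, -1, 2, 0.5)) + matrix(rnorm(24, sd = 0.1), 6, 4)
    hm <- toyHeatMatrix(X)
    bs <- sparsePct(hm, k = 1, lambda1 = 0, card = 2)
    support <- which(basesMatrix(bs)[, 1] != 0)

    S <- tcrossprod(heatValues(hm))            # brute force over 2-subsets
    combs <- combn(6, 2)
    vals <- apply(combs, 2, function(s) max(eigen(S[s, s])$values))
    expect_identical(support, sort(combs[, which.max(vals)]))
})

test_that("planted sparse support survives noise at high SNR", {
    set.seed(10)
    p <- 30; support <- c(4L, 11L, 23L)
    u <- numeric(p); u[support] <- c(2, -1.5, 1)
    X <- u %*% t(rnorm(6)) + matrix(rnorm(p * 6, sd = 0.05), p, 6)
    bs <- sparsePct(toyHeatMatrix(X), k = 1, lambda1 = 0, card = 3)
    expect_identical(which(basesMatrix(bs)[, 1] != 0), support)
})

test_that("stronger l1 thresholds never densify the leading basis", {
    set.seed(12)
    hm <- toyHeatMatrix(matrix(rnorm(80), 20, 4))
    nnz <- vapply(c(0, 0.1, 0.3, 0.5, 0.7), function(l1)
        sum(basesMatrix(sparsePct(hm, k = 1, lambda1 = l1))[, 1] != 0),
        numeric(1))
    expect_true(all(diff(nnz) <= 0))
    expect_error(sparsePct(hm, k = 1, lambda1 = -1), ">= 0")
})

test_that("variance fraction counts components against the spectrum", {
    mk <- function(d) new("BasisSet",
        bases = list(matrix(1, 1, 1)), singularValues = d,
        coefficients = matrix(0, 1, 1), method = "pct",
        sparsity = 0, converged = TRUE)
    expect_identical(varianceFraction(mk(c(2, 1, 1)), 0.8), 2L)
    expect_identical(varianceFraction(mk(c(2, 1, 1)), 1.0), 3L)
    expect_identical(varianceFraction(mk(5), 0.4), 1L)
    expect_error(varianceFraction(mk(c(2, 1)), 0), "in \\(0, 1\\]")
    expect_error(varianceFraction(mk(numeric(0)), 0.8), "empty")
})

test_that("avatars are square three-channel images in [0, 1]", {
    sq <- randomSequence(tau = 5, rows = 14, cols = 10, seed = 9)
    bs <- pct(buildHeatMatrix(sq, c(0, 0, 14, 10)), k = 3)
    av <- makeAvatar(bs, side = 32)
    img <- avatarImage(av)
    expect_identical(dim(img), c(32L, 32L, 3L))
    expect_true(all(img >= 0 & img <= 1))

    ## constant basis maps to an all-zero channel
    bs2 <- bs
    bs2@bases[[2]] <- matrix(0.7, 14, 10)
    expect_equal(max(abs(avatarImage(makeAvatar(bs2, side = 32))[, , 2])), 0)

    ## channel order: injected constants come back in basis order
    bs3 <- bs
    for (i in 1:3) bs3@bases[[i]] <- matrix(c(0.2, 0.5, 0.8)[i], 14, 10)
    av3 <- makeAvatar(bs3, side = 16, normalize = FALSE)
    expect_equal(apply(avatarImage(av3), 3, mean), c(0.2, 0.5, 0.8),
                 tolerance = 1e-12)

    bs1 <- bs; bs1@bases <- bs1@bases[1:2]
    expect_error(makeAvatar(bs1), "at least 3 bases")
})
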