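#' @include AllClasses.R
NULL

## Deterministic sign convention: the largest-magnitude entry of each basis
## vector is made positive (removes the SVD sign ambiguity).
.fixSign <- function(u) {
    s <- sign(u[which.max(abs(u))])
    if (s == 0) 1 else s
}

.toBasisImages <- function(U, roiShape) {
    lapply(seq_len(ncol(U)), function(i)
        matrix(U[, i], roiShape[1L], roiShape[2L], byrow = TRUE))
}

#' Principal component thermography (PCT)
#'
#' Economy singular value decomposition of the zero-mean heat matrix
#' \code{X = U Gamma V'}; the first k left singular vectors, reshaped to the
#' ROI, are the spatial bases that capture the dominant spatiotemporal
#' variance of the acquisition.
#'
#' @param hm a \linkS4class{HeatMatrix}.
#' @param k number of components, \code{1 <= k <= n} (default 3, the number
#'   of avatar channels).
#' @return A \linkS4class{BasisSet} with the full singular spectrum and k
#'   bases under a deterministic sign convention.
#' @examples
#' ts <- ThermalSequence(array(rnorm(6 * 10 * 10, 30), c(6, 10, 10)))
#' bs <- pct(buildHeatMatrix(ts), k = 3)
#' singularValues(bs)[1:3]
#' @export
pct <- function(hm, k = 3L) {
    stopifnot(is(hm, "HeatMatrix"))
    n <- ncol(hm@X)
    if (k < 1L || k > n)
        stop("'k' must satisfy 1 <= k <= n = ", n)
    sv <- svd(hm@X, nu = k, nv = k)
    signs <- apply(sv$u, 2L, .fixSign)
    U <- sweep(sv$u, 2L, signs, `*`)
    V <- sweep(sv$v, 2L, signs, `*`)
    new("BasisSet",
        bases = .toBasisImages(U, hm@roi[3:4]),
        singularValues = sv$d,
        coefficients = V,
        method = "pct",
        sparsity = colMeans(U == 0),
        converged = rep(TRUE, k))
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## One sparse component of the implicit covariance Sigma = X X' by
## soft-threshold / truncated power iteration. lambda1 is a relative
## threshold (fraction of the largest |Sigma v| entry), card an optional
## hard cardinality cap.
.sparseComponent <- function(X, lambda1, lambda2, card, maxIter, tol) {
    ## deterministic init: leading left singular direction via the small
    ## n x n Gram matrix
    G <- crossprod(X)
    ev <- eigen(G, symmetric = TRUE)
    v <- X %*% ev$vectors[, 1L]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-300) {                      # X numerically zero
        v <- rep(0, nrow(X)); v[1L] <- 1
        return(list(v = v, iter = 0L, converged = TRUE, delta = 0))
    }
    v <- v / nv
    converged <- FALSE
    delta <- NA_real_
    for (it in seq_len(maxIter)) {
        w <- X %*% crossprod(X, v)          # Sigma v without forming Sigma
        w <- w / (1 + lambda2)              # ridge shrinkage
        if (lambda1 > 0)
            w <- .softThreshold(w, lambda1 * max(abs(w)))
        if (!is.null(card) && sum(w != 0) > card) {
            keep <- order(abs(w), decreasing = TRUE)[seq_len(card)]
            w[-keep] <- 0
        }
        nw <- sqrt(sum(w^2))
        if (nw < 1e-300) {                  # fully thresholded: keep previous
            converged <- TRUE; delta <- 0; break
        }
        w <- w / nw
        delta <- min(sqrt(sum((w - v)^2)), sqrt(sum((w + v)^2)))
        v <- w
        if (delta < tol) { converged <- TRUE; break }
    }
    list(v = as.vector(v), iter = it, converged = converged, delta = delta)
}

#' Sparse principal component thermography
#'
#' Sequential extraction of k sparse spatial components maximizing the
#' explained variance \code{v' X X' v} under elastic-net-style penalties: a
#' soft-threshold power iteration with l1 threshold \code{lambda1} (relative
#' to the largest step entry, so it is scale-free), ridge shrinkage
#' \code{lambda2}, an optional hard cardinality cap, and projection
#' deflation between components. With both penalties zero this reduces
#' exactly to the power-iteration solution of \code{\link{pct}}.
#'
#' @param hm a \linkS4class{HeatMatrix}.
#' @param k number of components (default 3).
#' @param lambda1 relative l1 soft-threshold in [0, 1) (default 0.05).
#' @param lambda2 ridge (l2) weight >= 0 (default 0).
#' @param card optional integer cap on non-zero entries per basis.
#' @param maxIter,tol iteration cap and convergence tolerance on the
#'   change of direction between successive iterates (sign-invariant).
#' @return A \linkS4class{BasisSet}; non-convergence of a component raises a
#'   warning with the final tolerance but still returns the result.
#' @examples
#' ts <- ThermalSequence(array(rnorm(6 * 10 * 10, 30), c(6, 10, 10)))
#' bs <- sparsePct(buildHeatMatrix(ts), k = 3, lambda1 = 0.2)
#' basisSparsity(bs)
#' @export
sparsePct <- function(hm, k = 3L, lambda1 = 0.05, lambda2 = 0,
                      card = NULL, maxIter = 1000L, tol = 1e-6) {
    stopifnot(is(hm, "HeatMatrix"))
    if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0")
    n <- ncol(hm@X)
    if (k < 1L || k > n) stop("'k' must satisfy 1 <= k <= n = ", n)
    if (!is.null(card)) card <- max(1L, as.integer(card))
    X <- hm@X
    p <- nrow(X)
    U <- matrix(0, p, k)
    d <- numeric(k)
    conv <- logical(k)
    for (i in seq_len(k)) {
        comp <- .sparseComponent(X, lambda1, lambda2, card, maxIter, tol)
        if (!comp$converged)
            warning(sprintf(
                "sparse component %d did not converge in %d iterations (final change %.3g > tol %.3g)",
                i, maxIter, comp$delta, tol))
        v <- comp$v * .fixSign(comp$v)
        U[, i] <- v
        d[i] <- sqrt(sum((crossprod(X, v))^2))   # ||X'v||_2
        conv[i] <- comp$converged
        X <- X - v %*% crossprod(v, X)           # projection deflation
    }
    ## order components by explained variance (deflation usually already
    ## yields this; thresholding can perturb it slightly)
    ord <- order(d, decreasing = TRUE)
    U <- U[, ord, drop = FALSE]; d <- d[ord]; conv <- conv[ord]
    coeff <- crossprod(hm@X, U)
    coeff <- sweep(coeff, 2L, pmax(d, 1e-300), `/`)
    new("BasisSet",
        bases = .toBasisImages(U, hm@roi[3:4]),
        singularValues = d,
        coefficients = coeff,
        method = "sparse_pct",
        sparsity = colMeans(U == 0),
        converged = conv)
}

#' Components needed to reach a variance fraction
#'
#' Smallest m such that the cumulative squared singular values cover at
#' least \code{threshold} of the total variance. Reported as a diagnostic;
#' the avatar always uses the first three bases because the backbone input
#' has three channels.
#'
#' @param bs a \linkS4class{BasisSet}.
#' @param threshold fraction in (0, 1] (default 0.8).
#' @return Integer count m.
#' @examples
#' # squared spectrum 4, 1, 1: two components reach 5/6 >= 0.8
#' @export
varianceFraction <- function(bs, threshold = 0.8) {
    stopifnot(is(bs, "BasisSet"))
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must be in (0, 1]")
    d2 <- singularValues(bs)^2
    if (!length(d2) || sum(d2) == 0)
        stop("empty or all-zero singular spectrum")
    which(cumsum(d2) / sum(d2) >= threshold - 1e-12)[1L]
}

.minMax01 <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi - lo < 1e-300) matrix(0, nrow(m), ncol(m))
    else (m - lo) / (hi - lo)
}

.centerCropSquare <- function(m) {
    side <- min(dim(m))
    r0 <- floor((nrow(m) - side) / 2)
    c0 <- floor((ncol(m) - side) / 2)
    m[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
}

#' Assemble the three-channel avatar image
#'
#' Each of the first three bases is min-max normalized to [0, 1] (a constant
#' basis maps to all zeros), centre-cropped to a square and resized to
#' \code{side x side} by bilinear interpolation; the three results are
#' stacked as channels in basis order.
#'
#' @param bs a \linkS4class{BasisSet} with at least 3 bases.
#' @param side output side in pixels (default 224, the backbone input side).
#' @param normalize min-max normalize each channel (default TRUE; FALSE
#'   passes raw basis values through, assuming they already lie in [0, 1]).
#' @return An \linkS4class{Avatar}.
#' @export
makeAvatar <- function(bs, side = 224L, normalize = TRUE) {
    stopifnot(is(bs, "BasisSet"))
    if (length(bases(bs)) < 3L)
        stop("avatar assembly needs at least 3 bases, got ",
             length(bases(bs)))
    side <- as.integer(side)
    img <- array(0, c(side, side, 3L))
    for (ch in 1:3) {
        b <- bases(bs)[[ch]]
        if (normalize) b <- .minMax01(b)
        b <- .centerCropSquare(b)
        if (nrow(b) != side)
            b <- EBImage::resize(b, w = side, h = side, filter = "bilinear")
        img[, , ch] <- pmin(pmax(b, 0), 1)
    }
    new("Avatar", image = img, side = side,
        channelOrder = c("beta1", "beta2", "beta3"))
}
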