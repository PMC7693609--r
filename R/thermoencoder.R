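#' @include AllClasses.R
NULL

#' Mean binary cross-entropy
#'
#' \code{-mean(y * log(p) + (1 - y) * log(1 - p))} with predictions clipped
#' to \code{[eps, 1 - eps]}. This is the autoencoder reconstruction loss
#' between min-max scaled features and sigmoid outputs.
#'
#' @param y target values in [0, 1].
#' @param p predicted probabilities.
#' @param eps clipping constant (default 1e-7).
#' @return Scalar loss (>= 0; 0 only under clipped-perfect reconstruction).
#' @examples
#' bceLoss(1, 0.5)            # log(2)
#' bceLoss(c(1, 0), c(0.9, 0.2))
#' @export
bceLoss <- function(y, p, eps = 1e-7) {
    if (length(y) != length(p))
        stop("'y' and 'p' have different lengths (", length(y), " vs ",
             length(p), ")")
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Min-max scale a feature table to [0, 1]
#'
#' Per-feature (column) scaling \code{(x - min) / (max - min)}; constant
#' columns map to zero and are flagged in the scaler. Required because the
#' autoencoder's sigmoid/cross-entropy output contract needs targets in
#' [0, 1].
#'
#' @param x numeric matrix, subjects x features (>= 2 rows).
#' @return List with \code{scaled} (matrix in [0, 1]) and \code{scaler}
#'   (list: min, max, constant), invertible on non-constant features via
#'   \code{\link{unscaleFeatures}}.
#' @export
scaleFeatures <- function(x) {
    x <- as.matrix(x)
    if (!nrow(x)) stop("empty feature table")
    if (nrow(x) < 2L)
        stop("need >= 2 rows for a non-degenerate min/max")
    mins <- apply(x, 2L, min)
    maxs <- apply(x, 2L, max)
    rng <- maxs - mins
    constant <- rng <= 0
    rng[constant] <- 1
    scaled <- sweep(sweep(x, 2L, mins, `-`), 2L, rng, `/`)
    scaled[, constant] <- 0
    list(scaled = scaled,
         scaler = list(min = mins, max = maxs, constant = constant))
}

#' Apply / invert a feature scaler
#'
#' @param x matrix to scale with a previously fitted scaler.
#' @param scaler the scaler from \code{\link{scaleFeatures}}.
#' @return The scaled (clipped to [0, 1]) or unscaled matrix; constant
#'   features are not invertible and are restored to their training value.
#' @export
applyScaler <- function(x, scaler) {
    rng <- scaler$max - scaler$min
    rng[scaler$constant] <- 1
    out <- sweep(sweep(as.matrix(x), 2L, scaler$min, `-`), 2L, rng, `/`)
    out[, scaler$constant] <- 0
    pmin(pmax(out, 0), 1)
}

#' @rdname applyScaler
#' @export
unscaleFeatures <- function(x, scaler) {
    rng <- scaler$max - scaler$min
    rng[scaler$constant] <- 1
    out <- sweep(sweep(as.matrix(x), 2L, rng, `*`), 2L, scaler$min, `+`)
    out[, scaler$constant] <- rep(scaler$min[scaler$constant],
                                  each = nrow(out))
    out
}

.relu <- function(z) pmax(z, 0)
.sigmoid <- function(z) 1 / (1 + exp(-z))

.aeForward <- function(weights, x) {
    nl <- length(weights$W)
    H <- vector("list", nl + 1L)
    Z <- vector("list", nl)
    H[[1L]] <- x
    for (i in seq_len(nl)) {
        Z[[i]] <- sweep(H[[i]] %*% weights$W[[i]], 2L, weights$b[[i]], `+`)
        H[[i + 1L]] <- if (i == nl) .sigmoid(Z[[i]]) else .relu(Z[[i]])
    }
    list(H = H, Z = Z)
}

.aeInit <- function(dims, seed, tied) {
    set.seed(seed)
    full <- c(dims, rev(dims)[-1L])
    nl <- length(full) - 1L
    W <- vector("list", nl); b <- vector("list", nl)
    for (i in seq_len(nl)) {
        W[[i]] <- matrix(stats::rnorm(full[i] * full[i + 1L],
                                      sd = sqrt(2 / full[i])),
                         full[i], full[i + 1L])
        b[[i]] <- numeric(full[i + 1L])
    }
    if (tied) {
        ne <- length(dims) - 1L
        for (i in seq_len(ne)) W[[ne + i]] <- t(W[[ne - i + 1L]])
    }
    list(W = W, b = b, dims = full, nEncoder = length(dims) - 1L,
         tied = tied)
}

#' Train the sparse deep autoencoder
#'
#' Minimizes the binary cross-entropy reconstruction loss plus an l1
#' activity penalty on the first encoder layer's code (the sparse-code
#' constraint applied to the initial layer) by the Adam optimizer with
#' mini-batches. Hidden layers are rectified, the output layer is a
#' sigmoid; weights are initialized under the spec seed, so training is
#' reproducible run-to-run.
#'
#' @param x scaled feature matrix (values in [0, 1]; width must equal
#'   \code{dims[1]} of the spec).
#' @param spec an \linkS4class{AutoencoderSpec} (default: 2048-1024-256-64-16
#'   mirrored, l1 weight 1e-5).
#' @param epochs training epochs (default 500).
#' @param batchSize mini-batch size (default 128).
#' @param learningRate Adam step size (default 1e-3).
#' @param validationFraction fraction of rows held out for a validation
#'   loss curve (default 0).
#' @param verbose print the loss every 50 epochs.
#' @return A trained \linkS4class{AutoencoderModel}; its \code{codes} slot
#'   holds the bottleneck codes of \code{x} and \code{lossHistory} the
#'   per-epoch loss curve.
#' @export
trainAutoencoder <- function(x, spec = autoencoderSpec(), epochs = 500L,
                             batchSize = 128L, learningRate = 1e-3,
                             validationFraction = 0, verbose = FALSE) {
    stopifnot(is(spec, "AutoencoderSpec"), epochs >= 1L, batchSize >= 1L)
    x <- as.matrix(x)
    if (ncol(x) != spec@dims[1L])
        stop("feature width ", ncol(x), " does not match the spec input ",
             "width ", spec@dims[1L])
    if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
        stop("features must be scaled to [0, 1]; see scaleFeatures()")
    w <- .aeInit(spec@dims, spec@seed, spec@tiedWeights)
    nl <- length(w$W)
    n <- nrow(x)
    x0 <- x                       # codes are returned in input row order
    xval <- NULL
    if (validationFraction > 0 && n >= 4L) {
        nv <- max(1L, floor(validationFraction * n))
        vi <- sample.int(n, nv)
        xval <- x[vi, , drop = FALSE]
        x <- x[-vi, , drop = FALSE]
        n <- nrow(x)
    }
    ## Adam state
    mW <- lapply(w$W, function(m) m * 0); vW <- mW
    mb <- lapply(w$b, function(v) v * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
    step <- 0L
    lam <- spec@l1Weight
    hist <- data.frame(epoch = integer(), train = numeric(),
                       validation = numeric())
    for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        epLoss <- 0; nb <- 0L
        for (start in seq.int(1L, n, by = batchSize)) {
            idx <- ord[start:min(start + batchSize - 1L, n)]
            xb <- x[idx, , drop = FALSE]
            m <- nrow(xb)
            fw <- .aeForward(w, xb)
            P <- fw$H[[nl + 1L]]
            Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
            h1 <- fw$H[[2L]]
            loss <- -mean(xb * log(Pc) + (1 - xb) * log(1 - Pc)) +
                lam * sum(abs(h1)) / m
            if (!is.finite(loss))
                stop("training diverged (non-finite loss); ",
                     "try a lower learning rate")
            epLoss <- epLoss + loss; nb <- nb + 1L
            ## backprop: sigmoid + BCE head
            dZ <- (P - xb) / (m * ncol(xb))
            gW <- vector("list", nl); gb <- vector("list", nl)
            for (i in rev(seq_len(nl))) {
                gW[[i]] <- crossprod(fw$H[[i]], dZ)
                gb[[i]] <- colSums(dZ)
                if (i > 1L) {
                    dH <- tcrossprod(dZ, w$W[[i]])
                    if (i == 2L && lam > 0)      # l1 on the first code
                        dH <- dH + lam * sign(fw$H[[2L]]) / m
                    dZ <- dH * (fw$Z[[i - 1L]] > 0)
                }
            }
            if (w$tied) {
                ne <- w$nEncoder
                for (i in seq_len(ne)) {
                    gW[[ne - i + 1L]] <- gW[[ne - i + 1L]] +
                        t(gW[[ne + i]])
                    gW[ne + i] <- list(NULL)
                }
            }
            step <- step + 1L
            corr <- sqrt(1 - b2^step) / (1 - b1^step)
            for (i in seq_len(nl)) {
                if (!is.null(gW[[i]])) {
                    mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW[[i]]
                    vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW[[i]]^2
                    w$W[[i]] <- w$W[[i]] - learningRate * corr * mW[[i]] /
                        (sqrt(vW[[i]]) + aeps)
                }
                mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb[[i]]
                vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb[[i]]^2
                w$b[[i]] <- w$b[[i]] - learningRate * corr * mb[[i]] /
                    (sqrt(vb[[i]]) + aeps)
            }
            if (w$tied) {
                ne <- w$nEncoder
                for (i in seq_len(ne)) w$W[[ne + i]] <- t(w$W[[ne - i + 1L]])
            }
        }
        val <- NA_real_
        if (!is.null(xval)) {
            fv <- .aeForward(w, xval)
            val <- bceLoss(xval, fv$H[[nl + 1L]])
        }
        hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / nb,
                                       validation = val))
        if (verbose && ep %% 50L == 0L)
            message(sprintf("epoch %d: loss %.5f", ep, epLoss / nb))
    }
    model <- new("AutoencoderModel", spec = spec, weights = w,
                 trained = TRUE, lossHistory = hist,
                 codes = matrix(0, 0L, bottleneckDim(spec)))
    model@codes <- encodeFeatures(model, x0)
    model
}

#' Encode features to the latent space
#'
#' Deterministic forward pass through the trained encoder; returns the
#' bottleneck codes (16-dimensional latent thermomics for the default spec).
#'
#' @param model a trained \linkS4class{AutoencoderModel}.
#' @param x scaled feature matrix (width = spec input width).
#' @return Matrix n x bottleneck.
#' @export
encodeFeatures <- function(model, x) {
    stopifnot(is(model, "AutoencoderModel"))
    if (!model@trained) stop("the autoencoder has not been trained")
    x <- as.matrix(x)
    w <- model@weights
    if (ncol(x) != w$dims[1L])
        stop("feature width ", ncol(x), " does not match the model input ",
             w$dims[1L])
    for (i in seq_len(w$nEncoder))
        x <- .relu(sweep(x %*% w$W[[i]], 2L, w$b[[i]], `+`))
    x
}

#' Reconstruct features through the full autoencoder
#'
#' @param model a trained \linkS4class{AutoencoderModel}.
#' @param x scaled feature matrix.
#' @return Matrix of sigmoid reconstructions in (0, 1).
#' @export
reconstructFeatures <- function(model, x) {
    stopifnot(is(model, "AutoencoderModel"))
    if (!model@trained) stop("the autoencoder has not been trained")
    x <- as.matrix(x)
    w <- model@weights
    fw <- .aeForward(w, x)
    fw$H[[length(w$W) + 1L]]
}
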