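#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## ResNet-50 plan: one ordered op list drives both the flat layer table
## (parameter counting) and the forward pass, so the two cannot drift apart.
## Convention (the one reproducing the published Keras totals): convolutions
## carry biases, batch-norm scale/offset are trainable, batch-norm moving
## mean/variance are non-trainable. Downsampling bottlenecks stride in their
## first 1x1 convolution.
## ---------------------------------------------------------------------------

.convOp <- function(name, k, ins, outs, stride = 1L, pad = 0L)
    list(kind = "conv", name = name, k = k, ins = ins, outs = outs,
         stride = stride, pad = pad)
.bnOp <- function(name, ch) list(kind = "batchnorm", name = name, ch = ch)
.reluOp <- function() list(kind = "relu")

.resnet50Plan <- function() {
    ops <- list(
        .convOp("conv1", 7L, 3L, 64L, stride = 2L, pad = 3L),
        .bnOp("conv1_bn", 64L), .reluOp(),
        list(kind = "maxpool", k = 3L, stride = 2L, pad = 1L))
    stages <- list(
        list(tag = "conv2", nBlocks = 3L, f = c(64L, 64L, 256L),
             stride = 1L),
        list(tag = "conv3", nBlocks = 4L, f = c(128L, 128L, 512L),
             stride = 2L),
        list(tag = "conv4", nBlocks = 6L, f = c(256L, 256L, 1024L),
             stride = 2L),
        list(tag = "conv5", nBlocks = 3L, f = c(512L, 512L, 2048L),
             stride = 2L))
    ins <- 64L
    for (st in stages) {
        f <- st$f
        for (b in seq_len(st$nBlocks)) {
            nm <- sprintf("%s_block%d", st$tag, b)
            s <- if (b == 1L) st$stride else 1L
            ops <- c(ops, list(list(kind = "save")))
            if (b == 1L)
                ops <- c(ops, list(
                    list(kind = "shortcut",
                         conv = .convOp(paste0(nm, "_0_conv"), 1L, ins,
                                        f[3L], stride = s),
                         bn = .bnOp(paste0(nm, "_0_bn"), f[3L]))))
            ops <- c(ops, list(
                .convOp(paste0(nm, "_1_conv"), 1L, ins, f[1L], stride = s),
                .bnOp(paste0(nm, "_1_bn"), f[1L]), .reluOp(),
                .convOp(paste0(nm, "_2_conv"), 3L, f[1L], f[2L], pad = 1L),
                .bnOp(paste0(nm, "_2_bn"), f[2L]), .reluOp(),
                .convOp(paste0(nm, "_3_conv"), 1L, f[2L], f[3L]),
                .bnOp(paste0(nm, "_3_bn"), f[3L]),
                list(kind = "add"), .reluOp()))
            ins <- f[3L]
        }
    }
    c(ops, list(list(kind = "global_avg_pool")))
}

.planToTable <- function(ops, head = TRUE) {
    rows <- list()
    add <- function(name, kind, kernel, ins, outs, stride, bias)
        rows[[length(rows) + 1L]] <<- data.frame(
            name = name, kind = kind, kernel = kernel, inChannels = ins,
            outChannels = outs, stride = stride, bias = bias,
            stringsAsFactors = FALSE)
    for (op in ops) {
        if (op$kind == "shortcut") {
            add(op$conv$name, "conv", op$conv$k, op$conv$ins, op$conv$outs,
                op$conv$stride, TRUE)
            add(op$bn$name, "batchnorm", 0L, op$bn$ch, op$bn$ch, 1L, FALSE)
        } else if (op$kind == "conv")
            add(op$name, "conv", op$k, op$ins, op$outs, op$stride, TRUE)
        else if (op$kind == "batchnorm")
            add(op$name, "batchnorm", 0L, op$ch, op$ch, 1L, FALSE)
        else if (op$kind == "relu")
            add("relu", "relu", 0L, 0L, 0L, 1L, FALSE)
        else if (op$kind == "maxpool")
            add("pool1", "maxpool", op$k, 0L, 0L, op$stride, FALSE)
        else if (op$kind == "add")
            add("add", "identity_add", 0L, 0L, 0L, 1L, FALSE)
        else if (op$kind == "global_avg_pool")
            add("avg_pool", "global_avg_pool", 0L, 0L, 0L, 1L, FALSE)
    }
    if (head)
        add("predictions", "dense", 0L, 2048L, 1000L, 1L, TRUE)
    do.call(rbind, rows)
}

#' Canonical ResNet-50 backbone specification
#'
#' The published 50-layer residual ImageNet configuration as a declarative
#' layer table: a 7x7/2 stem, four bottleneck stages of 3, 4, 6 and 3 blocks
#' with channel widths growing 64 to 2048, global average pooling, and (for
#' parameter accounting) the 1000-class dense head. Convolutions carry
#' biases and every convolution is followed by batch normalization; this is
#' the convention under which the table reproduces the published totals of
#' 25,583,592 trainable and 53,120 non-trainable parameters. Feature
#' extraction taps the 2048-wide global-average-pool output and never uses
#' the head.
#'
#' @return A \linkS4class{BackboneSpec} with \code{inputSide} 224 and
#'   \code{featureDim} 2048.
#' @examples
#' spec <- canonicalResNet50Spec()
#' countParameters(spec)
#' @export
canonicalResNet50Spec <- function() {
    new("BackboneSpec", layers = .planToTable(.resnet50Plan()),
        inputSide = 224L, featureDim = 2048L)
}

#' Dense-stack specification
#'
#' A \linkS4class{BackboneSpec}-style layer table for a plain stack of dense
#' layers (e.g. the autoencoder's 2048-1024-256-64-16-64-256-1024-2048
#' schedule), usable with \code{\link{countParameters}}.
#'
#' @param dims layer widths including input; one dense layer per adjacent
#'   pair.
#' @param bias include bias vectors (default TRUE).
#' @return A \linkS4class{BackboneSpec}.
#' @examples
#' d <- c(2048, 1024, 256, 64, 16, 64, 256, 1024, 2048)
#' countParameters(denseStackSpec(d))[["trainable"]]
#' @export
denseStackSpec <- function(dims, bias = TRUE) {
    dims <- as.integer(dims)
    layers <- data.frame(
        name = sprintf("dense_%d", seq_len(length(dims) - 1L)),
        kind = "dense", kernel = 0L,
        inChannels = dims[-length(dims)], outChannels = dims[-1L],
        stride = 1L, bias = bias, stringsAsFactors = FALSE)
    new("BackboneSpec", layers = layers, inputSide = 0L,
        featureDim = dims[length(dims)])
}

#' Count backbone parameters in closed form
#'
#' Sums parameters over the layer table without instantiating a network:
#' a convolution contributes \code{k^2 * in * out} weights (+ \code{out}
#' biases when flagged), a dense layer \code{in * out} (+ \code{out}), and a
#' batch-norm layer 2 trainable (scale, offset) plus 2 non-trainable (moving
#' mean, moving variance) parameters per channel. The count is additive over
#' rows and therefore invariant to row order.
#'
#' @param spec a \linkS4class{BackboneSpec}.
#' @return Named numeric: \code{trainable}, \code{nonTrainable}.
#' @examples
#' countParameters(denseStackSpec(c(2, 3)))   # 2*3 + 3 = 9 trainable
#' @export
countParameters <- function(spec) {
    stopifnot(is(spec, "BackboneSpec"))
    tab <- spec@layers
    train <- 0; nonTrain <- 0
    for (i in seq_len(nrow(tab))) {
        r <- tab[i, ]
        if (r$kind == "conv") {
            if (r$kernel < 1L || r$inChannels < 1L || r$outChannels < 1L)
                stop("malformed conv layer '", r$name, "'")
            train <- train + r$kernel^2 * r$inChannels * r$outChannels +
                if (r$bias) r$outChannels else 0
        } else if (r$kind == "dense") {
            if (r$inChannels < 1L || r$outChannels < 1L)
                stop("malformed dense layer '", r$name, "'")
            train <- train + r$inChannels * r$outChannels +
                if (r$bias) r$outChannels else 0
        } else if (r$kind == "batchnorm") {
            if (r$outChannels < 1L)
                stop("malformed batchnorm layer '", r$name, "'")
            train <- train + 2 * r$outChannels
            nonTrain <- nonTrain + 2 * r$outChannels
        }
    }
    c(trainable = train, nonTrainable = nonTrain)
}

## ---------------------------------------------------------------------------
## Weight realization and forward pass
## ---------------------------------------------------------------------------

## im2col weight layout: row blocks ordered (dh, dw) with channels within.
.convWeightMatrix <- function(W) {
    k <- dim(W)[1L]; ins <- dim(W)[3L]; outs <- dim(W)[4L]
    m <- matrix(0, k * k * ins, outs)
    r <- 0L
    for (dh in seq_len(k)) for (dw in seq_len(k)) {
        m[r + seq_len(ins), ] <- W[dh, dw, , ]
        r <- r + ins
    }
    m
}

#' Realize a backbone with concrete weights
#'
#' Instantiates the convolutional backbone for feature extraction. With
#' \code{weights = "seeded_random"} all convolution weights are drawn from a
#' He-scaled normal distribution (s.d. \code{sqrt(2 / fan_in)}) under the
#' given seed, biases are zero, and batch-norm layers carry unit scale, zero
#' offset and unit moving statistics -- a deterministic, training-free
#' random-projection feature extractor. \code{weights =
#' "imagenet_pretrained"} requires a local \code{weightsFile} (an RDS list
#' of arrays keyed by layer name in the table's naming scheme); pretrained
#' weights are never required by the package's tests or pipeline.
#'
#' @param spec a \linkS4class{BackboneSpec} from
#'   \code{\link{canonicalResNet50Spec}}.
#' @param weights \code{"seeded_random"} or \code{"imagenet_pretrained"}.
#' @param seed integer seed for the random weights.
#' @param weightsFile path to a local RDS weight list (pretrained mode only).
#' @return A \linkS4class{RealizedBackbone}.
#' @export
realizeBackbone <- function(spec = canonicalResNet50Spec(),
                            weights = c("seeded_random",
                                        "imagenet_pretrained"),
                            seed = 1L, weightsFile = NULL) {
    weights <- match.arg(weights)
    plan <- .resnet50Plan()
    wl <- list()
    if (weights == "imagenet_pretrained") {
        if (is.null(weightsFile) || !file.exists(weightsFile))
            stop("pretrained mode needs a local 'weightsFile' (RDS list of ",
                 "arrays keyed by layer name); tests and the pipeline use ",
                 "weights = \"seeded_random\" instead")
        wl <- readRDS(weightsFile)
    } else {
        set.seed(as.integer(seed))
        initConv <- function(op) {
            W <- array(stats::rnorm(op$k^2 * op$ins * op$outs,
                                    sd = sqrt(2 / (op$k^2 * op$ins))),
                       c(op$k, op$k, op$ins, op$outs))
            list(W = .convWeightMatrix(W), b = numeric(op$outs),
                 k = op$k, ins = op$ins, outs = op$outs,
                 stride = op$stride, pad = op$pad)
        }
        for (op in plan) {
            if (op$kind == "conv") wl[[op$name]] <- initConv(op)
            else if (op$kind == "shortcut") {
                wl[[op$conv$name]] <- initConv(op$conv)
                wl[[op$bn$name]] <- list(gamma = rep(1, op$bn$ch),
                                         beta = numeric(op$bn$ch),
                                         mean = numeric(op$bn$ch),
                                         var = rep(1, op$bn$ch))
            } else if (op$kind == "batchnorm")
                wl[[op$name]] <- list(gamma = rep(1, op$ch),
                                      beta = numeric(op$ch),
                                      mean = numeric(op$ch),
                                      var = rep(1, op$ch))
        }
    }
    new("RealizedBackbone", spec = spec, weights = wl, mode = weights,
        seed = as.integer(seed))
}

.pad3d <- function(x, pad, fill = 0) {
    if (pad == 0L) return(x)
    d <- dim(x)
    out <- array(fill, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
    out[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
    out
}

.applyConv <- function(x, w) {
    x <- .pad3d(x, w$pad %||% 0L)
    d <- dim(x)
    oh <- (d[1L] - w$k) %/% w$stride + 1L
    ow <- (d[2L] - w$k) %/% w$stride + 1L
    ri <- seq.int(1L, by = w$stride, length.out = oh)
    ci <- seq.int(1L, by = w$stride, length.out = ow)
    if (w$k == 1L) {
        xm <- x[ri, ci, , drop = FALSE]
        dim(xm) <- c(oh * ow, w$ins)
    } else {
        blocks <- vector("list", w$k * w$k)
        b <- 0L
        for (dh in seq_len(w$k)) for (dw in seq_len(w$k)) {
            blk <- x[ri + dh - 1L, ci + dw - 1L, , drop = FALSE]
            dim(blk) <- c(oh * ow, w$ins)
            b <- b + 1L
            blocks[[b]] <- blk
        }
        xm <- do.call(cbind, blocks)
    }
    y <- xm %*% w$W
    if (any(w$b != 0)) y <- sweep(y, 2L, w$b, `+`)
    dim(y) <- c(oh, ow, w$outs)
    y
}

.applyBn <- function(x, w, eps = 1.001e-5) {
    scale <- w$gamma / sqrt(w$var + eps)
    shift <- w$beta - w$mean * scale
    sweep(sweep(x, 3L, scale, `*`), 3L, shift, `+`)
}

.applyMaxpool <- function(x, k, stride, pad) {
    x <- .pad3d(x, pad, fill = -Inf)
    d <- dim(x)
    oh <- (d[1L] - k) %/% stride + 1L
    ow <- (d[2L] - k) %/% stride + 1L
    ri <- seq.int(1L, by = stride, length.out = oh)
    ci <- seq.int(1L, by = stride, length.out = ow)
    out <- NULL
    for (dh in seq_len(k)) for (dw in seq_len(k)) {
        blk <- x[ri + dh - 1L, ci + dw - 1L, , drop = FALSE]
        out <- if (is.null(out)) blk else pmax(out, blk)
    }
    out
}

## ImageNet channel statistics, applied only in pretrained mode.
.imagenetMean <- c(0.485, 0.456, 0.406)
.imagenetSd <- c(0.229, 0.224, 0.225)

#' Extract deep thermomic features from an avatar
#'
#' Runs a deterministic inference-mode forward pass (batch normalization in
#' moving-statistics mode) of the realized backbone on the avatar and
#' returns the global-average-pool activations: the 2048-dimensional deep
#' thermomic feature vector. In pretrained mode the input is standardized by
#' the pretraining corpus channel statistics; in seeded-random mode the
#' avatar's [0, 1] values are used as-is.
#'
#' @param avatar an \linkS4class{Avatar} whose side matches the spec input
#'   side.
#' @param backbone a \linkS4class{RealizedBackbone}.
#' @return Numeric vector of length \code{featureDim(spec)} (2048 for the
#'   canonical backbone).
#' @export
extractFeatures <- function(avatar, backbone) {
    stopifnot(is(avatar, "Avatar"), is(backbone, "RealizedBackbone"))
    side <- backbone@spec@inputSide
    if (avatar@side != side)
        stop("avatar side ", avatar@side, " does not match the backbone ",
             "input side ", side, "; build it with makeAvatar(bs, side = ",
             side, ")")
    x <- avatarImage(avatar)
    if (backbone@mode == "imagenet_pretrained") {
        x <- sweep(x, 3L, .imagenetMean, `-`)
        x <- sweep(x, 3L, .imagenetSd, `/`)
    }
    wl <- backbone@weights
    saved <- NULL
    shortcut <- NULL
    for (op in .resnet50Plan()) {
        switch(op$kind,
            conv = { x <- .applyConv(x, wl[[op$name]]) },
            batchnorm = { x <- .applyBn(x, wl[[op$name]]) },
            relu = { x <- pmax(x, 0) },
            maxpool = { x <- .applyMaxpool(x, op$k, op$stride, op$pad) },
            save = { saved <- x; shortcut <- NULL },
            shortcut = {
                shortcut <- .applyBn(.applyConv(saved, wl[[op$conv$name]]),
                                     wl[[op$bn$name]])
            },
            add = { x <- x + if (is.null(shortcut)) saved else shortcut },
            global_avg_pool = {
                d <- dim(x)
                dim(x) <- c(d[1L] * d[2L], d[3L])
                x <- colMeans(x)
            })
    }
    as.numeric(x)
}
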