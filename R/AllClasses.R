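#' @import methods
NULL

#' ThermalSequence: a dynamic infrared acquisition
#'
#' Container for a stack of single-channel temperature frames recorded at a
#' fixed interval, together with minimal subject metadata. Temperatures are
#' degrees Celsius; frames are stored as a \code{tau x rows x cols} array.
#'
#' @slot frames numeric array, \code{tau x rows x cols}, degrees Celsius.
#' @slot frameInterval numeric(1), seconds between frames.
#' @slot subjectId character(1).
#' @slot label character(1), one of \code{"healthy"}, \code{"symptomatic"},
#'   \code{"unknown"}.
#' @slot noiseSigma numeric(1), standard deviation of the additive sensor
#'   noise already present in \code{frames} (degrees Celsius; 0 if none).
#'
#' @exportClass ThermalSequence
setClass("ThermalSequence",
    representation(frames = "array", frameInterval = "numeric",
                   subjectId = "character", label = "character",
                   noiseSigma = "numeric"))

setValidity("ThermalSequence", function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
        msg <- c(msg, "'frames' must be a 3-d array (tau x rows x cols)")
    else if (dim(object@frames)[1L] < 1L)
        msg <- c(msg, "need at least one frame (tau >= 1)")
    if (!all(is.finite(object@frames)))
        msg <- c(msg, "'frames' contains non-finite temperatures")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
        msg <- c(msg, "'frameInterval' must be a single positive number")
    if (!object@label %in% c("healthy", "symptomatic", "unknown"))
        msg <- c(msg, "'label' must be healthy, symptomatic or unknown")
    if (length(msg)) msg else TRUE
})

#' Construct a ThermalSequence
#'
#' @param frames 3-d array (\code{tau x rows x cols}) of temperatures in
#'   degrees Celsius, or a list of equally sized matrices.
#' @param frameInterval seconds between consecutive frames (default 15).
#' @param subjectId subject identifier.
#' @param label \code{"healthy"}, \code{"symptomatic"} or \code{"unknown"}.
#' @param noiseSigma sensor noise s.d. already contained in the frames.
#' @return A \linkS4class{ThermalSequence}.
#' @examples
#' ts <- ThermalSequence(array(30, c(5, 8, 8)))
#' nFrames(ts)
#' @export
ThermalSequence <- function(frames, frameInterval = 15, subjectId = "subject",
                            label = "unknown", noiseSigma = 0) {
    if (is.list(frames)) {
        shapes <- unique(lapply(frames, dim))
        if (length(shapes) != 1L)
            stop("frames differ in shape: ",
                 paste(vapply(shapes, paste, "", collapse = "x"),
                       collapse = " vs "))
        frames <- aperm(simplify2array(frames), c(3L, 1L, 2L))
    }
    new("ThermalSequence", frames = frames, frameInterval = frameInterval,
        subjectId = subjectId, label = label, noiseSigma = noiseSigma)
}

#' TissueGrid: a 2-d Pennes bioheat phantom
#'
#' A rectangular grid of tissue cells carrying the physical fields of the
#' Pennes bioheat equation. The 2-d grid is the observed skin plane; the
#' breast mask delimits tissue, and the tumor mask (a subset of the breast
#' mask) marks cells with elevated metabolic heat generation and perfusion.
#'
#' @slot cellSize numeric(1), cell edge length in metres.
#' @slot rho density, kg/m^3 (matrix, per cell).
#' @slot cp specific heat, J/(kg K) (matrix).
#' @slot k thermal conductivity, W/(m K) (matrix; may be zero for analytic
#'   test phantoms).
#' @slot omegaB blood perfusion rate, kg/(m^3 s) (matrix; >= 0).
#' @slot qm metabolic heat generation, W/m^3 (matrix).
#' @slot cb blood specific heat, J/(kg K) (scalar).
#' @slot Ta arterial blood temperature, degrees Celsius (scalar).
#' @slot breastMask logical matrix, TRUE inside the tissue region of interest.
#' @slot tumorMask logical matrix, subset of \code{breastMask}.
#'
#' @exportClass TissueGrid
setClass("TissueGrid",
    representation(cellSize = "numeric", rho = "matrix", cp = "matrix",
                   k = "matrix", omegaB = "matrix", qm = "matrix",
                   cb = "numeric", Ta = "numeric",
                   breastMask = "matrix", tumorMask = "matrix"))

setValidity("TissueGrid", function(object) {
    msg <- character()
    dims <- lapply(list(object@rho, object@cp, object@k, object@omegaB,
                        object@qm, object@breastMask, object@tumorMask), dim)
    if (length(unique(dims)) != 1L)
        msg <- c(msg, "all per-cell fields must share the grid shape")
    if (object@cellSize <= 0) msg <- c(msg, "'cellSize' must be positive")
    if (any(object@rho <= 0) || any(object@cp <= 0))
        msg <- c(msg, "density and specific heat must be strictly positive")
    if (any(object@k < 0) || any(object@omegaB < 0))
        msg <- c(msg, "conductivity and perfusion must be non-negative")
    if (object@cb <= 0) msg <- c(msg, "'cb' must be positive")
    if (any(object@tumorMask & !object@breastMask))
        msg <- c(msg, "tumorMask must be a subset of breastMask")
    if (!all(is.finite(c(object@rho, object@cp, object@k, object@omegaB,
                         object@qm))))
        msg <- c(msg, "physical fields contain non-finite values")
    if (length(msg)) msg else TRUE
})

#' HeatMatrix: mean-centred pixels-by-frames matrix
#'
#' The vectorized representation of a cropped thermal sequence: column j is
#' the row-major vectorization of the region of interest (ROI) of frame j,
#' with the per-pixel temporal mean removed. The economy shape p > n (more
#' pixels than frames) is enforced.
#'
#' @slot X numeric matrix, p x n, zero row means.
#' @slot rowMean numeric(p), the per-pixel temporal means removed.
#' @slot roi integer(4): row0, col0, height, width (0-based, half-open).
#' @slot sourceShape integer(2): rows, cols of the originating frames.
#'
#' @exportClass HeatMatrix
setClass("HeatMatrix",
    representation(X = "matrix", rowMean = "numeric", roi = "integer",
                   sourceShape = "integer"))

setValidity("HeatMatrix", function(object) {
    msg <- character()
    if (nrow(object@X) <= ncol(object@X))
        msg <- c(msg, sprintf(
            "heat matrix must satisfy p > n (got p = %d pixels, n = %d frames)",
            nrow(object@X), ncol(object@X)))
    if (length(object@rowMean) != nrow(object@X))
        msg <- c(msg, "'rowMean' length must equal nrow(X)")
    if (max(abs(rowMeans(object@X))) >= 1e-9)
        msg <- c(msg, "rows of X are not mean-centred (|mean| >= 1e-9)")
    if (length(object@roi) != 4L)
        msg <- c(msg, "'roi' must be integer(4): row0, col0, height, width")
    if (length(msg)) msg else TRUE
})

#' BasisSet: spatial bases of a low-rank thermal decomposition
#'
#' Result of \code{\link{pct}} or \code{\link{sparsePct}}: k spatial basis
#' images (reshaped left singular vectors / sparse loadings), the singular
#' value spectrum, and the temporal coefficient vectors.
#'
#' @slot bases list of k matrices (ROI shape), unit l2 norm each.
#' @slot singularValues full non-increasing spectrum (length >= k).
#' @slot coefficients n x k matrix of temporal coefficients.
#' @slot method \code{"pct"} or \code{"sparse_pct"}.
#' @slot sparsity numeric(k), fraction of zero entries per basis.
#' @slot converged logical(k), per-component convergence flag.
#'
#' @exportClass BasisSet
setClass("BasisSet",
    representation(bases = "list", singularValues = "numeric",
                   coefficients = "matrix", method = "character",
                   sparsity = "numeric", converged = "logical"))

setValidity("BasisSet", function(object) {
    msg <- character()
    if (length(object@singularValues) &&
        any(diff(object@singularValues) > 1e-8))
        msg <- c(msg, "'singularValues' must be non-increasing")
    if (any(object@singularValues < -1e-12))
        msg <- c(msg, "'singularValues' must be non-negative")
    if (!object@method %in% c("pct", "sparse_pct"))
        msg <- c(msg, "'method' must be pct or sparse_pct")
    if (length(unique(lapply(object@bases, dim))) > 1L)
        msg <- c(msg, "all bases must share the ROI shape")
    if (length(msg)) msg else TRUE
})

#' Avatar: three-channel low-rank surrogate image
#'
#' The square 3-channel image whose channels are the first three spatial
#' bases of a thermal decomposition, min-max normalized to [0, 1] and resized
#' to the backbone input side. It plays the role of an RGB image for an
#' RGB-pretrained convolutional network.
#'
#' @slot image numeric array, side x side x 3, values in [0, 1].
#' @slot side integer(1), image side in pixels.
#' @slot channelOrder character(3), which basis fills which channel.
#'
#' @exportClass Avatar
setClass("Avatar",
    representation(image = "array", side = "integer",
                   channelOrder = "character"))

setValidity("Avatar", function(object) {
    msg <- character()
    d <- dim(object@image)
    if (length(d) != 3L || d[3L] != 3L || d[1L] != d[2L])
        msg <- c(msg, "'image' must be a square side x side x 3 array")
    else if (d[1L] != object@side)
        msg <- c(msg, "'side' does not match the image dimensions")
    if (!all(is.finite(object@image)) || min(object@image) < -1e-12 ||
        max(object@image) > 1 + 1e-12)
        msg <- c(msg, "avatar values must be finite and in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' BackboneSpec: declarative layer table of a convolutional backbone
#'
#' A flat, ordered table of layer descriptors sufficient for closed-form
#' parameter counting: one row per layer with kind (conv, batchnorm, relu,
#' maxpool, identity_add, global_avg_pool, dense), kernel size, input/output
#' channels, stride and bias flag.
#'
#' @slot layers data.frame with columns name, kind, kernel, inChannels,
#'   outChannels, stride, bias.
#' @slot inputSide integer(1), expected input side in pixels.
#' @slot featureDim integer(1), width of the feature tap (global average
#'   pool output).
#'
#' @exportClass BackboneSpec
setClass("BackboneSpec",
    representation(layers = "data.frame", inputSide = "integer",
                   featureDim = "integer"))

setValidity("BackboneSpec", function(object) {
    msg <- character()
    need <- c("name", "kind", "kernel", "inChannels", "outChannels",
              "stride", "bias")
    if (!all(need %in% names(object@layers)))
        msg <- c(msg, paste("'layers' must have columns:",
                            paste(need, collapse = ", ")))
    else {
        kinds <- c("conv", "batchnorm", "relu", "maxpool", "identity_add",
                   "global_avg_pool", "dense", "input")
        if (!all(object@layers$kind %in% kinds))
            msg <- c(msg, "unknown layer kind in 'layers'")
    }
    if (length(msg)) msg else TRUE
})

#' RealizedBackbone: a BackboneSpec with concrete weights
#'
#' @slot spec the \linkS4class{BackboneSpec} this network realizes.
#' @slot weights named list of weight arrays (internal layout).
#' @slot mode \code{"seeded_random"} or \code{"imagenet_pretrained"}.
#' @slot seed integer(1) used for weight initialization.
#'
#' @exportClass RealizedBackbone
setClass("RealizedBackbone",
    representation(spec = "BackboneSpec", weights = "list",
                   mode = "character", seed = "integer"))

#' AutoencoderSpec: architecture of the sparse deep autoencoder
#'
#' @slot dims integer vector of encoder layer widths, strictly decreasing;
#'   the decoder mirrors it. Default \code{c(2048, 1024, 256, 64, 16)}.
#' @slot l1Weight numeric(1), l1 activity penalty on the first hidden code.
#' @slot seed integer(1) for weight initialization and batching.
#' @slot tiedWeights logical(1); if TRUE the decoder reuses transposed
#'   encoder weights.
#'
#' @exportClass AutoencoderSpec
setClass("AutoencoderSpec",
    representation(dims = "integer", l1Weight = "numeric", seed = "integer",
                   tiedWeights = "logical"))

setValidity("AutoencoderSpec", function(object) {
    msg <- character()
    if (length(object@dims) < 2L)
        msg <- c(msg, "'dims' needs at least an input and a bottleneck width")
    if (any(diff(object@dims) >= 0))
        msg <- c(msg, "'dims' must be strictly decreasing (encoder side)")
    if (object@l1Weight < 0) msg <- c(msg, "'l1Weight' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an AutoencoderSpec
#'
#' @param dims encoder layer widths, strictly decreasing; first entry is the
#'   feature width, last the bottleneck. Default \code{c(2048, 1024, 256,
#'   64, 16)} giving a 128x compression.
#' @param l1Weight l1 activity penalty on the first hidden layer's code
#'   (default \code{1e-5}).
#' @param seed RNG seed for initialization and batch shuffling.
#' @param tiedWeights reuse transposed encoder weights in the decoder.
#' @return An \linkS4class{AutoencoderSpec}.
#' @examples
#' sp <- autoencoderSpec()
#' bottleneckDim(sp)
#' compressionFactor(sp)
#' @export
autoencoderSpec <- function(dims = c(2048L, 1024L, 256L, 64L, 16L),
                            l1Weight = 1e-5, seed = 1L,
                            tiedWeights = FALSE) {
    new("AutoencoderSpec", dims = as.integer(dims), l1Weight = l1Weight,
        seed = as.integer(seed), tiedWeights = tiedWeights)
}

#' AutoencoderModel: a trained sparse deep autoencoder
#'
#' @slot spec the \linkS4class{AutoencoderSpec} trained.
#' @slot weights list of dense layer weights/biases (encoder then decoder).
#' @slot trained logical(1).
#' @slot lossHistory data.frame with per-epoch columns epoch, train
#'   (and validation when a validation split was used).
#' @slot codes numeric matrix, n x bottleneck latent codes of the training
#'   table.
#'
#' @exportClass AutoencoderModel
setClass("AutoencoderModel",
    representation(spec = "AutoencoderSpec", weights = "list",
                   trained = "logical", lossHistory = "data.frame",
                   codes = "matrix"))

#' DesignMatrix: subjects-by-features table for classification
#'
#' @slot x numeric matrix, one row per subject (latent thermomics and/or
#'   encoded clinical covariates).
#' @slot labels integer vector, 0 = healthy, 1 = symptomatic.
#' @slot subjectIds character vector, unique.
#' @slot featureSet \code{"latent_only"}, \code{"clinical_only"} or
#'   \code{"latent_plus_clinical"}.
#'
#' @exportClass DesignMatrix
setClass("DesignMatrix",
    representation(x = "matrix", labels = "integer",
                   subjectIds = "character", featureSet = "character"))

setValidity("DesignMatrix", function(object) {
    msg <- character()
    if (nrow(object@x) != length(object@labels) ||
        nrow(object@x) != length(object@subjectIds))
        msg <- c(msg, "rows of 'x', 'labels' and 'subjectIds' must align")
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "'labels' must be 0 (healthy) or 1 (symptomatic)")
    if (anyDuplicated(object@subjectIds))
        msg <- c(msg, "'subjectIds' must be unique")
    if (any(!is.finite(object@x)))
        msg <- c(msg, "'x' contains missing or non-finite values")
    if (length(msg)) msg else TRUE
})

#' EvalReport: leave-one-out classification report
#'
#' @slot accuracy percent correct over out-of-fold predictions.
#' @slot accuracyInterval numeric(2), percentile-bootstrap interval (percent).
#' @slot auc area under the pooled out-of-fold ROC curve.
#' @slot roc data.frame of ROC points (fpr, tpr, threshold).
#' @slot predictions data.frame: subjectId, label, prob, predicted, correct.
#' @slot seed integer(1).
#' @slot nSubjects integer(1).
#' @slot featureSet character(1) tag of the design matrix evaluated.
#'
#' @exportClass EvalReport
setClass("EvalReport",
    representation(accuracy = "numeric", accuracyInterval = "numeric",
                   auc = "numeric", roc = "data.frame",
                   predictions = "data.frame", seed = "integer",
                   nSubjects = "integer", featureSet = "character"))

setValidity("EvalReport", function(object) {
    msg <- character()
    if (length(object@accuracyInterval) != 2L)
        msg <- c(msg, "'accuracyInterval' must be (lo, hi)")
    else if (object@accuracyInterval[1L] > object@accuracy + 1e-9 ||
             object@accuracyInterval[2L] < object@accuracy - 1e-9)
        msg <- c(msg, "interval must contain the point accuracy")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "'auc' must lie in [0, 1]")
    if (nrow(object@predictions) != object@nSubjects)
        msg <- c(msg, "one out-of-fold prediction per subject required")
    if (length(msg)) msg else TRUE
})
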