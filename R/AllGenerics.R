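#' @include AllClasses.R
NULL

#' Accessors for thermomics objects
#'
#' Small accessor generics for the core S4 classes; use these instead of
#' direct slot access.
#'
#' @param object a thermomics S4 object.
#' @param ... unused.
#' @return The slot value (see details per method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object, ...) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object, ...) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval",
           function(object, ...) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object, ...) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("subjectLabel",
           function(object, ...) standardGeneric("subjectLabel"))
#' @rdname accessors
#' @export
setGeneric("heatValues", function(object, ...) standardGeneric("heatValues"))
#' @rdname accessors
#' @export
setGeneric("roi", function(object, ...) standardGeneric("roi"))
#' @rdname accessors
#' @export
setGeneric("bases", function(object, ...) standardGeneric("bases"))
#' @rdname accessors
#' @export
setGeneric("singularValues",
           function(object, ...) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("decompMethod",
           function(object, ...) standardGeneric("decompMethod"))
#' @rdname accessors
#' @export
setGeneric("basisSparsity",
           function(object, ...) standardGeneric("basisSparsity"))
#' @rdname accessors
#' @export
setGeneric("avatarImage", function(object, ...) standardGeneric("avatarImage"))
#' @rdname accessors
#' @export
setGeneric("backboneLayers",
           function(object, ...) standardGeneric("backboneLayers"))
#' @rdname accessors
#' @export
setGeneric("featureDim", function(object, ...) standardGeneric("featureDim"))
#' @rdname accessors
#' @export
setGeneric("bottleneckDim",
           function(object, ...) standardGeneric("bottleneckDim"))
#' @rdname accessors
#' @export
setGeneric("compressionFactor",
           function(object, ...) standardGeneric("compressionFactor"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object, ...) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("latentCodes", function(object, ...) standardGeneric("latentCodes"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("accuracyInterval",
           function(object, ...) standardGeneric("accuracyInterval"))
#' @rdname accessors
#' @export
setGeneric("rocAuc", function(object, ...) standardGeneric("rocAuc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object, ...) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("foldPredictions",
           function(object, ...) standardGeneric("foldPredictions"))
#' @rdname accessors
#' @export
setGeneric("featureSet", function(object, ...) standardGeneric("featureSet"))

## ThermalSequence
#' @rdname accessors
#' @export
setMethod("frames", "ThermalSequence", function(object, ...) object@frames)
#' @rdname accessors
#' @export
setMethod("nFrames", "ThermalSequence",
          function(object, ...) dim(object@frames)[1L])
#' @rdname accessors
#' @export
setMethod("frameInterval", "ThermalSequence",
          function(object, ...) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("subjectId", "ThermalSequence",
          function(object, ...) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectLabel", "ThermalSequence",
          function(object, ...) object@label)

## HeatMatrix
#' @rdname accessors
#' @export
setMethod("heatValues", "HeatMatrix", function(object, ...) object@X)
#' @rdname accessors
#' @export
setMethod("roi", "HeatMatrix", function(object, ...) object@roi)

## BasisSet
#' @rdname accessors
#' @export
setMethod("bases", "BasisSet", function(object, ...) object@bases)
#' @rdname accessors
#' @export
setMethod("singularValues", "BasisSet",
          function(object, ...) object@singularValues)
#' @rdname accessors
#' @export
setMethod("decompMethod", "BasisSet", function(object, ...) object@method)
#' @rdname accessors
#' @export
setMethod("basisSparsity", "BasisSet", function(object, ...) object@sparsity)

## Avatar
#' @rdname accessors
#' @export
setMethod("avatarImage", "Avatar", function(object, ...) object@image)

## BackboneSpec
#' @rdname accessors
#' @export
setMethod("backboneLayers", "BackboneSpec",
          function(object, ...) object@layers)
#' @rdname accessors
#' @export
setMethod("featureDim", "BackboneSpec",
          function(object, ...) object@featureDim)

## AutoencoderSpec / AutoencoderModel
#' @rdname accessors
#' @export
setMethod("bottleneckDim", "AutoencoderSpec",
          function(object, ...) object@dims[length(object@dims)])
#' @rdname accessors
#' @export
setMethod("compressionFactor", "AutoencoderSpec",
          function(object, ...) object@dims[1L] / object@dims[length(object@dims)])
#' @rdname accessors
#' @export
setMethod("bottleneckDim", "AutoencoderModel",
          function(object, ...) bottleneckDim(object@spec))
#' @rdname accessors
#' @export
setMethod("compressionFactor", "AutoencoderModel",
          function(object, ...) compressionFactor(object@spec))
#' @rdname accessors
#' @export
setMethod("lossHistory", "AutoencoderModel",
          function(object, ...) object@lossHistory)
#' @rdname accessors
#' @export
setMethod("latentCodes", "AutoencoderModel", function(object, ...) object@codes)

## EvalReport
#' @rdname accessors
#' @export
setMethod("accuracy", "EvalReport", function(object, ...) object@accuracy)
#' @rdname accessors
#' @export
setMethod("accuracyInterval", "EvalReport",
          function(object, ...) object@accuracyInterval)
#' @rdname accessors
#' @export
setMethod("rocAuc", "EvalReport", function(object, ...) object@auc)
#' @rdname accessors
#' @export
setMethod("rocPoints", "EvalReport", function(object, ...) object@roc)
#' @rdname accessors
#' @export
setMethod("foldPredictions", "EvalReport",
          function(object, ...) object@predictions)
#' @rdname accessors
#' @export
setMethod("featureSet", "EvalReport", function(object, ...) object@featureSet)
#' @rdname accessors
#' @export
setMethod("featureSet", "DesignMatrix", function(object, ...) object@featureSet)

## show methods --------------------------------------------------------------

setMethod("show", "ThermalSequence", function(object) {
    d <- dim(object@frames)
    cat("ThermalSequence '", object@subjectId, "' (", object@label, ")\n",
        "  ", d[1L], " frames of ", d[2L], " x ", d[3L],
        " px every ", object@frameInterval, " s\n",
        "  temperature range [", sprintf("%.2f", min(object@frames)), ", ",
        sprintf("%.2f", max(object@frames)), "] degC\n", sep = "")
})

setMethod("show", "TissueGrid", function(object) {
    d <- dim(object@rho)
    cat("TissueGrid ", d[1L], " x ", d[2L], " cells of ",
        object@cellSize * 1000, " mm\n",
        "  breast cells: ", sum(object@breastMask),
        ", tumor cells: ", sum(object@tumorMask), "\n",
        "  q_m range [", min(object@qm), ", ", max(object@qm), "] W/m^3\n",
        sep = "")
})

setMethod("show", "HeatMatrix", function(object) {
    cat("HeatMatrix ", nrow(object@X), " pixels x ", ncol(object@X),
        " frames (p > n), ROI [", paste(object@roi, collapse = ", "),
        "] of ", paste(object@sourceShape, collapse = " x "), "\n", sep = "")
})

setMethod("show", "BasisSet", function(object) {
    cat("BasisSet (", object@method, "): ", length(object@bases),
        " spatial bases of ",
        paste(dim(object@bases[[1L]]), collapse = " x "), "\n",
        "  leading singular values: ",
        paste(sprintf("%.3g", utils::head(object@singularValues, 3L)),
              collapse = ", "), "\n",
        "  sparsity (zero fraction): ",
        paste(sprintf("%.2f", object@sparsity), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "Avatar", function(object) {
    cat("Avatar ", object@side, " x ", object@side, " x 3 (channels: ",
        paste(object@channelOrder, collapse = ", "), ")\n", sep = "")
})

setMethod("show", "BackboneSpec", function(object) {
    pc <- countParameters(object)
    cat("BackboneSpec: ", nrow(object@layers), " layers, input ",
        object@inputSide, " x ", object@inputSide, " x 3, feature dim ",
        object@featureDim, "\n  parameters: ",
        format(pc[["trainable"]], big.mark = ","), " trainable, ",
        format(pc[["nonTrainable"]], big.mark = ","), " non-trainable\n",
        sep = "")
})

setMethod("show", "AutoencoderModel", function(object) {
    cat("AutoencoderModel ", paste(object@spec@dims, collapse = "-"),
        " (mirrored), ", if (object@trained) "trained" else "untrained",
        "\n  l1 weight ", object@spec@l1Weight, ", compression ",
        compressionFactor(object), "x\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport [", object@featureSet, "]: accuracy ",
        sprintf("%.2f", object@accuracy), "% (",
        sprintf("%.2f", object@accuracyInterval[1L]), "-",
        sprintf("%.2f", object@accuracyInterval[2L]), "%), AUC ",
        sprintf("%.3f", object@auc), ", n = ", object@nSubjects, "\n",
        sep = "")
})
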