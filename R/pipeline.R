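#' @include AllClasses.R
NULL

#' Default end-to-end run configuration
#'
#' The default run simulates a 60-subject synthetic cohort (30 healthy, 30
#' symptomatic) under the standard acquisition protocol (23 frames of
#' 64 x 64 every 15 s, 0.04 degC sensor noise), decomposes each sequence
#' with sparse PCT, extracts 2048 deep thermomics with the seeded-random
#' backbone, compresses them to 16 latent thermomics and evaluates a
#' leave-one-out random forest on latent-plus-clinical features.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param nHealthy,nSymptomatic cohort sizes.
#' @param method \code{"sparse_pct"}, \code{"pct"} or \code{"both"}.
#' @param shape,nFrames,frameInterval,noiseSigma simulator settings.
#' @param lambda1,lambda2 sparse-PCT penalties.
#' @param epochs,batchSize,l1Weight autoencoder training settings.
#' @param nTrees forest size.
#' @param featureSets character vector of design-matrix variants to
#'   evaluate.
#' @param dataDir optional directory of externally acquired sequences (one
#'   subdirectory per subject, see \code{\link{readSequence}}); when set, a
#'   \code{roiTable} and \code{cohortFile} are required and the simulator
#'   is skipped.
#' @param roiTable,cohortFile per-subject ROI CSV and covariate CSV for
#'   external data.
#' @return A named list (the run configuration).
#' @export
defaultRunConfig <- function(seed = 1L, nHealthy = 30L, nSymptomatic = 30L,
                             method = "sparse_pct",
                             shape = c(64L, 64L), nFrames = 23L,
                             frameInterval = 15, noiseSigma = 0.04,
                             lambda1 = 0.05, lambda2 = 0,
                             epochs = 500L, batchSize = 128L,
                             l1Weight = 1e-5, nTrees = 1000L,
                             featureSets = c("latent_plus_clinical",
                                             "latent_only",
                                             "clinical_only"),
                             dataDir = NULL, roiTable = NULL,
                             cohortFile = NULL) {
    as.list(environment())
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file.
#' @return A run configuration list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- defaultRunConfig()
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    base[names(cfg)] <- cfg
    base
}

.validateConfig <- function(cfg) {
    if (!cfg$method %in% c("pct", "sparse_pct", "both"))
        stop("method must be pct, sparse_pct or both")
    if (!is.null(cfg$dataDir)) {
        if (is.null(cfg$roiTable))
            stop("external data requires an ROI table ",
                 "(per-subject crop rectangles); set 'roiTable'")
        if (is.null(cfg$cohortFile))
            stop("external data requires a covariate table; ",
                 "set 'cohortFile'")
    }
    invisible(cfg)
}

.loadExternal <- function(cfg) {
    dirs <- list.dirs(cfg$dataDir, recursive = FALSE)
    if (!length(dirs)) stop("no subject directories under ", cfg$dataDir)
    sequences <- lapply(dirs, readSequence)
    cohort <- utils::read.csv(cfg$cohortFile, stringsAsFactors = FALSE)
    ids <- vapply(sequences, subjectId, "")
    cohort <- cohort[match(ids, cohort$subjectId), ]
    if (anyNA(cohort$subjectId))
        stop("cohort table is missing subjects: ",
             paste(ids[is.na(cohort$subjectId)], collapse = ", "))
    rois <- readRoiTable(cfg$roiTable)
    list(sequences = sequences, cohort = cohort, rois = rois)
}

.subjectRoi <- function(rois, id, shape) {
    if (is.null(rois)) return(centeredRoi(shape))
    r <- rois[rois$subjectId == id, ]
    if (!nrow(r)) stop("no ROI for subject ", id)
    as.integer(r[1L, c("row0", "col0", "height", "width")])
}

#' Run the full thermomics pipeline
#'
#' Orchestrates simulate (or load) -> heat matrix -> low-rank avatar ->
#' deep features -> sparse autoencoder -> leave-one-out random forest as
#' one reproducible run. With \code{method = "both"} the sparse-PCT and PCT
#' branches are run on the same cohort and backbone and a comparison table
#' is produced. All artifacts (cohort table, features, latent codes,
#' reports, manifest) are written under \code{outDir} when given.
#'
#' @param cfg run configuration from \code{\link{defaultRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param outDir optional output directory for artifacts.
#' @param verbose print stage progress (default TRUE).
#' @return List with elements \code{cohort}, per-method \code{features},
#'   \code{codes} and \code{reports} (list of \linkS4class{EvalReport} per
#'   feature set), and \code{comparison} (summary data.frame across all
#'   evaluated variants).
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir = NULL,
                        verbose = TRUE) {
    .validateConfig(cfg)
    say <- function(...) if (verbose) message("[thermomics] ", ...)
    seed <- as.integer(cfg$seed)
    if (!is.null(outDir))
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    ## stage 1: cohort ------------------------------------------------------
    if (is.null(cfg$dataDir)) {
        say("simulating cohort: ", cfg$nHealthy, " healthy + ",
            cfg$nSymptomatic, " symptomatic")
        sim <- generateCohort(cfg$nHealthy, cfg$nSymptomatic, seed = seed,
                              shape = cfg$shape, nFrames = cfg$nFrames,
                              frameInterval = cfg$frameInterval,
                              noiseSigma = cfg$noiseSigma)
        sequences <- sim$sequences
        cohort <- sim$cohort
        rois <- NULL
    } else {
        say("loading external sequences from ", cfg$dataDir)
        ext <- .loadExternal(cfg)
        sequences <- ext$sequences
        cohort <- ext$cohort
        rois <- ext$rois
    }
    n <- length(sequences)
    if (n < 3L) stop("pipeline needs at least 3 subjects")
    methods <- if (cfg$method == "both") c("sparse_pct", "pct")
               else cfg$method

    ## stage 2+3: avatars and deep features --------------------------------
    backbone <- realizeBackbone(seed = seed)
    features <- list()
    for (m in methods) {
        say("decomposition (", m, ") and feature extraction, n = ", n)
        feat <- matrix(NA_real_, n, featureDim(backbone@spec))
        for (i in seq_len(n)) {
            sq <- sequences[[i]]
            hm <- buildHeatMatrix(sq, .subjectRoi(rois, subjectId(sq),
                                                  dim(frames(sq))[2:3]))
            bs <- if (m == "sparse_pct")
                sparsePct(hm, k = 3L, lambda1 = cfg$lambda1,
                          lambda2 = cfg$lambda2)
            else pct(hm, k = 3L)
            feat[i, ] <- extractFeatures(makeAvatar(bs), backbone)
        }
        rownames(feat) <- cohort$subjectId
        features[[m]] <- feat
    }

    ## stage 4: autoencoder -------------------------------------------------
    codes <- list()
    for (m in methods) {
        say("training sparse autoencoder (", m, "), ", cfg$epochs,
            " epochs")
        sc <- scaleFeatures(features[[m]])
        model <- trainAutoencoder(
            sc$scaled,
            spec = autoencoderSpec(l1Weight = cfg$l1Weight, seed = seed),
            epochs = cfg$epochs, batchSize = cfg$batchSize)
        codes[[m]] <- latentCodes(model)
        rownames(codes[[m]]) <- cohort$subjectId
    }

    ## stage 5: classification ----------------------------------------------
    reports <- list()
    for (m in methods) {
        say("leave-one-out random forest (", m, ")")
        dms <- lapply(cfg$featureSets, function(fs)
            buildDesignMatrix(codes[[m]], cohort, featureSet = fs))
        names(dms) <- cfg$featureSets
        cmp <- compareFeatureSets(dms, nTrees = cfg$nTrees, seed = seed)
        reports[[m]] <- cmp$reports
    }
    comparison <- do.call(rbind, lapply(methods, function(m) {
        s <- do.call(rbind, lapply(reports[[m]], function(r)
            data.frame(method = m, featureSet = featureSet(r),
                       accuracy = accuracy(r),
                       lo = accuracyInterval(r)[1L],
                       hi = accuracyInterval(r)[2L],
                       auc = rocAuc(r), stringsAsFactors = FALSE)))
        s
    }))
    comparison <- comparison[order(comparison$accuracy, decreasing = TRUE), ]
    rownames(comparison) <- NULL

    ## artifacts -------------------------------------------------------------
    if (!is.null(outDir)) {
        utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                         row.names = FALSE)
        for (m in methods) {
            utils::write.csv(
                data.frame(subjectId = cohort$subjectId, features[[m]],
                           check.names = FALSE),
                file.path(outDir, paste0("features_", m, ".csv")),
                row.names = FALSE)
            utils::write.csv(
                data.frame(subjectId = cohort$subjectId, codes[[m]],
                           check.names = FALSE),
                file.path(outDir, paste0("codes_", m, ".csv")),
                row.names = FALSE)
            for (fs in names(reports[[m]]))
                writeEvalReport(reports[[m]][[fs]],
                                file.path(outDir,
                                          sprintf("report_%s_%s.json",
                                                  m, fs)))
        }
        utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                         row.names = FALSE)
        manifest <- list(
            package = as.character(utils::packageVersion("thermomics")),
            rVersion = R.version.string,
            seed = seed,
            config = cfg[setdiff(names(cfg),
                                 c("dataDir", "roiTable", "cohortFile"))],
            nSubjects = n,
            methods = methods,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
    }
    list(cohort = cohort, features = features, codes = codes,
         reports = reports, comparison = comparison)
}
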