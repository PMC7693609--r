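#' @include AllClasses.R
NULL

#' Build a subjects-by-features design matrix
#'
#' Combines latent thermomics and/or encoded clinical covariates (age as a
#' number; family history either any-vs-none, the default, or one-hot per
#' condition; hormone therapy optionally as 0/1) into a
#' \linkS4class{DesignMatrix} with binary labels (healthy = 0,
#' symptomatic = 1).
#'
#' @param codes numeric matrix of latent codes, one row per subject (may be
#'   NULL for \code{featureSet = "clinical_only"}). Rows are matched to
#'   \code{cohort} by position.
#' @param cohort data.frame with columns subjectId, age, familyHistory,
#'   hormoneTherapy, label (as produced by \code{\link{generateCohort}}).
#' @param featureSet \code{"latent_plus_clinical"}, \code{"latent_only"} or
#'   \code{"clinical_only"}.
#' @param familyHistory \code{"any"} (indicator of any family history,
#'   default) or \code{"per_condition"} (one-hot).
#' @param includeHormoneTherapy include the hormone therapy indicator among
#'   the clinical covariates (default FALSE: the reference covariate set is
#'   age and family history).
#' @return A \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(codes, cohort,
                              featureSet = c("latent_plus_clinical",
                                             "latent_only",
                                             "clinical_only"),
                              familyHistory = c("any", "per_condition"),
                              includeHormoneTherapy = FALSE) {
    featureSet <- match.arg(featureSet)
    familyHistory <- match.arg(familyHistory)
    labels <- as.integer(cohort$label == "symptomatic")
    parts <- list()
    if (featureSet != "clinical_only") {
        codes <- as.matrix(codes)
        if (nrow(codes) != nrow(cohort))
            stop("latent codes (", nrow(codes), " rows) do not match the ",
                 "cohort (", nrow(cohort), " subjects)")
        colnames(codes) <- sprintf("latent%02d", seq_len(ncol(codes)))
        parts$latent <- codes
    }
    if (featureSet != "latent_only") {
        clin <- cbind(age = as.numeric(cohort$age))
        if (familyHistory == "any") {
            clin <- cbind(clin,
                          familyHistoryAny =
                              as.numeric(cohort$familyHistory != "none"))
        } else {
            for (lev in c("diabetes", "hypertensive", "leukemia"))
                clin <- cbind(clin, as.numeric(cohort$familyHistory == lev))
            colnames(clin)[-1L] <- paste0("familyHistory_",
                                          c("diabetes", "hypertensive",
                                            "leukemia"))
        }
        if (includeHormoneTherapy)
            clin <- cbind(clin,
                          hormoneTherapy = as.numeric(cohort$hormoneTherapy))
        parts$clinical <- clin
    }
    new("DesignMatrix", x = do.call(cbind, parts), labels = labels,
        subjectIds = as.character(cohort$subjectId),
        featureSet = featureSet)
}

.rocFromScores <- function(labels, scores) {
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    list(auc = as.numeric(pROC::auc(r)),
         points = data.frame(fpr = 1 - r$specificities,
                             tpr = r$sensitivities,
                             threshold = r$thresholds))
}

#' Leave-one-out random-forest evaluation
#'
#' For every subject, a random forest is trained on all remaining subjects
#' and predicts the held-out one; the point accuracy is the fraction of
#' correct out-of-fold predictions, the accuracy interval is a percentile
#' bootstrap (default 2000 resamples) over the per-subject correctness
#' vector, and the ROC curve is pooled from the out-of-fold class-1
#' probabilities. Subjects are processed in a canonical order (sorted by
#' subjectId), so the report is invariant to the row order of the design
#' matrix under a fixed seed.
#'
#' @param dm a \linkS4class{DesignMatrix} with both classes present and at
#'   least 3 subjects.
#' @param nTrees trees per forest (default 1000).
#' @param seed integer seed controlling forest growth and the bootstrap.
#' @param nBoot bootstrap resamples for the accuracy interval
#'   (default 2000).
#' @param level interval coverage (default 0.95).
#' @return An \linkS4class{EvalReport}.
#' @export
loocvRandomForest <- function(dm, nTrees = 1000L, seed = 1L,
                              nBoot = 2000L, level = 0.95) {
    stopifnot(is(dm, "DesignMatrix"))
    n <- nrow(dm@x)
    if (n < 3L) stop("leave-one-out evaluation needs at least 3 subjects")
    if (length(unique(dm@labels)) < 2L)
        stop("both classes (healthy and symptomatic) must be present")
    ord <- order(dm@subjectIds)
    x <- dm@x[ord, , drop = FALSE]
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
    y <- dm@labels[ord]
    ids <- dm@subjectIds[ord]
    prob <- numeric(n)
    for (i in seq_len(n)) {
        fit <- ranger::ranger(
            x = x[-i, , drop = FALSE],
            y = factor(y[-i], levels = c(0, 1)),
            num.trees = nTrees, probability = TRUE,
            seed = as.integer(seed) + i, num.threads = 1L,
            verbose = FALSE)
        prob[i] <- stats::predict(fit, x[i, , drop = FALSE],
                                  num.threads = 1L)$predictions[1L, "1"]
    }
    predicted <- as.integer(prob > 0.5)
    correct <- as.integer(predicted == y)
    acc <- 100 * mean(correct)
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(nBoot), function(b)
        mean(correct[sample.int(n, n, replace = TRUE)]), numeric(1))
    a <- (1 - level) / 2
    ci <- 100 * as.numeric(stats::quantile(boots, c(a, 1 - a), names = FALSE))
    ci <- c(min(ci[1L], acc), max(ci[2L], acc))
    roc <- .rocFromScores(y, prob)
    new("EvalReport", accuracy = acc, accuracyInterval = ci,
        auc = roc$auc, roc = roc$points,
        predictions = data.frame(subjectId = ids, label = y, prob = prob,
                                 predicted = predicted, correct = correct,
                                 stringsAsFactors = FALSE),
        seed = as.integer(seed), nSubjects = as.integer(n),
        featureSet = dm@featureSet)
}

#' Evaluate several feature sets on the same subjects
#'
#' Runs \code{\link{loocvRandomForest}} on each design-matrix variant
#' (e.g. sparse-PCT latents, PCT latents, clinical only, each with or
#' without clinical covariates) and returns the reports with a ranked
#' summary table. All variants must describe the same subjects with the
#' same labels.
#'
#' @param dmVariants named list of \linkS4class{DesignMatrix} objects.
#' @param nTrees,seed,nBoot passed to \code{\link{loocvRandomForest}}.
#' @return List with \code{reports} (named list of
#'   \linkS4class{EvalReport}) and \code{summary} (data.frame ranked by
#'   accuracy: variant, featureSet, accuracy, lo, hi, auc).
#' @export
compareFeatureSets <- function(dmVariants, nTrees = 1000L, seed = 1L,
                               nBoot = 2000L) {
    stopifnot(is.list(dmVariants), length(dmVariants) >= 1L)
    if (is.null(names(dmVariants)))
        names(dmVariants) <- vapply(dmVariants, featureSet, "")
    ref <- dmVariants[[1L]]
    for (dm in dmVariants[-1L]) {
        o1 <- order(ref@subjectIds); o2 <- order(dm@subjectIds)
        if (!identical(ref@subjectIds[o1], dm@subjectIds[o2]) ||
            !identical(ref@labels[o1], dm@labels[o2]))
            stop("all design-matrix variants must share subjects and labels")
    }
    reports <- lapply(dmVariants, loocvRandomForest, nTrees = nTrees,
                      seed = seed, nBoot = nBoot)
    summary <- data.frame(
        variant = names(reports),
        featureSet = vapply(reports, featureSet, ""),
        accuracy = vapply(reports, accuracy, numeric(1)),
        lo = vapply(reports, function(r) accuracyInterval(r)[1L], numeric(1)),
        hi = vapply(reports, function(r) accuracyInterval(r)[2L], numeric(1)),
        auc = vapply(reports, rocAuc, numeric(1)),
        stringsAsFactors = FALSE)
    summary <- summary[order(summary$accuracy, decreasing = TRUE), ]
    rownames(summary) <- NULL
    list(reports = reports, summary = summary)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
    jsonlite::write_json(list(
        featureSet = featureSet(report),
        accuracy = accuracy(report),
        accuracyInterval = accuracyInterval(report),
        auc = rocAuc(report),
        nSubjects = report@nSubjects,
        seed = report@seed,
        predictions = foldPredictions(report),
        roc = rocPoints(report)), path, auto_unbox = TRUE, digits = NA,
        dataframe = "columns")
    invisible(path)
}
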