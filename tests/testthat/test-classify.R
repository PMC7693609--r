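separableDesign <- function(n = 40, gap = 10, sd = 0.1, seed = 1,
                            featureSet = "latent_only") {
    set.seed(seed)
    lab <- rep(0:1, each = n / 2)
    x <- cbind(f1 = lab * gap + rnorm(n, sd = sd),
               f2 = -lab * gap + rnorm(n, sd = sd))
    new("DesignMatrix", x = x, labels = as.integer(lab),
        subjectIds = sprintf("S%03d", seq_len(n)), featureSet = featureSet)
}

test_that("linearly separated clusters are classified perfectly", {
    r <- loocvRandomForest(separableDesign(), nTrees = 300, seed = 1,
                           nBoot = 500)
    expect_equal(accuracy(r), 100)
    expect_equal(rocAuc(r), 1)
    expect_identical(r@nSubjects, 40L)
    expect_identical(nrow(foldPredictions(r)), 40L)
})

test_that("label permutation collapses accuracy to chance", {
    dm <- separableDesign(seed = 2)
    set.seed(3)
    dm@labels <- sample(dm@labels)
    r <- loocvRandomForest(dm, nTrees = 300, seed = 2, nBoot = 500)
    expect_gte(accuracy(r), 25)     # +/- 3 binomial SD around 50% at n = 40
    expect_lte(accuracy(r), 75)
})

test_that("label-independent clinical covariates stay at chance", {
    set.seed(4)
    lab <- rep(0:1, each = 20)
    cohort <- toyCohort(lab, seed = 4)      # covariates drawn independently
    dm <- buildDesignMatrix(NULL, cohort, featureSet = "clinical_only")
    r <- loocvRandomForest(dm, nTrees = 300, seed = 4, nBoot = 500)
    expect_gte(accuracy(r), 25)
    expect_lte(accuracy(r), 75)
})

test_that("informative covariates add to weak latent features", {
    set.seed(5)
    n <- 40
    lab <- rep(0:1, each = n / 2)
    ## weak latent signal: heavy class overlap
    codes <- matrix(rnorm(n * 4, sd = 1), n, 4) + lab * 0.5
    ## strongly informative age
    cohort <- toyCohort(lab, ages = 45 + lab * 20 + sample(-3:3, n, TRUE))
    dms <- list(
        latent_only = buildDesignMatrix(codes, cohort, "latent_only"),
        latent_plus_clinical =
            buildDesignMatrix(codes, cohort, "latent_plus_clinical"))
    cmp <- compareFeatureSets(dms, nTrees = 300, seed = 5, nBoot = 500)
    accs <- vapply(cmp$reports, accuracy, numeric(1))
    expect_gte(accs[["latent_plus_clinical"]], accs[["latent_only"]])
    expect_identical(nrow(cmp$summary), 2L)
    expect_true(all(cmp$summary$lo <= cmp$summary$accuracy &
                    cmp$summary$accuracy <= cmp$summary$hi))
})

test_that("a single variant reduces to the plain LOOCV report", {
    dm <- separableDesign(n = 20, seed = 6)
    cmp <- compareFeatureSets(list(only = dm), nTrees = 200, seed = 6,
                              nBoot = 300)
    direct <- loocvRandomForest(dm, nTrees = 200, seed = 6, nBoot = 300)
    expect_equal(accuracy(cmp$reports$only), accuracy(direct))
    expect_equal(foldPredictions(cmp$reports$only)$prob,
                 foldPredictions(direct)$prob)
})

test_that("reports are invariant to subject row order", {
    dm <- separableDesign(n = 24, gap = 2, sd = 1, seed = 7)
    set.seed(8)
    perm <- sample(24)
    dmP <- new("DesignMatrix", x = dm@x[perm, ], labels = dm@labels[perm],
               subjectIds = dm@subjectIds[perm], featureSet = "latent_only")
    r1 <- loocvRandomForest(dm, nTrees = 200, seed = 9, nBoot = 300)
    r2 <- loocvRandomForest(dmP, nTrees = 200, seed = 9, nBoot = 300)
    p1 <- foldPredictions(r1); p2 <- foldPredictions(r2)
    expect_identical(p1$subjectId, p2$subjectId)   # canonical order
    expect_equal(p1$prob, p2$prob)
    expect_equal(accuracy(r1), accuracy(r2))
})

test_that("bootstrap intervals contain the point and tighten with n", {
    mk <- function(n, seed) separableDesign(n = n, gap = 1.6, sd = 1,
                                            seed = seed)
    r40 <- loocvRandomForest(mk(40, 10), nTrees = 200, seed = 10,
                             nBoot = 1000)
    r200 <- loocvRandomForest(mk(200, 11), nTrees = 200, seed = 10,
                              nBoot = 1000)
    ci40 <- accuracyInterval(r40); ci200 <- accuracyInterval(r200)
    expect_true(ci40[1] <= accuracy(r40) && accuracy(r40) <= ci40[2])
    expect_true(ci200[1] <= accuracy(r200) && accuracy(r200) <= ci200[2])
    expect_lt(diff(ci200), diff(ci40))
})

test_that("degenerate designs are rejected", {
    dm <- separableDesign(n = 10)
    dm1 <- dm; dm1@labels <- rep(0L, 10)
    expect_error(loocvRandomForest(dm1), "both classes")
    expect_error(loocvRandomForest(separableDesign(n = 2)), "at least 3")
    other <- separableDesign(n = 12, seed = 12)
    expect_error(compareFeatureSets(list(dm, other)),
                 "share subjects and labels")
    expect_error(buildDesignMatrix(matrix(0, 3, 2), toyCohort(rep(0:1, 2))),
                 "do not match")
})
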