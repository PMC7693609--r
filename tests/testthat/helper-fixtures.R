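## Shared fixture builders; everything is generated in code under fixed
## seeds, no binary data.

## Wrap an arbitrary matrix as a HeatMatrix (centering applied), declaring a
## column-vector ROI so decomposition tests can use hand-picked matrices.
toyHeatMatrix <- function(X) {
    rm <- rowMeans(X)
    new("HeatMatrix", X = X - rm, rowMean = rm,
        roi = c(0L, 0L, nrow(X), 1L),
        sourceShape = c(nrow(X), 1L))
}

## Random thermal sequence around a baseline temperature.
randomSequence <- function(tau = 6L, rows = 12L, cols = 12L, seed = 1L,
                           sd = 0.5) {
    set.seed(seed)
    ThermalSequence(array(rnorm(tau * rows * cols, 30, sd),
                          c(tau, rows, cols)))
}

## Two well-separated feature clusters in [0, 1]^width.
twoClusterFeatures <- function(n = 40L, width = 24L, gap = 0.5, sd = 0.04,
                               seed = 1L) {
    set.seed(seed)
    lab <- rep(0:1, length.out = n)
    base <- matrix(runif(width, 0.2, 0.4), n, width, byrow = TRUE)
    x <- base + lab * gap + rnorm(n * width, sd = sd)
    list(x = pmin(pmax(x, 0), 1), labels = lab)
}

## Minimal cohort table for design-matrix tests.
toyCohort <- function(labels, ages = NULL, seed = 1L) {
    set.seed(seed)
    n <- length(labels)
    data.frame(
        subjectId = sprintf("S%03d", seq_len(n)),
        age = if (is.null(ages)) sample(35:80, n, replace = TRUE) else ages,
        familyHistory = sample(c("none", "diabetes", "hypertensive"), n,
                               replace = TRUE, prob = c(0.7, 0.25, 0.05)),
        hormoneTherapy = runif(n) < 0.2,
        label = ifelse(labels == 1, "symptomatic", "healthy"),
        stringsAsFactors = FALSE)
}

## Deterministic (RNG-free) avatar for backbone regression tests.
patternAvatar <- function(side = 224L) {
    i <- matrix(seq_len(side), side, side)
    j <- t(i)
    img <- array(0, c(side, side, 3L))
    img[, , 1L] <- (sin(i / 9) * cos(j / 13) + 1) / 2
    img[, , 2L] <- (sin((i + j) / 17) + 1) / 2
    img[, , 3L] <- ((i + j) %% 29) / 28
    new("Avatar", image = img, side = side,
        channelOrder = c("beta1", "beta2", "beta3"))
}
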