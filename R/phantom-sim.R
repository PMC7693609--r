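#' @include AllClasses.R
NULL

## Neumann (zero-flux) edge replication: ghost cell equals edge cell, so the
## boundary flux difference vanishes identically.
.shiftUp <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
.shiftDown <- function(m) m[c(seq_len(nrow(m) - 1L) + 1L, nrow(m)), , drop = FALSE]
.shiftLeft <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
.shiftRight <- function(m) m[, c(seq_len(ncol(m) - 1L) + 1L, ncol(m)), drop = FALSE]

.asField <- function(value, shape, what) {
    if (is.matrix(value)) {
        if (!identical(dim(value), shape))
            stop("'", what, "' matrix does not match the grid shape")
        value
    } else matrix(value, shape[1L], shape[2L])
}

#' Construct a tissue grid phantom
#'
#' Builds a \linkS4class{TissueGrid} for the 2-d Pennes bioheat equation.
#' Scalars are expanded to per-cell fields. Physical defaults are
#' literature-typical soft-tissue values: density 1050 kg/m^3, specific heat
#' 3600 J/(kg K), conductivity 0.48 W/(m K), blood specific heat
#' 3617 J/(kg K), arterial temperature 37 degC. Metabolic heat defaults to
#' 2e4 W/m^3 inside the breast mask (normal breast tissue) and, when a tumor
#' mask is given, \code{tumorQm} (default 6e5 W/m^3, the midpoint of the
#' 1e5-1.2e6 W/m^3 range reported for cancerous tissue) inside the tumor.
#'
#' @param shape integer(2), grid rows and cols.
#' @param cellSize cell edge in metres (default 2.5 mm).
#' @param rho,cp,k,omegaB,qm scalar or matrix physical fields (see
#'   \linkS4class{TissueGrid} for units). \code{qm = NULL} uses the
#'   breast/tumor defaults above.
#' @param cb,Ta blood specific heat and arterial temperature.
#' @param breastMask logical matrix; default a centred disc of radius
#'   0.4 x min(shape).
#' @param tumorMask logical matrix or NULL.
#' @param tumorQm metabolic heat of tumor cells, W/m^3.
#' @param tumorOmegaFactor multiplier on perfusion inside the tumor
#'   (vasodilation surrogate, default 3).
#' @return A \linkS4class{TissueGrid}.
#' @examples
#' g <- tissueGrid(shape = c(32, 32))
#' g
#' @export
tissueGrid <- function(shape = c(64L, 64L), cellSize = 0.0025,
                       rho = 1050, cp = 3600, k = 0.48, omegaB = 0.5,
                       qm = NULL, cb = 3617, Ta = 37,
                       breastMask = NULL, tumorMask = NULL,
                       tumorQm = 6e5, tumorOmegaFactor = 3) {
    shape <- as.integer(shape)
    if (is.null(breastMask)) breastMask <- discMask(shape)
    breastMask <- .asField(breastMask, shape, "breastMask") > 0
    if (is.null(tumorMask)) tumorMask <- matrix(FALSE, shape[1L], shape[2L])
    tumorMask <- .asField(tumorMask, shape, "tumorMask") > 0
    if (is.null(qm)) {
        qm <- matrix(0, shape[1L], shape[2L])
        qm[breastMask] <- 2e4
        qm[tumorMask] <- tumorQm
    }
    omegaB <- .asField(omegaB, shape, "omegaB")
    omegaB[tumorMask] <- omegaB[tumorMask] * tumorOmegaFactor
    new("TissueGrid", cellSize = cellSize,
        rho = .asField(rho, shape, "rho"), cp = .asField(cp, shape, "cp"),
        k = .asField(k, shape, "k"), omegaB = omegaB,
        qm = .asField(qm, shape, "qm"), cb = cb, Ta = Ta,
        breastMask = breastMask, tumorMask = tumorMask)
}

#' Disc mask helper
#'
#' @param shape integer(2) grid shape.
#' @param center numeric(2) centre (row, col); default grid centre.
#' @param radius disc radius in cells; default 0.4 x min(shape).
#' @return A logical matrix.
#' @export
discMask <- function(shape, center = (shape + 1) / 2,
                     radius = 0.4 * min(shape)) {
    r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    (r - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

#' Largest stable explicit time step for a tissue grid
#'
#' The forward-Euler 5-point scheme is stable for
#' \code{dt <= min(rho * cp * h^2 / (4 k))} over cells (conduction) and
#' \code{dt <= min(rho * cp / (omegaB * cb))} (perfusion relaxation); the
#' smaller bound is returned.
#'
#' @param grid a \linkS4class{TissueGrid}.
#' @return Maximal admissible \code{dt} in seconds.
#' @export
maxStableDt <- function(grid) {
    rc <- grid@rho * grid@cp
    dtc <- Inf
    if (any(grid@k > 0))
        dtc <- min((rc * grid@cellSize^2 / (4 * grid@k))[grid@k > 0])
    dtp <- Inf
    if (any(grid@omegaB > 0))
        dtp <- min((rc / (grid@omegaB * grid@cb))[grid@omegaB > 0])
    min(dtc, dtp)
}

## Conduction term in W/m^3: face conductivities are arithmetic means of the
## adjacent cells, edges replicated (insulated boundary).
.conduction <- function(temp, k, h2) {
    up <- .shiftUp(temp); dn <- .shiftDown(temp)
    lf <- .shiftLeft(temp); rt <- .shiftRight(temp)
    ku <- (k + .shiftUp(k)) / 2; kd <- (k + .shiftDown(k)) / 2
    kl <- (k + .shiftLeft(k)) / 2; kr <- (k + .shiftRight(k)) / 2
    (ku * (up - temp) + kd * (dn - temp) +
     kl * (lf - temp) + kr * (rt - temp)) / h2
}

#' Simulate the Pennes bioheat equation on a tissue grid
#'
#' Integrates \code{rho cp dT/dt = div(k grad T) + omegaB cb (Ta - T) + qm}
#' by explicit forward Euler with a 5-point Laplacian and insulated
#' (zero-flux) boundaries, recording the 2-d temperature field every
#' \code{frameInterval} seconds. The grid is the observed skin plane.
#'
#' @param grid a \linkS4class{TissueGrid}.
#' @param T0 initial temperature: scalar or matrix, degrees Celsius
#'   (default 30, a post-acclimatization surrogate).
#' @param nFrames number of frames to record (default 23).
#' @param frameInterval seconds between recorded frames (default 15).
#' @param dt integration step in seconds; default
#'   \code{0.5 * maxStableDt(grid)} rounded down so an integer number of
#'   steps fits in one frame interval.
#' @param noiseSigma s.d. of Gaussian sensor noise added per pixel per frame
#'   (degC, default 0: noise-free physics).
#' @param subjectId,label metadata passed to the result.
#' @return A \linkS4class{ThermalSequence} of \code{nFrames} frames.
#' @examples
#' g <- tissueGrid(shape = c(24, 24), k = 0, omegaB = 0, qm = 0)
#' ts <- simulatePennes(g, T0 = 32, nFrames = 3)
#' max(abs(frames(ts) - 32))   # conserved: no sources, no fluxes
#' @export
simulatePennes <- function(grid, T0 = 30, nFrames = 23L, frameInterval = 15,
                           dt = NULL, noiseSigma = 0,
                           subjectId = "phantom", label = "unknown") {
    stopifnot(is(grid, "TissueGrid"), nFrames >= 1L, frameInterval > 0)
    shape <- dim(grid@rho)
    temp <- .asField(T0, shape, "T0")
    if (!all(is.finite(temp))) stop("initial field 'T0' must be finite")
    dtMax <- maxStableDt(grid)
    if (is.null(dt)) {
        dt <- if (is.finite(dtMax)) 0.5 * dtMax else frameInterval
        dt <- frameInterval / ceiling(frameInterval / dt)
    }
    if (dt > dtMax * (1 + 1e-12))
        stop(sprintf(
            "explicit scheme unstable: dt = %g s exceeds the maximal admissible dt = %g s",
            dt, dtMax))
    nSub <- max(1L, as.integer(round(frameInterval / dt)))
    dt <- frameInterval / nSub
    rc <- grid@rho * grid@cp
    h2 <- grid@cellSize^2
    hasK <- any(grid@k > 0)
    out <- array(NA_real_, c(nFrames, shape[1L], shape[2L]))
    for (f in seq_len(nFrames)) {
        for (s in seq_len(nSub)) {
            src <- grid@omegaB * grid@cb * (grid@Ta - temp) + grid@qm
            if (hasK) src <- src + .conduction(temp, grid@k, h2)
            temp <- temp + dt * src / rc
        }
        out[f, , ] <- temp
    }
    if (!all(is.finite(out)))
        stop("simulation produced non-finite temperatures; reduce dt")
    if (noiseSigma > 0)
        out <- out + stats::rnorm(length(out), sd = noiseSigma)
    ThermalSequence(out, frameInterval = frameInterval,
                    subjectId = subjectId, label = label,
                    noiseSigma = noiseSigma)
}

.sampleFamilyHistory <- function(n) {
    sample(c("none", "diabetes", "hypertensive", "leukemia"), n,
           replace = TRUE, prob = c(0.721, 0.250, 0.024, 0.005))
}

#' Generate a labeled synthetic thermal cohort
#'
#' Simulates \code{nHealthy + nSymptomatic} subjects on per-subject tissue
#' grids. Symptomatic subjects receive a randomly placed tumor disc with
#' metabolic heat generation drawn uniformly from 1e5-1.2e6 W/m^3 and
#' locally elevated perfusion (a vasodilation surrogate); all subjects get
#' mild baseline variability (initial temperature, perfusion) and Gaussian
#' sensor noise (default s.d. 0.04 degC, the sensitivity of the reference
#' camera). Clinical covariates are sampled to match the screening cohort's
#' demographics: age centred on 60, family history of diabetes 25%,
#' hypertension 2.4%, leukemia 0.5%, hormone replacement therapy 18.3%.
#' Covariates are label-independent unless \code{ageShift != 0}, which adds
#' that many years to symptomatic subjects (for additive-information
#' experiments).
#'
#' @param nHealthy,nSymptomatic subject counts (>= 0).
#' @param seed integer RNG seed; the same arguments and seed reproduce the
#'   cohort exactly.
#' @param shape grid shape (default 64 x 64; use c(480, 640) to mimic the
#'   camera resolution).
#' @param nFrames,frameInterval acquisition protocol (defaults 23 frames
#'   every 15 s).
#' @param noiseSigma sensor noise s.d. in degC (default 0.04).
#' @param tumorQmRange range of tumor metabolic heat, W/m^3.
#' @param tumorRadiusRange tumor disc radius range as a fraction of
#'   min(shape) (default 0.05-0.11).
#' @param tumorOmegaFactor perfusion multiplier inside the tumor (default 3).
#' @param ageShift years added to symptomatic ages (default 0: covariates
#'   carry no label information).
#' @return A list with \code{sequences} (list of
#'   \linkS4class{ThermalSequence}) and \code{cohort} (data.frame with
#'   subjectId, age, familyHistory, hormoneTherapy, label).
#' @examples
#' co <- generateCohort(2, 2, seed = 7, shape = c(24, 24), nFrames = 4)
#' co$cohort
#' @export
generateCohort <- function(nHealthy, nSymptomatic, seed = 1L,
                           shape = c(64L, 64L), nFrames = 23L,
                           frameInterval = 15, noiseSigma = 0.04,
                           tumorQmRange = c(1e5, 1.2e6),
                           tumorRadiusRange = c(0.05, 0.11),
                           tumorOmegaFactor = 3, ageShift = 0) {
    stopifnot(nHealthy >= 0, nSymptomatic >= 0)
    set.seed(as.integer(seed))
    shape <- as.integer(shape)
    n <- nHealthy + nSymptomatic
    labels <- c(rep("healthy", nHealthy), rep("symptomatic", nSymptomatic))
    ids <- sprintf("S%03d", seq_len(max(n, 1L)))[seq_len(n)]
    breastR <- 0.4 * min(shape)
    center <- (shape + 1) / 2
    sequences <- vector("list", n)
    ages <- integer(n)
    for (i in seq_len(n)) {
        tumorMask <- NULL
        if (labels[i] == "symptomatic") {
            tr <- stats::runif(1, tumorRadiusRange[1L],
                               tumorRadiusRange[2L]) * min(shape)
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- sqrt(stats::runif(1)) * max(breastR - tr - 1, 1)
            tcen <- center + rad * c(cos(ang), sin(ang))
            tumorMask <- discMask(shape, center = tcen, radius = tr) &
                discMask(shape, center = center, radius = breastR)
            tumorQm <- stats::runif(1, tumorQmRange[1L], tumorQmRange[2L])
        } else tumorQm <- 0
        grid <- tissueGrid(shape = shape,
                           omegaB = max(0.1, stats::rnorm(1, 0.5, 0.05)),
                           qm = NULL,
                           breastMask = discMask(shape, center, breastR),
                           tumorMask = tumorMask, tumorQm = tumorQm,
                           tumorOmegaFactor = tumorOmegaFactor)
        t0 <- stats::rnorm(1, 30, 0.3)
        sequences[[i]] <- simulatePennes(grid, T0 = t0, nFrames = nFrames,
                                         frameInterval = frameInterval,
                                         noiseSigma = noiseSigma,
                                         subjectId = ids[i],
                                         label = labels[i])
        ages[i] <- as.integer(round(min(120, max(
            18, stats::rnorm(1, 60, 15) +
                if (labels[i] == "symptomatic") ageShift else 0))))
    }
    cohort <- data.frame(
        subjectId = ids,
        age = ages,
        familyHistory = if (n) .sampleFamilyHistory(n) else character(),
        hormoneTherapy = if (n) stats::runif(n) < 0.183 else logical(),
        label = labels,
        stringsAsFactors = FALSE)
    list(sequences = sequences, cohort = cohort)
}
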