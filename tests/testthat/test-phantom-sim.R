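test_that("zero-source insulated phantom is exactly stationary", {
    g <- tissueGrid(shape = c(24, 24), k = 0.48, omegaB = 0, qm = 0)
    ts <- simulatePennes(g, T0 = 32, nFrames = 5)
    expect_lt(max(abs(frames(ts) - 32)), 1e-10)
})

test_that("insulated zero-source phantom conserves thermal energy", {
    set.seed(11)
    shape <- c(16L, 16L)
    g <- tissueGrid(shape = shape, k = 0.48, omegaB = 0, qm = 0,
                    breastMask = matrix(TRUE, 16, 16))
    T0 <- matrix(rnorm(256, 31, 1.5), 16, 16)
    dt <- 0.4 * maxStableDt(g)
    ## 10 frames x 100 substeps = 1000 explicit steps
    ts <- simulatePennes(g, T0 = T0, nFrames = 10, frameInterval = 100 * dt,
                         dt = dt)
    e0 <- sum(T0)                         # uniform rho*cp: energy ~ sum(T)
    e1 <- sum(frames(ts)[10, , ])
    expect_lt(abs(e1 - e0) / abs(e0), 1e-8)
    ## diffusion did something: the field is no longer the initial one
    expect_gt(max(abs(frames(ts)[10, , ] - T0)), 0.01)
})

test_that("perfusion-only phantom follows the analytic exponential", {
    g <- tissueGrid(shape = c(8, 8), k = 0, omegaB = 0.5, qm = 0,
                    breastMask = matrix(TRUE, 8, 8))
    tau <- 1050 * 3600 / (0.5 * 3617)     # relaxation time rho*cp/(omega*cb)
    tt <- (1:4) * 15
    closed <- 37 + (30 - 37) * exp(-tt / tau)
    ts <- simulatePennes(g, T0 = 30, nFrames = 4, frameInterval = 15,
                         dt = 0.01)
    expect_lt(max(abs(frames(ts)[, 1, 1] - closed)), 1e-6)

    ## explicit Euler is first order: halving dt roughly halves the error
    errAt <- function(dt) {
        s <- simulatePennes(g, T0 = 30, nFrames = 2, frameInterval = 15,
                            dt = dt)
        abs(frames(s)[2, 1, 1] - closed[2])
    }
    ratio <- errAt(0.5) / errAt(0.25)
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 2.5)
})

test_that("tumor heat source can only raise steady-state temperatures", {
    shape <- c(32L, 32L)
    tmask <- discMask(shape, center = c(12, 20), radius = 3)
    base <- tissueGrid(shape = shape)
    withTumor <- tissueGrid(shape = shape, tumorMask = tmask,
                            tumorQm = 6e5, tumorOmegaFactor = 1)
    ## long horizon approaches steady state
    fB <- frames(simulatePennes(base, nFrames = 3, frameInterval = 2000))
    fT <- frames(simulatePennes(withTumor, nFrames = 3,
                                frameInterval = 2000))
    expect_true(all(fT[3, , ] >= fB[3, , ] - 1e-9))
    ## and the tumor footprint is hotter than its contralateral mirror
    mirror <- tmask[, rev(seq_len(shape[2L]))]
    expect_gt(mean(fT[3, , ][tmask]), mean(fT[3, , ][mirror]))
})

test_that("stability violations and bad physics are rejected clearly", {
    g <- tissueGrid(shape = c(16, 16))
    expect_error(simulatePennes(g, dt = 10 * maxStableDt(g)),
                 "maximal admissible dt")
    expect_error(tissueGrid(shape = c(8, 8), rho = -1),
                 "strictly positive")
    expect_error(simulatePennes(g, T0 = NaN), "finite")
    tm <- matrix(FALSE, 8, 8); tm[1, 1] <- TRUE   # outside the breast disc
    expect_error(tissueGrid(shape = c(8, 8), tumorMask = tm),
                 "subset of breastMask")
})

test_that("cohort generation is deterministic and correctly labeled", {
    a <- generateCohort(2, 3, seed = 42, shape = c(24, 24), nFrames = 4)
    b <- generateCohort(2, 3, seed = 42, shape = c(24, 24), nFrames = 4)
    expect_identical(lapply(a$sequences, frames),
                     lapply(b$sequences, frames))
    expect_identical(a$cohort, b$cohort)
    expect_identical(a$cohort$label,
                     c("healthy", "healthy", rep("symptomatic", 3)))
    expect_true(all(a$cohort$age >= 18 & a$cohort$age <= 120))

    empty <- generateCohort(0, 0, seed = 1)
    expect_length(empty$sequences, 0)
    expect_identical(nrow(empty$cohort), 0L)
})

test_that("symptomatic subjects show more temporal variance in the breast", {
    co <- generateCohort(40, 40, seed = 1, shape = c(64, 64), nFrames = 23)
    mask <- discMask(c(64L, 64L))
    tvar <- vapply(co$sequences, function(sq) {
        fr <- frames(sq)
        v <- apply(fr, c(2, 3), var)
        mean(v[mask])
    }, numeric(1))
    lab <- co$cohort$label
    expect_gt(mean(tvar[lab == "symptomatic"]), mean(tvar[lab == "healthy"]))
})
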