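test_that("binary and text dialects round-trip losslessly", {
    sq <- randomSequence(tau = 4, rows = 9, cols = 7, seed = 3)
    for (dialect in c("bin", "txt_matrix")) {
        d <- withr::local_tempdir()
        writeSequence(sq, d, dialect = dialect)
        back <- readSequence(d)
        expect_identical(dim(frames(back)), dim(frames(sq)))
        expect_equal(frames(back), frames(sq), tolerance = 0)
        expect_equal(frameInterval(back), frameInterval(sq))
        expect_identical(subjectId(back), subjectId(sq))
    }
})

test_that("quantized image dialects round-trip within their resolution", {
    sq <- randomSequence(tau = 3, rows = 8, cols = 8, seed = 5, sd = 2)
    rng <- diff(range(frames(sq)))
    steps <- c(tiff = 65535, png_stack = 255)   # 16-bit vs 8-bit storage
    for (dialect in names(steps)) {
        d <- withr::local_tempdir()
        writeSequence(sq, d, dialect = dialect)
        back <- readSequence(d)
        expect_lt(max(abs(frames(back) - frames(sq))),
                  rng / steps[[dialect]] + 1e-9)
    }
})

test_that("frames are ordered by their numeric filename index", {
    d <- withr::local_tempdir()
    for (i in c(2, 10, 1))
        write.table(matrix(i, 3, 3), file.path(d, sprintf("frame_%d.txt", i)),
                    row.names = FALSE, col.names = FALSE)
    sq <- readSequence(d, dialect = "txt_matrix")
    expect_equal(frames(sq)[, 1, 1], c(1, 2, 10))
})

test_that("mixed frame shapes raise an error naming both shapes", {
    d <- withr::local_tempdir()
    write.table(matrix(1, 3, 3), file.path(d, "frame_1.txt"),
                row.names = FALSE, col.names = FALSE)
    write.table(matrix(1, 4, 3), file.path(d, "frame_2.txt"),
                row.names = FALSE, col.names = FALSE)
    expect_error(readSequence(d), "4x3.*3x3|3x3.*4x3")
    expect_error(readSequence(file.path(d, "nope")), "no such directory")
})

test_that("heat matrix columns are centred row-major ROI vectorizations", {
    ## 3-pixel column ROI over 2 frames: means removed per pixel
    fr <- array(0, c(2, 3, 1))
    fr[1, , 1] <- c(1, 3, 5)
    fr[2, , 1] <- c(3, 5, 7)
    sq <- ThermalSequence(fr)
    hm <- buildHeatMatrix(sq, roi = c(0, 0, 3, 1))
    expect_equal(hm@rowMean, c(2, 4, 6))
    expect_equal(heatValues(hm),
                 matrix(c(-1, -1, -1, 1, 1, 1), 3, 2), tolerance = 1e-12)

    ## constant sequence centres to the zero matrix
    cs <- ThermalSequence(array(31.5, c(3, 5, 5)))
    expect_equal(max(abs(heatValues(buildHeatMatrix(cs, c(0, 0, 5, 4))))), 0)

    ## row-major order: reshaping a column recovers the ROI frame
    sq2 <- randomSequence(tau = 3, rows = 6, cols = 8, seed = 8)
    roi <- c(1L, 2L, 4L, 5L)
    hm2 <- buildHeatMatrix(sq2, roi)
    for (j in 1:3)
        expect_equal(roiFrame(hm2, j),
                     frames(sq2)[j, 2:5, 3:7], tolerance = 1e-12)
    expect_equal(uncenteredMatrix(hm2)[, 2],
                 as.vector(t(frames(sq2)[2, 2:5, 3:7])), tolerance = 1e-12)
})

test_that("economy shape p > n and ROI bounds are enforced", {
    sq <- randomSequence(tau = 10, rows = 6, cols = 6)
    expect_error(buildHeatMatrix(sq, roi = c(0, 0, 3, 3)), "p > n")
    expect_error(buildHeatMatrix(sq, roi = c(0, 0, 7, 6)), "bounds")
    ## phantom-sized case: 48x48 ROI of a 64x64 sequence, 23 frames
    big <- ThermalSequence(array(rnorm(23 * 64 * 64, 30), c(23, 64, 64)))
    hm <- buildHeatMatrix(big)
    expect_identical(dim(heatValues(hm)), c(2304L, 23L))
    expect_lt(max(abs(rowMeans(heatValues(hm)))), 1e-9)
})

test_that("ROI tables are read and validated", {
    d <- withr::local_tempdir()
    f <- file.path(d, "roi.csv")
    write.csv(data.frame(subjectId = "S001", row0 = 1, col0 = 2,
                         height = 10, width = 11), f, row.names = FALSE)
    tab <- readRoiTable(f)
    expect_equal(tab$height, 10)
    write.csv(data.frame(id = "S001"), f, row.names = FALSE)
    expect_error(readRoiTable(f), "columns")
})
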