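test_that("the second-order all-pass has unit magnitude and the stated poles", {
    omega <- seq(0, pi, length.out = 512)
    for (R in c(0.3, 0.9, 0.992)) {
        ap <- designAllpass(R, 2 * pi / 3)
        expect_equal(Mod(filterResponse(ap, omega)), rep(1, 512),
                     tolerance = 1e-10)
    }
    ap <- designAllpass(0.99, 2 * pi / 3)
    poles <- polyroot(rev(ap@a))
    expect_equal(sort(Mod(poles)), rep(0.99, 2), tolerance = 1e-9)
    expect_equal(sort(abs(Arg(poles))), rep(2 * pi / 3, 2),
                 tolerance = 1e-9)
    ## R -> 0 limit is a pure two-sample delay
    tiny <- designAllpass(1e-9, 2 * pi / 3)
    w <- c(0.3, 1.1, 2.5)
    expect_equal(filterResponse(tiny, w), exp(-2i * w), tolerance = 1e-6)
    expect_error(designAllpass(1, 2 * pi / 3), "stability")
    expect_error(designAllpass(0.5, pi), "omega0")
})

test_that("notch and anti-notch are complementary around 2*pi/3", {
    d <- designFilter1(R = 0.992)
    w0 <- 2 * pi / 3
    expect_lt(Mod(filterResponse(d$notch, w0)), 1e-10)
    expect_equal(Mod(filterResponse(d$antinotch, w0)), 1,
                 tolerance = 1e-10)
    expect_equal(Mod(filterResponse(d$notch, 0)), 1, tolerance = 1e-9)
    expect_equal(Mod(filterResponse(d$antinotch, 0)), 0, tolerance = 1e-9)
    grid <- seq(0, pi, length.out = 1024)
    expect_equal(Mod(filterResponse(d$notch, grid))^2 +
                 Mod(filterResponse(d$antinotch, grid))^2,
                 rep(1, 1024), tolerance = 1e-9)
})

test_that("both narrowband designs peak at the period-3 frequency", {
    grid <- seq(0, pi, length.out = 4096)
    step <- grid[2] - grid[1]
    for (design in list(designFilter1()$antinotch, designFilter2())) {
        mag <- Mod(filterResponse(design, grid))
        expect_lt(abs(grid[which.max(mag)] - 2 * pi / 3), step + 1e-12)
    }
})

test_that("the peaking design has unit peak gain and bandwidth-controlled skirts", {
    d <- designFilter2(bandwidth = 0.02 * pi)
    expect_equal(Mod(filterResponse(d, 2 * pi / 3)), 1, tolerance = 1e-10)
    ## the gap between the two -3 dB crossings is the design bandwidth
    bw <- 0.02 * pi
    f <- function(w) Mod(filterResponse(d, w))^2 - 0.5
    lo <- uniroot(f, c(2 * pi / 3 - 5 * bw, 2 * pi / 3), tol = 1e-12)$root
    hi <- uniroot(f, c(2 * pi / 3, 2 * pi / 3 + 5 * bw), tol = 1e-12)$root
    expect_equal(hi - lo, bw, tolerance = 1e-6)
    ## narrower bandwidth attenuates the stop band more
    wide <- Mod(filterResponse(designFilter2(0.05 * pi), pi / 3))
    narrow <- Mod(filterResponse(designFilter2(0.01 * pi), pi / 3))
    expect_lt(narrow, wide)
    expect_error(designFilter2(0), "bandwidth")
    ## independent check of the coefficient response route
    grid <- c(0.5, 2 * pi / 3, 3)
    expect_equal(Mod(filterResponse(d, grid)),
                 naiveMagnitude(d@b, d@a, grid), tolerance = 1e-12)
})

test_that("causal filtering is linear, energy-consistent and length preserving", {
    d <- designFilter1()$antinotch
    expect_identical(applyFilter(d, rep(0, 100)), rep(0, 100))
    x <- rnorm(50)
    expect_length(applyFilter(d, x), 50L)
    ## an all-pass preserves impulse energy (Parseval)
    ap <- designAllpass(0.992, 2 * pi / 3)
    h <- applyFilter(ap, c(1, rep(0, 9999)))
    expect_equal(sum(h^2), 1, tolerance = 1e-6)
    ## period-3 drive excites the passband far more than period-2
    n <- 0:1999
    y3 <- applyFilter(d, cos(2 * pi * n / 3))
    y2 <- applyFilter(d, cos(pi * n))
    expect_gt(sum(y3^2), 50 * sum(y2^2))
})

test_that("four-channel track reflects steady-state responses", {
    d <- designFilter1(R = 0.97)$antinotch
    allA <- binaryIndicators(dnaRegion(strrep("A", 2000)))
    yA <- trackValues(fourChannelTrack(allA, d))
    expect_lt(max(tail(yA, 200)), 1e-6)          # DC is in the notch
    rep3 <- binaryIndicators(dnaRegion(strrep("ACG", 700)))
    y3 <- trackValues(fourChannelTrack(rep3, d))
    tailVals <- tail(y3, 600)
    expect_gt(min(smoothTail <- vapply(seq_len(500), function(i)
        mean(tailVals[i:(i + 100)]), numeric(1))), 0.1)
    expect_true(all(y3 >= 0))
    set.seed(14)
    rnd <- binaryIndicators(dnaRegion(randomDnaString(500)))
    expect_true(all(trackValues(fourChannelTrack(rnd, d)) >= 0))
})

test_that("reduced track is the single-channel specialisation", {
    set.seed(15)
    ind <- binaryIndicators(dnaRegion(randomDnaString(600)))
    d <- designFilter2()
    gOnly <- combinedSequence(ind, c(A = 0, C = 0, G = 1, T = 0))
    yG <- applyFilter(d, indicator(ind, "G"))
    expect_equal(trackValues(reducedTrack(gOnly, d)), yG^2,
                 tolerance = 1e-12)
    ## zero weights give a zero track; scaling weights scales power by c^2
    zero <- combinedSequence(ind, c(A = 0, C = 0, G = 0, T = 0))
    expect_identical(max(trackValues(reducedTrack(zero, d))), 0)
    sc <- combinedSequence(ind, c(A = 0, C = 0, G = 3, T = 0))
    expect_equal(trackValues(reducedTrack(sc, d)),
                 9 * trackValues(reducedTrack(gOnly, d)),
                 tolerance = 1e-9)
    ## four-channel power is the sum of the per-base reduced tracks
    perBase <- lapply(c("A", "C", "G", "T"), function(b) {
        w <- c(A = 0, C = 0, G = 0, T = 0); w[b] <- 1
        trackValues(reducedTrack(combinedSequence(ind, w), d))
    })
    expect_equal(trackValues(fourChannelTrack(ind, d)),
                 Reduce(`+`, perBase), tolerance = 1e-9)
})

test_that("planted exons carry more filter output power than background", {
    spec <- synthSpec(3000, data.frame(start = c(1001, 2001),
                                       end = c(1400, 2400)), seed = 21)
    g <- generateGenome(spec)
    ind <- binaryIndicators(g$region)
    inside <- c(1001:1400, 2001:2400)
    for (d in list(designFilter1()$antinotch, designFilter2())) {
        y <- trackValues(fourChannelTrack(ind, d))
        expect_gt(mean(y[inside]), mean(y[-inside]))
    }
})

test_that("filter designs export as coefficient JSON", {
    path <- withr::local_tempfile(fileext = ".json")
    d <- designFilter2(0.03 * pi)
    writeFilterJSON(d, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(back$b, d@b)
    expect_equal(back$a, d@a)
    expect_equal(back$center_frequency, 2 * pi / 3)
    expect_equal(back$params$bandwidth, 0.03 * pi)
})
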