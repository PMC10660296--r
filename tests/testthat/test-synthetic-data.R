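test_that("named regimes fix the experimental design", {
    cfg <- experimentConfig("steady_state", seed = 1)
    expect_equal(cfg$T, 100L)
    expect_equal(cfg$nTraj, 40L)
    cfg4 <- experimentConfig("short", seed = 1)
    expect_equal(cfg4$T, 50L)
    expect_equal(cfg4$nTraj, 40L)
    expect_error(experimentConfig("steady_state", T = 60), "custom")
    expect_error(experimentConfig("custom", nTraj = 5), "explicit")
})

test_that("generated datasets have the declared shape", {
    ds <- generateDataset(experimentConfig("custom", nTraj = 3, T = 25,
                                           seed = 4))
    expect_s4_class(ds$observations, "ObservationSet")
    expect_equal(length(ds$observations@data), 3L)
    expect_equal(dim(ds$observations@data[[1L]]), c(1L, 26L))
    expect_equal(ds$observations@species, "Y")
    expect_equal(length(ds$trajectories), 3L)
    expect_equal(dim(ds$counts[[1L]]), c(4L, 25L))
})

test_that("ground truth is chi-consistent and noise-free where unobserved", {
    ds <- generateDataset(experimentConfig("custom", nTraj = 4, T = 40,
                                           seed = 12))
    for (i in 1:4) {
        expect_true(chiConsistent(ds$net, ds$counts[[i]],
                                  ds$trajectories[[i]]))
        expect_true(is.integer(ds$trajectories[[i]]))
    }
    ## observations differ from the truth only by noise on Y
    resid <- ds$observations@data[[1L]][1L, ] -
        ds$trajectories[[1L]]["Y", ]
    expect_gt(sd(resid), 1)
})

test_that("observation noise has the state-dependent variance", {
    ## at Y = 0 the noise variance is sigmaE
    set.seed(99)
    draws <- rnorm(1e4, 0, sqrt(0 + 10))
    expect_equal(var(draws), 10, tolerance = 0.45)
    ## generator reproduces it: early time points have Y = 0
    ds <- generateDataset(experimentConfig("custom", nTraj = 200, T = 2,
                                           seed = 31))
    y0 <- vapply(ds$observations@data, function(m) m[1L, 1L], 0)
    expect_equal(var(y0), 10, tolerance = 1.5)
    expect_equal(mean(y0), 0, tolerance = 3 * sqrt(10 / 200))
})

test_that("scaling production and Michaelis constant together is invisible", {
    cfg <- experimentConfig("custom", nTraj = 40, T = 60, seed = 1)
    pair <- degeneracyDataset(2, cfg)
    expect_equal(parameterValues(pair$scaled$net)[["AX"]], 20)
    expect_equal(parameterValues(pair$scaled$net)[["KM"]], 200)
    A <- vapply(pair$base$observations@data, function(m) m[1L, ],
                numeric(61))
    B <- vapply(pair$scaled$observations@data, function(m) m[1L, ],
                numeric(61))
    se <- sqrt(apply(A, 1L, var) / 40 + apply(B, 1L, var) / 40)
    z <- (rowMeans(A) - rowMeans(B)) / pmax(se, 1e-9)
    expect_true(all(abs(z) < 3))
    ## identical scale factor 1 gives bit-identical data
    same <- degeneracyDataset(1, experimentConfig("custom", nTraj = 2,
                                                  T = 20, seed = 7))
    expect_identical(same$base$observations@data,
                     same$scaled$observations@data)
})

test_that("only the sum of the two delays shapes the data", {
    ## Gamma(3.6,.6)+Gamma(3.6,.6) and Gamma(1.2,.6)+Gamma(6,.6) have
    ## exactly the same summed distribution (equal rates)
    dEven <- gammaSumDelay(c(3.6, 3.6), c(0.6, 0.6))
    dUneven <- gammaSumDelay(c(1.2, 6.0), c(0.6, 0.6))
    tt <- seq(0.5, 40, length.out = 50)
    expect_lt(max(abs(delayCDF(dEven, tt) - delayCDF(dUneven, tt))), 2e-6)
    ## and the paired datasets agree within Monte-Carlo error
    pair <- delaySplitDataset(experimentConfig("custom", nTraj = 30,
                                               T = 60, seed = 44))
    A <- vapply(pair$even$observations@data, function(m) m[1L, ],
                numeric(61))
    B <- vapply(pair$uneven$observations@data, function(m) m[1L, ],
                numeric(61))
    se <- sqrt(apply(A, 1L, var) / 30 + apply(B, 1L, var) / 30)
    z <- (rowMeans(A) - rowMeans(B)) / pmax(se, 1e-9)
    expect_true(all(abs(z) < 3.5))
})
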