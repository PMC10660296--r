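test_that("delay means follow Gamma component sums", {
    expect_equal(delayMean(gammaDelay(18 / 5, 3 / 5)), 6)
    expect_equal(delayMean(noDelay()), 0)
    expect_equal(delayMean(gammaSumDelay(c(3.6, 3.6), c(0.6, 0.6))), 12)
    expect_equal(delayMean(gammaSumDelay(c(1.2, 6.0), c(0.6, 0.6))), 12)
})

test_that("delay distributions validate their parameters", {
    expect_error(gammaDelay(-1, 2), "shapes and rates")
    expect_error(gammaDelay(2, 0), "shapes and rates")
    expect_error(gammaSumDelay(c(1, 2), c(1, -3)), "shapes and rates")
})

test_that("delay CDF handles the degenerate and exponential cases", {
    expect_equal(delayCDF(noDelay(), 5), 1)
    expect_equal(delayCDF(noDelay(), 0), 1)
    expect_equal(delayCDF(noDelay(), -1), 0)
    expect_equal(delayCDF(gammaDelay(1, 0.5), 2), 1 - exp(-1),
                 tolerance = 1e-9)
    expect_equal(delayCDF(gammaDelay(3, 2), -0.5), 0)
})

test_that("numerical convolution CDF matches closed-form Gamma sums", {
    ## equal-rate Gammas add shapes: Gamma(2,1) + Gamma(3,1) = Gamma(5,1)
    d <- gammaSumDelay(c(2, 3), c(1, 1))
    tt <- seq(0.05, 20, length.out = 100)
    expect_lt(max(abs(delayCDF(d, tt) - pgamma(tt, 5, 1))), 1e-6)
    expect_equal(delayCDF(d, 4), pgamma(4, 5, 1), tolerance = 1e-6)
    ## CDF is nondecreasing with limits 0 and 1
    expect_true(all(diff(delayCDF(d, tt)) >= -1e-12))
    expect_equal(delayCDF(d, 1e4), 1, tolerance = 1e-7)
})

test_that("lag weights reduce to the trapezoid rule without delay", {
    expect_equal(delayWeights(noDelay()), c(0.5, 0.5))
})

test_that("lag weights are a probability-weighted interpolation kernel", {
    for (d in list(gammaDelay(3.6, 0.6), gammaDelay(2, 1),
                   gammaSumDelay(c(3.6, 3.6), c(0.6, 0.6)))) {
        w <- delayWeights(d)
        expect_true(all(w >= 0))
        expect_equal(sum(w), 1, tolerance = 1e-10)
        ## the mean lag of the kernel is the mean delay shifted by the
        ## half-interval of the interpolation
        expect_equal(sum((seq_along(w) - 1) * w), delayMean(d) + 0.5,
                     tolerance = 1e-3)
    }
})

test_that("combineDelays concatenates Gamma components", {
    d <- combineDelays(gammaDelay(3.6, 0.6), gammaDelay(3.6, 0.6))
    expect_s4_class(d, "DelayDistribution")
    expect_equal(d@family, "sum_of_gammas")
    expect_equal(delayMean(d), 12)
    expect_equal(combineDelays(noDelay(), noDelay())@family, "dirac_zero")
    expect_equal(combineDelays(noDelay(), gammaDelay(2, 1))@family, "gamma")
})

test_that("sampled delays match their distribution", {
    set.seed(11)
    x <- sampleDelay(gammaSumDelay(c(2, 3), c(1, 1)), 4000)
    expect_equal(mean(x), 5, tolerance = 0.1)
    expect_equal(sampleDelay(noDelay(), 3), c(0, 0, 0))
})
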