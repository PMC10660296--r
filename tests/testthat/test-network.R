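test_that("the two-step activation model has the canonical structure", {
    net <- twoStepFig()
    expect_s4_class(net, "DelayedNetwork")
    expect_equal(speciesNames(net), c("X", "Y"))
    expect_equal(observedSpecies(net), "Y")
    expect_equal(length(reactions(net)), 4L)
    expect_equal(unname(initialState(net)), c(0L, 0L))
    ## reporter production carries the summed regulation + maturation delay
    d <- realizedDelay(reactions(net)[[3L]], parameters(net))
    expect_equal(d@family, "sum_of_gammas")
    expect_equal(delayMean(d), 12)
    ## activator production and both dilutions are undelayed
    for (k in c(1L, 2L, 4L))
        expect_equal(realizedDelay(reactions(net)[[k]],
                                   parameters(net))@family, "dirac_zero")
    ## dilution is one shared parameter
    expect_equal(reactions(net)[[2L]]@rateLabel,
                 reactions(net)[[4L]]@rateLabel)
})

test_that("propensities evaluate per their functional forms", {
    net <- twoStepFig()
    expect_equal(reactionPropensity(net, "prodY", c(X = 0, Y = 0)), 0)
    expect_equal(reactionPropensity(net, "degX", c(X = 0, Y = 0)), 0)
    expect_equal(reactionPropensity(net, "degX", c(X = 1, Y = 0)), 0.05)
    expect_equal(reactionPropensity(net, "prodX", c(X = 7, Y = 3)), 10)
    expect_equal(reactionPropensity(net, "prodY", c(X = 100, Y = 0)), 30)
})

test_that("Michaelis-Menten propensity is monotone and bounded by AY", {
    net <- twoStepFig()
    x <- 0:5000
    h <- reactionPropensity(net, "prodY",
                            rbind(X = x, Y = integer(length(x))))
    expect_true(all(diff(h) >= 0))
    expect_true(all(h <= 60))
    expect_equal(h[length(h)], 60 * 5000 / 5100)
})

test_that("invalid model parameters are rejected", {
    expect_error(buildTwoStepModel(AX = -1, AY = 60, KM = 100, B = 0.05),
                 "strictly positive")
    expect_error(buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0),
                 "strictly positive")
    expect_error(buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0.05,
                                   x0 = -2), "nonnegative integers")
    expect_error(setParameterValues(twoStepFig(), AX = -5),
                 "strictly positive")
    expect_error(setParameterValues(twoStepFig(), nope = 1), "unknown")
})

test_that("parameter accessors and the free mask behave", {
    net <- twoStepFig()
    expect_equal(parameterValues(net)[["AX"]], 10)
    expect_equal(freeParameters(net), character(0))
    freeParameters(net) <- c("AX", "betaX")
    expect_setequal(freeParameters(net), c("AX", "betaX"))
    net <- setParameterValues(net, AX = 12)
    expect_equal(parameterValues(net)[["AX"]], 12)
    ## fixed entries unaffected by an update of others
    expect_equal(parameterValues(net)[["KM"]], 100)
})

test_that("general networks validate stoichiometry and substrates", {
    expect_error(delayedNetwork(
        species = "Z",
        reactions = list(reaction("r", products = c(W = 1),
                                  form = "constant", rate = 1)),
        observed = "Z"), "unknown species")
    expect_error(delayedNetwork(
        species = "Z",
        reactions = list(reaction("r", reactants = c(Z = -1),
                                  form = "constant", rate = 1)),
        observed = "Z"), "nonnegative")
    expect_error(delayedNetwork(
        species = "Z",
        reactions = list(reaction("r", form = "mass_action_linear",
                                  rate = 1)),
        observed = "Z"), "substrate")
})

test_that("short-form YAML config builds the two-step network", {
    path <- tempfile(fileext = ".yaml")
    writeLines(c("AX: 10", "AY: 60", "KM: 100", "B: 0.05",
                 "tauX: [3.6, 0.6]", "tauY: [3.6, 0.6]",
                 "sigma_e: 10"), path)
    cfg <- readNetworkConfig(path)
    expect_equal(cfg$sigmaE, 10)
    expect_equal(parameterValues(cfg$net)[["AX"]], 10)
    expect_equal(delayMean(realizedDelay(reactions(cfg$net)[[3L]],
                                         parameters(cfg$net))), 12)
    unlink(path)
})
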