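test_that("constant propensity integrates to itself once delay mass is in", {
    ## after the delay support has passed, the completion propensity of
    ## a constant-rate reaction equals the rate
    net <- birthNet(A = 5, delay = gammaDelay(2, 2))  # mean 1 min
    traj <- matrix(0L, 1, 41, dimnames = list("Z", 0:40))
    f <- completionPropensity(net, traj)
    expect_equal(unname(f["birth", 40L]), 5, tolerance = 1e-6)
    ## early intervals carry only the delay mass that fits into [0, i]
    expect_lt(f["birth", 1L], 5)
})

test_that("no-delay completion propensity is the trapezoid rule", {
    net <- delayedNetwork(
        species = "Z",
        reactions = list(reaction("lin", form = "mass_action_linear",
                                  rate = 0.5, substrate = "Z",
                                  products = c(Z = 1))),
        observed = "Z")
    traj <- matrix(c(4L, 8L), 1, dimnames = list("Z", 0:1))
    f <- completionPropensity(net, traj)
    expect_equal(unname(f[1L, 1L]), 0.5 * (4 + 8) / 2)  # = 3
})

test_that("interpolated completion propensity matches brute-force quadrature", {
    ## ramp trajectory, linear propensity, single Gamma delay
    traj <- matrix(0:10, 1, dimnames = list("Z", 0:10))
    net <- delayedNetwork(
        species = "Z",
        reactions = list(reaction("lin", form = "mass_action_linear",
                                  rate = 1, substrate = "Z",
                                  products = c(Z = 1),
                                  delay = gammaDelay(2, 1))),
        observed = "Z")
    f <- completionPropensity(net, traj)
    h <- as.numeric(traj)
    for (i in c(1L, 2L, 3L, 5L, 8L, 10L))
        expect_equal(unname(f[1L, i]), bruteForceFhat(i, h, 2, 1),
                     tolerance = 1e-5)
})

test_that("brute-force agreement holds over random delays and paths", {
    set.seed(42)
    for (rep in 1:3) {
        shape <- runif(1, 1, 6)
        rate <- runif(1, 0.4, 2)
        z <- as.integer(cumsum(sample(0:3, 9, replace = TRUE)))
        traj <- matrix(c(0L, z), 1, dimnames = list("Z", 0:9))
        net <- delayedNetwork(
            species = "Z",
            reactions = list(reaction("lin", form = "mass_action_linear",
                                      rate = 0.7, substrate = "Z",
                                      products = c(Z = 1),
                                      delay = gammaDelay(shape, rate))),
            observed = "Z")
        f <- completionPropensity(net, traj)
        h <- 0.7 * as.numeric(traj)
        for (i in c(2L, 5L, 9L))
            expect_equal(unname(f[1L, i]), bruteForceFhat(i, h, shape, rate),
                         tolerance = 1e-5)
    }
})

test_that("count likelihood is the product of Poisson masses", {
    ## single reaction, single interval, fhat = 2, r = 3
    net <- birthNet(A = 2)
    traj <- matrix(c(0L, 3L), 1, dimnames = list("Z", 0:1))
    counts <- matrix(3L, 1, 1, dimnames = list("birth", 1))
    ll <- approxLogLikelihood(counts, traj, net)
    expect_equal(ll, 3 * log(2) - 2 - log(6))
    expect_equal(ll, dpois(3, 2, log = TRUE))
})

test_that("inconsistent counts give zero likelihood", {
    net <- birthNet(A = 2)
    traj <- matrix(c(0L, 5L), 1, dimnames = list("Z", 0:1))
    counts <- matrix(3L, 1, 1)
    expect_identical(approxLogLikelihood(counts, traj, net), -Inf)
    expect_false(chiConsistent(net, counts, traj))
})

test_that("count likelihood equals a term-by-term Poisson oracle", {
    net <- birthDeathNet(A = 3, B = 0.2)
    set.seed(8)
    sim <- simulateTauLeaping(net, 5, seed = 8)
    f <- completionPropensity(net, sim$trajectory)
    oracle <- sum(dpois(as.integer(sim$counts), as.numeric(f), log = TRUE))
    expect_equal(approxLogLikelihood(sim$counts, sim$trajectory, net),
                 oracle, tolerance = 1e-10)
})

test_that("per-cell Poisson masses are normalised", {
    ## sum over r of exp(log-mass) at fixed fhat is 1 (truncated tail)
    f <- 2.7
    mass <- sum(exp(0:60 * log(f) - f - lgamma(0:60 + 1)))
    expect_equal(mass, 1, tolerance = 1e-10)
})

test_that("observation likelihood matches closed forms", {
    y <- rep(0, 101)
    expect_equal(observationLogLikelihood(y, y, observationModel(10)),
                 -101 * 0.5 * log(2 * pi * 10))
    ## doubling residuals at fixed variance scales the quadratic term by 4
    y3 <- c(5, 9, 14)
    r3 <- c(1, -2, 0.5)
    om <- observationModel(3)
    base <- observationLogLikelihood(y3, y3, om)
    l1 <- observationLogLikelihood(y3, y3 + r3, om)
    l2 <- observationLogLikelihood(y3, y3 + 2 * r3, om)
    expect_equal(l2 - base, 4 * (l1 - base), tolerance = 1e-10)
})

test_that("degenerate observation variance errors", {
    expect_error(observationLogLikelihood(c(0, 1), c(0, 1), 0),
                 "degenerate")
})

test_that("a flatter observation model is less informative", {
    ## |d logL / dy| at fixed residual decreases as sigmaE grows
    grad <- function(sigmaE) {
        eps <- 1e-5
        (observationLogLikelihood(10 + eps, 14, sigmaE) -
         observationLogLikelihood(10 - eps, 14, sigmaE)) / (2 * eps)
    }
    g <- vapply(c(1, 10, 100, 1000), grad, 0)
    expect_true(all(diff(abs(g)) < 0))
})

test_that("joint likelihood decomposes and reconstructs", {
    net <- twoStepFig()
    sim <- simulateTauLeaping(net, 5, seed = 31)
    yobs <- sim$trajectory["Y", ] + 0.5
    om <- observationModel(10)
    jl <- jointLogLikelihood(sim$counts, net, yobs, om)
    expect_equal(jl,
                 observationLogLikelihood(sim$trajectory["Y", ], yobs, om) +
                 approxLogLikelihood(sim$counts, sim$trajectory, net))
    ## independent recomputation from first principles
    f <- completionPropensity(net, sim$trajectory)
    byHand <- sum(dpois(as.integer(sim$counts), as.numeric(f),
                        log = TRUE)) +
        sum(dnorm(yobs, sim$trajectory["Y", ],
                  sqrt(sim$trajectory["Y", ] + 10), log = TRUE))
    expect_equal(jl, byHand, tolerance = 1e-9)
    ## infeasible counts (negative reconstruction) are impossible
    bad <- sim$counts
    bad["degY", 1L] <- bad["degY", 1L] + 5L
    expect_identical(jointLogLikelihood(bad, net, yobs, om), -Inf)
})
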