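test_that("undelayed pure birth completes as a Poisson process", {
    net <- birthNet(A = 5)
    set.seed(1)
    tot <- vapply(simulateDelayedSSA(net, T = 10, nTraj = 1000, seed = 1),
                  function(s) sum(s$counts), 0)
    expect_lt(abs(mean(tot) - 50), 3 * sqrt(50 / 1000))
    ## final state equals total births
    expect_equal(mean(vapply(simulateDelayedSSA(net, 10, 50, seed = 7),
                             function(s) s$trajectory["Z", 11L], 0L)),
                 mean(tot), tolerance = 0.15)
})

test_that("delayed pure birth matches its analytic mean", {
    d <- gammaDelay(3.6, 0.6)
    net <- birthNet(A = 5, delay = d)
    ## E[Z(t)] = A * int_0^t F(s) ds for a delayed Poisson input
    expected <- 5 * stats::integrate(function(s) delayCDF(d, s),
                                     0, 10)$value
    z10 <- vapply(simulateDelayedSSA(net, 10, 1000, seed = 3),
                  function(s) s$trajectory["Z", 11L], 0L)
    expect_lt(abs(mean(z10) - expected), 3 * sd(z10) / sqrt(1000))
})

test_that("an absorbing empty state stays empty", {
    net <- twoStepFig()
    net@params@values[["AX"]] <- 1e-12  # effectively zero production
    sim <- simulateDelayedSSA(net, 50, seed = 5)
    expect_true(all(sim$trajectory == 0L))
    expect_true(all(sim$counts == 0L))
})

test_that("tau-leaping with constant propensity gives i.i.d. Poisson counts", {
    net <- birthNet(A = 2)
    counts <- unlist(lapply(simulateTauLeaping(net, 20, nTraj = 500,
                                               seed = 11),
                            function(s) as.integer(s$counts)))
    expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / (20 * 500)))
    expect_equal(var(counts), 2, tolerance = 0.1)
})

test_that("zero rates leave the state constant under tau-leaping", {
    net <- birthDeathNet(A = 10, B = 0.05)
    net@params@values[c("A", "B")] <- c(1e-14, 1e-14)
    sim <- simulateTauLeaping(net, 30, seed = 2)
    expect_true(all(sim$counts == 0L))
    expect_true(all(sim$trajectory == 0L))
})

test_that("trajectories are exactly the stoichiometric reconstruction", {
    net <- twoStepFig()
    for (s in seq_len(4L)) {
        ssa <- simulateDelayedSSA(net, 60, seed = 100 + s)
        expect_true(chiConsistent(net, ssa$counts, ssa$trajectory))
        tau <- simulateTauLeaping(net, 60, seed = 200 + s)
        expect_true(chiConsistent(net, tau$counts, tau$trajectory))
        expect_identical(reconstructTrajectory(net, tau$counts),
                         tau$trajectory)
    }
})

test_that("simulations are deterministic under a fixed seed", {
    net <- twoStepFig()
    a <- simulateDelayedSSA(net, 40, seed = 9)
    b <- simulateDelayedSSA(net, 40, seed = 9)
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(a$counts, b$counts)
    expect_identical(a$eventLog, b$eventLog)
    ta <- simulateTauLeaping(net, 40, seed = 9)
    tb <- simulateTauLeaping(net, 40, seed = 9)
    expect_identical(ta$trajectory, tb$trajectory)
    expect_identical(ta$counts, tb$counts)
})

test_that("the event log reports pending reactions beyond T", {
    net <- birthNet(A = 5, delay = gammaDelay(3.6, 0.1))  # mean 36 min
    sim <- simulateDelayedSSA(net, 10, seed = 4)
    ## most initiations have not completed by T = 10
    expect_gt(nrow(sim$pending), 0L)
    expect_true(all(sim$pending$t_complete > 10))
    expect_true(all(sim$eventLog$t_complete <= 10))
    expect_true(all(sim$eventLog$t_complete >= sim$eventLog$t_init))
})

test_that("exact event-history likelihood of a birth process", {
    net <- birthNet(A = 5)
    sim <- simulateDelayedSSA(net, 6, seed = 21)
    M <- nrow(sim$eventLog)
    ## no delay: completion propensity is A, cumulative hazard A*T
    expect_equal(exactBirthEventLogLik(sim$eventLog$t_complete, 5,
                                       noDelay(), 6),
                 M * log(5) - 5 * 6, tolerance = 1e-8)
    d <- gammaDelay(2, 1)
    netD <- birthNet(A = 5, delay = d)
    simD <- simulateDelayedSSA(netD, 6, seed = 22)
    ll <- exactBirthEventLogLik(simD$eventLog$t_complete, 5, d, 6)
    expect_true(is.finite(ll))
    ## delayed completions are rarer early on, so the delayed hazard is
    ## strictly smaller and the likelihood of few events higher
    expect_gt(-5 * stats::integrate(function(s) delayCDF(d, s),
                                    0, 6)$value, -5 * 6)
})

test_that("delayed reactions with reactants are rejected by tau-leaping", {
    net <- delayedNetwork(
        species = "Z",
        reactions = list(
            reaction("decay", reactants = c(Z = 1),
                     form = "mass_action_linear", rate = 0.1,
                     substrate = "Z", delay = gammaDelay(2, 1))),
        initState = c(Z = 5L), observed = "Z")
    expect_error(simulateTauLeaping(net, 5, seed = 1), "without")
    ## while the delayed SSA handles them (consume at initiation)
    sim <- simulateDelayedSSA(net, 50, seed = 1)
    expect_true(all(sim$trajectory >= 0L))
    expect_equal(sim$trajectory["Z", 51L],
                 5L - sum(sim$counts) - nrow(sim$pending))
})
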