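test_that("conjugate Gamma conditional matches a grid posterior", {
    ## one reaction, exposure 10, 7 counts, Gamma(1, 0.01) prior
    post <- conjugateGammaPosterior(7, 10, prior = c(1, 0.01))
    expect_equal(unname(post), c(8, 10.01))
    ## brute-force grid posterior from the Poisson likelihood
    th <- seq(1e-4, 5, by = 1e-4)
    logp <- 7 * log(th) - th * 10 + dgamma(th, 1, 0.01, log = TRUE)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    q <- dgamma(th, post[1L], post[2L])
    q <- q / sum(q)
    expect_lt(0.5 * sum(abs(p - q)), 1e-3)  # total variation
})

test_that("conjugate conditional with no counts is prior plus exposure", {
    expect_equal(unname(conjugateGammaPosterior(0, 4, prior = c(0.5, 2))),
                 c(0.5, 6))
    expect_error(conjugateGammaPosterior(3, 0, prior = "improper"),
                 "non-integrable")
})

test_that("acceptance probability reduces to the observation ratio", {
    y <- c(10, 20, 30)
    yobs <- c(11, 19, 31)
    om <- observationModel(10)
    expect_equal(acceptanceProbability(y, y, yobs, om), 1)
    ## a log-2 improvement is capped at 1; a log-4 loss gives 1/4
    l <- function(yy) observationLogLikelihood(yy, yobs, om)
    y2 <- c(10.5, 19.5, 30.5)
    expect_equal(acceptanceProbability(y2, y, yobs, om),
                 min(1, exp(l(y2) - l(y))))
    expect_equal(acceptanceProbability(y, y, yobs, om,
                                       logPriorRatio = log(2)), 1)
    expect_equal(acceptanceProbability(y, y, yobs, om,
                                       logPriorRatio = -log(4)), 0.25)
})

test_that("count proposals are deterministic and degenerate cleanly", {
    net <- twoStepFig()
    a <- proposeCounts(net, 30, seed = 5)
    b <- proposeCounts(net, 30, seed = 5)
    expect_identical(a$counts, b$counts)
    net0 <- net
    net0@params@values[c("AX", "AY")] <- 1e-14
    z <- proposeCounts(net0, 30, seed = 5)
    expect_true(all(z$counts == 0L))
})

test_that("gibbsUpdateKinetics respects the free mask and conjugacy", {
    net <- twoStepFig()
    freeParameters(net) <- c("AX", "B")
    sims <- lapply(1:3, function(i) simulateTauLeaping(net, 40,
                                                       seed = 40 + i))
    set.seed(1)
    upd <- gibbsUpdateKinetics(net,
                               lapply(sims, `[[`, "counts"),
                               lapply(sims, `[[`, "trajectory"))
    v0 <- parameterValues(net)
    v1 <- parameterValues(upd)
    ## fixed parameters untouched
    for (lab in c("AY", "KM", "alphaX", "betaX", "alphaY", "betaY"))
        expect_identical(v1[[lab]], v0[[lab]])
    ## free draws near the generative values (counts carry ~4000 events)
    expect_lt(abs(v1[["AX"]] / 10 - 1), 0.2)
    expect_lt(abs(v1[["B"]] / 0.05 - 1), 0.3)
})

test_that("identical seeds give identical chains", {
    cfg <- experimentConfig("custom", nTraj = 3, T = 40, seed = 77)
    ds <- generateDataset(cfg)
    run <- function() runMCMC(ds$net, ds$observations, nIter = 120,
                              burnIn = 40, seed = 19,
                              free = c("AX", "AY", "B", "betaX"),
                              initial = c(AX = 8, AY = 50, B = 0.04,
                                          betaX = 0.5))
    a <- run()
    b <- run()
    expect_identical(a@draws, b@draws)
    expect_identical(a@acceptance, b@acceptance)
})

test_that("chains started at the generative parameters do not drift", {
    cfg <- experimentConfig("custom", nTraj = 5, T = 60, seed = 31)
    ds <- generateDataset(cfg)
    ps <- runMCMC(ds$net, ds$observations, nIter = 900, burnIn = 0,
                  seed = 13, free = c("AX", "AY", "B", "betaX"),
                  initial = c(AX = 10, AY = 60, B = 0.05, betaX = 0.6))
    d <- ps@draws
    half <- nrow(d) %/% 2
    for (p in c("AX_over_KM", "B", "mu_tauX")) {
        m1 <- mean(d[seq_len(half), p])
        m2 <- mean(d[(half + 1):nrow(d), p])
        expect_lt(abs(m2 - m1), 3 * sd(d[, p]))  # no systematic drift
    }
    ## acceptance bookkeeping is reported and non-degenerate
    expect_true(all(ps@acceptance$counts > 0))
    expect_true(all(ps@acceptance$counts < 1))
    expect_gt(ps@acceptance$delay[["betaX"]], 0)
})

test_that("posterior draws respect positivity and config bookkeeping", {
    cfg <- experimentConfig("custom", nTraj = 2, T = 30, seed = 55)
    ds <- generateDataset(cfg)
    ps <- runMCMC(ds$net, ds$observations, nIter = 200, burnIn = 100,
                  thin = 2, seed = 3, free = c("AX", "B"),
                  initial = c(AX = 5, B = 0.1))
    expect_equal(nrow(ps@draws), 50L)
    expect_true(all(ps@draws[, c("AX", "B", "AX_over_KM")] > 0))
    expect_equal(ps@config$nIter, 200)
    expect_equal(ps@config$seed, 3)
    expect_setequal(ps@config$free, c("AX", "B"))
})

test_that("unsupported free parameters are rejected", {
    cfg <- experimentConfig("custom", nTraj = 2, T = 20, seed = 50)
    ds <- generateDataset(cfg)
    expect_error(runMCMC(ds$net, ds$observations, nIter = 10, seed = 1,
                         free = c("AX", "KM")), "KM")
    expect_error(runMCMC(ds$net, ds$observations, nIter = 10, seed = 1,
                         free = c("alphaX")), "alphaX")
})

test_that("posterior precision grows with the number of trajectories", {
    sds <- vapply(c(4L, 12L), function(n) {
        cfg <- experimentConfig("custom", nTraj = n, T = 80, seed = 900)
        ds <- generateDataset(cfg)
        ps <- runMCMC(ds$net, ds$observations, nIter = 700, burnIn = 350,
                      seed = 23, free = c("AY", "B", "betaX"),
                      initial = c(AY = 60, B = 0.05, betaX = 0.6))
        s <- summarizePosterior(ps)
        s$sd[s$parameter == "B"]
    }, 0)
    expect_lt(sds[2L], sds[1L])
})
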