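#' @include likelihood.R
NULL

## ---- priors -------------------------------------------------------------

## Normalise a prior spec: named list with elements c(shape, rate) or
## "improper" plus a "default"; returns list(a, b, proper).
.priorFor <- function(priors, label) {
    p <- priors[[label]]
    if (is.null(p)) p <- priors[["default"]]
    if (is.null(p)) p <- c(0.01, 0.01)
    if (identical(p, "improper"))
        return(list(a = 1, b = 0, proper = FALSE))
    stopifnot(is.numeric(p), length(p) == 2L, all(p > 0))
    list(a = p[1L], b = p[2L], proper = TRUE)
}

.logPrior <- function(prior, x) {
    if (!prior$proper) return(0)
    dgamma(x, shape = prior$a, rate = prior$b, log = TRUE)
}

#' Conjugate Gamma conditional for a rate parameter
#'
#' For a rate parameter that multiplies the completion propensity
#' linearly, the Poisson count likelihood is conjugate to a Gamma prior:
#' given total completion counts \code{n} and total exposure \code{E}
#' (the rate-free part of the summed completion propensities), the
#' conditional posterior is Gamma(a0 + n, b0 + E).
#'
#' @param n Total completion counts of the reactions tied to the
#'   parameter.
#' @param E Total exposure (sum over trajectories and intervals of the
#'   completion propensity divided by the rate).
#' @param prior \code{c(a0, b0)} Gamma hyperparameters, or
#'   \code{"improper"} for a flat prior on (0, Inf).
#' @return \code{c(shape, rate)} of the Gamma conditional posterior.
#' @export
conjugateGammaPosterior <- function(n, E, prior = c(0.01, 0.01)) {
    p <- .priorFor(list(default = prior), "default")
    if (!p$proper && E <= 0)
        stop("zero exposure with an improper prior: conditional posterior ",
             "is non-integrable")
    c(shape = p$a + n, rate = p$b + E)
}

## ---- operations of the sampler (exported surface) -----------------------

#' Propose latent reaction counts by simulating the model
#'
#' One delayed tau-leaping simulation of the network at its current
#' parameters, used as the Metropolis-Hastings proposal for the latent
#' per-interval reaction counts of one cell.  Because the proposal
#' density is the approximate count-likelihood factor itself, that
#' factor cancels from the acceptance ratio, which therefore involves
#' the observation likelihood only.
#'
#' @inheritParams simulateTauLeaping
#' @return List with \code{trajectory} and \code{counts}.
#' @export
proposeCounts <- function(net, T, seed = NULL, weights = NULL) {
    simulateTauLeaping(net, T, nTraj = 1L, seed = seed, weights = weights)
}

#' Acceptance probability for simulation-based count proposals
#'
#' With a uniform prior over reaction counts and proposals drawn by
#' simulating the model, the approximate count-likelihood factor cancels
#' and the Metropolis-Hastings acceptance probability reduces to the
#' ratio of observation likelihoods of the proposed and current
#' trajectories of the observed species.
#'
#' @param yStar,yCurr Proposed and current trajectories of the observed
#'   species (vector or matrix on the grid 0..T).
#' @param yobs Noisy observations, same shape.
#' @param om \linkS4class{ObservationModel} or sigmaE value.
#' @param logPriorRatio Optional log prior ratio log pi(r*) - log pi(r)
#'   for a non-uniform count prior.
#' @return Acceptance probability in \[0, 1\].
#' @export
acceptanceProbability <- function(yStar, yCurr, yobs, om,
                                  logPriorRatio = 0) {
    lStar <- observationLogLikelihood(yStar, yobs, om)
    lCurr <- observationLogLikelihood(yCurr, yobs, om)
    min(1, exp(lStar - lCurr + logPriorRatio))
}

#' One Gibbs update of the kinetic rate parameters
#'
#' Draws every free rate-type parameter from its conjugate Gamma
#' conditional given the current latent reaction counts and
#' trajectories; reactions sharing a parameter label pool their counts
#' and exposures.  Fixed parameters and delay parameters are left
#' untouched (free delay rates are updated by a random-walk step inside
#' \code{\link{runMCMC}}).
#'
#' @param net A \linkS4class{DelayedNetwork} (its free mask selects the
#'   parameters to update; see \code{\link{freeParameters}}).
#' @param countsList,trajList Lists (one element per trajectory) of
#'   completion-count matrices and trajectories.
#' @param priors Prior specification (named list of \code{c(a0, b0)} or
#'   \code{"improper"}, with optional \code{default}).
#' @return The network with updated parameter values.
#' @export
gibbsUpdateKinetics <- function(net, countsList, trajList,
                                priors = list(default = c(0.01, 0.01))) {
    rateLabels <- vapply(net@reactions, slot, "", "rateLabel")
    free <- intersect(freeParameters(net), unique(rateLabels))
    if (!length(free)) return(net)
    weights <- lapply(net@reactions, function(rx)
        delayWeights(realizedDelay(rx, net@params)))
    for (lab in free) {
        vals <- net@params@values
        ks <- which(rateLabels == lab)
        n <- 0
        E <- 0
        for (c in seq_along(countsList)) {
            fhat <- completionPropensity(net, trajList[[c]], weights)
            n <- n + sum(countsList[[c]][ks, ])
            E <- E + sum(fhat[ks, ]) / vals[[lab]]
        }
        pr <- .priorFor(priors, lab)
        post <- conjugateGammaPosterior(n, E, if (pr$proper)
            c(pr$a, pr$b) else "improper")
        net <- setParameterValues(
            net, setNames(rgamma(1L, shape = post[[1L]],
                                 rate = post[[2L]]), lab))
    }
    net
}

## ---- main sampler -------------------------------------------------------

.asObservationList <- function(obs) {
    if (is(obs, "ObservationSet")) return(obs@data)
    if (is.matrix(obs)) return(list(obs))
    if (is.numeric(obs)) return(list(matrix(obs, nrow = 1L)))
    stopifnot(is.list(obs))
    lapply(obs, function(m) if (is.matrix(m)) m else matrix(m, nrow = 1L))
}

## shape label paired with a delay-rate label.
.pairedShapeLabel <- function(net, rateLab) {
    for (rx in net@reactions) {
        hit <- which(rx@delayRateLabels == rateLab)
        if (length(hit)) return(rx@delayShapeLabels[hit[1L]])
    }
    stop("no delay component for label '", rateLab, "'")
}

.muName <- function(lab) {
    if (grepl("^beta", lab)) paste0("mu_tau", substring(lab, 5L))
    else paste0("mu_", lab)
}

#' Data-driven starting values for the two-step model
#'
#' Initialises the MCMC inside the posterior's basin of attraction using
#' only the observed data.  Companion parameters (\code{AY}, \code{B},
#' free delay rates) come from a least-squares fit of the model's
#' deterministic mean dynamics to the average observed trajectory.  The
#' position on the ridge that trades the activator scale \code{AX/KM}
#' against the maximal reporter rate \code{AY} -- which the mean
#' trajectory cannot resolve -- is then profiled with a Gaussian
#' synthetic likelihood: at each candidate ratio the model is simulated
#' exactly (delayed SSA ensembles, common random numbers) and every
#' cell's measured path is scored under a multivariate normal with the
#' ensemble mean and covariance plus the diagonal observation noise, so
#' that the variance/autocovariance signature of the transmitted
#' activator fluctuations enters the comparison.  The chain is started
#' at the sharply determined lower edge of the resulting score plateau
#' (see the vignette for why the edge, not the noisy plateau peak, is
#' the right starting point).  Fixed parameters keep the network's
#' values.  For networks without the two-step structure the
#' least-squares mean fit alone is used.
#'
#' @param net A two-step \linkS4class{DelayedNetwork} (labels \code{AX},
#'   \code{AY}, \code{KM}, \code{B}, \code{alphaX}, \code{betaX},
#'   \code{alphaY}, \code{betaY}).
#' @param obs Observations accepted by \code{\link{runMCMC}}.
#' @param free Labels to initialise (subset of \code{AX}, \code{AY},
#'   \code{B}, \code{betaX}, \code{betaY}).
#' @param sigmaE Observation noise offset of the measurement model.
#' @param scanSeed Integer seed for the common-random-number ensembles
#'   of the scans (drawn from the current RNG stream when NULL).
#' @param sims Ensemble size per score evaluation.
#' @param rounds Number of independent ensembles averaged per profile
#'   point (reduce for quick runs).
#' @param ridgeProfile Run the synthetic-likelihood ridge profile;
#'   disable for a quick heuristic ridge position (used e.g. in short
#'   screening runs).
#' @return Named numeric of starting values for \code{free}.
#' @export
momentInit <- function(net, obs, free = freeParameters(net), sigmaE = 10,
                       scanSeed = NULL, sims = 200L, rounds = 2L,
                       ridgeProfile = TRUE) {
    obsL <- .asObservationList(obs)
    T <- ncol(obsL[[1L]]) - 1L
    Y <- vapply(obsL, function(x) x[1L, ], numeric(T + 1L))
    m <- rowMeans(Y)
    vals <- net@params@values
    need <- c("AX", "AY", "KM", "B", "alphaX", "betaX", "alphaY", "betaY")
    twoStep <- all(need %in% names(vals))
    freeBeta <- intersect(free, c("betaX", "betaY"))
    fit <- c(intersect(free, c("AX", "AY", "B")), freeBeta)
    if (!twoStep || !length(fit)) return(setNames(numeric(0), character(0)))
    KM <- vals[["KM"]]
    ## mean delay carried by components whose rate is held fixed
    alphaOf <- c(betaX = "alphaX", betaY = "alphaY")
    muFixed <- sum(vapply(setdiff(names(alphaOf), freeBeta), function(b)
        vals[[alphaOf[[b]]]] / vals[[b]], 0))

    ## crude half-rise heuristics seed the optimiser
    yInf <- max(mean(m[max(1L, round(0.85 * T)):(T + 1L)]), 1)
    tAt <- function(q) {
        idx <- which(m >= q * yInf)
        if (length(idx)) min(idx) - 1L else T
    }
    t50 <- tAt(0.5)
    t80 <- tAt(0.8)
    B0 <- if ("B" %in% fit) {
        max(min(log(2.5) / max(t80 - t50, 1), 1), 1e-3)
    } else vals[["B"]]
    muX0 <- min(max(t50 - log(2) / B0 - muFixed, 0.5), T / 2)
    nFB <- max(length(freeBeta), 1L)
    muComp <- max(muX0 / nFB, 0.3)        # free delay mean per component
    base <- c(AX = unname(B0 * KM), AY = unname(2 * B0 * yInf),
              B = unname(B0),
              betaX = unname(vals[["alphaX"]] / muComp),
              betaY = unname(vals[["alphaY"]] / muComp))
    for (lab in setdiff(names(base), fit))
        base[lab] <- vals[[lab]]

    meanTraj <- function(p) {
        tt <- 0:T
        X <- p[["AX"]] / p[["B"]] * (1 - exp(-p[["B"]] * tt))
        g <- X / (KM + X)
        w <- delayWeights(gammaSumDelay(
            c(vals[["alphaX"]], vals[["alphaY"]]),
            c(p[["betaX"]], p[["betaY"]])), maxSupport = 4 * T)
        out <- numeric(T + 1L)
        for (i in seq_len(T)) {
            j <- 0:min(length(w) - 1L, i)
            f3 <- p[["AY"]] * sum(w[j + 1L] * g[i - j + 1L])
            out[i + 1L] <- (out[i] * (1 - p[["B"]] / 2) + f3) /
                (1 + p[["B"]] / 2)
        }
        out
    }
    fitMean <- function(sub, p0) {
        if (!length(sub))
            return(list(par = p0, sse = sum((meanTraj(p0) - m)^2)))
        obj <- function(lp) {
            p <- p0
            p[sub] <- exp(lp)
            if (p[["betaX"]] < 1e-4 || p[["betaY"]] < 1e-4 ||
                p[["B"]] > 2) return(1e12)
            sum((meanTraj(p) - m)^2)
        }
        opt <- stats::optim(log(p0[sub]), obj, method = "Nelder-Mead",
                            control = list(maxit = 300, reltol = 1e-6))
        p <- p0
        p[sub] <- exp(opt$par)
        list(par = p, sse = opt$value)
    }

    ## Gaussian synthetic likelihood of the measured paths: the model is
    ## simulated exactly (delayed SSA, common random numbers across
    ## candidates) and each cell's path is scored under a multivariate
    ## normal with the ensemble mean and covariance plus the diagonal
    ## observation noise.  The covariance carries the variance and
    ## autocovariance structure that resolves the AX/KM - AY degeneracy
    ## ridge, which the mean trajectory alone cannot.
    if (is.null(scanSeed)) scanSeed <- floor(runif(1L) * 1e6) + 1L
    slik <- function(p, S, crn, lambda = 0.05) {
        netC <- setParameterValues(net, p)
        sims <- simulateDelayedSSA(netC, T, nTraj = S, seed = crn)
        Ys <- vapply(sims, function(s)
            as.numeric(s$trajectory[net@observed, ]), numeric(T + 1L))
        mS <- rowMeans(Ys)
        Sg <- tcrossprod(Ys - mS) / (S - 1)
        Sg <- (1 - lambda) * Sg + lambda * diag(diag(Sg))
        diag(Sg) <- diag(Sg) + mS + sigmaE
        ch <- tryCatch(chol(Sg), error = function(e) NULL)
        if (is.null(ch)) return(-Inf)
        R <- backsolve(ch, Y - mS, transpose = TRUE)
        -0.5 * (ncol(Y) * 2 * sum(log(diag(ch))) + sum(R^2))
    }
    if ("AX" %in% fit) {
        ## Coordinate scans in a reparametrisation with nearly separable
        ## coordinates: r = AX/KM (ridge position), mu = total mean
        ## delay of the free delay components, B = dilution rate,
        ## L = steady reporter level AY g(Xinf)/B.
        toPar <- function(q) {
            Xinf <- q[["r"]] * KM / q[["B"]]
            g <- Xinf / (KM + Xinf)
            p <- c(AX = q[["r"]] * KM,
                   AY = unname(q[["L"]] * q[["B"]] / g), B = q[["B"]])
            for (b in freeBeta)   # split the free delay mean evenly
                p[b] <- vals[[alphaOf[[b]]]] * length(freeBeta) /
                    q[["mu"]]
            p
        }
        ## companion coordinates from the deterministic mean-trajectory
        ## fit at a neutral ridge position (the mean curve is nearly
        ## ridge-invariant, so these are usable at any candidate r)
        pLS <- fitMean(setdiff(fit, "AX"), {
            p0 <- base
            p0[["AX"]] <- 0.2 * KM
            p0
        })$par
        XinfLS <- pLS[["AX"]] / pLS[["B"]]
        q <- c(r = 0.2,
               mu = unname(sum(vapply(freeBeta, function(b)
                   vals[[alphaOf[[b]]]] / pLS[[b]], 0))),
               B = unname(pLS[["B"]]),
               L = unname(pLS[["AY"]] * XinfLS / (KM + XinfLS) /
                          pLS[["B"]]))
        if (!is.finite(q[["mu"]]) || q[["mu"]] <= 0) q[["mu"]] <- muX0
        ## alternate a profile scan over the ridge position (with the
        ## steady level compensated through toPar) with line polishing
        ## of the companion coordinates at the current ridge estimate
        ## The profile over the ridge has an asymmetric geometry: the
        ## score collapses steeply below the identified region (too
        ## little activator cannot reproduce the transmitted
        ## fluctuations) but is nearly flat above it.  The sampler's
        ## level-shift moves push the chain up-ridge from below far more
        ## strongly than down from above, so the chain is started at the
        ## sharply determined lower edge of the score plateau (the point
        ## where the profile first comes within `edgeDrop` of its
        ## maximum) rather than at the noisy plateau peak.
        if (ridgeProfile) {
            rr <- exp(seq(log(0.02), log(2), length.out = 10L))
            sc <- 0
            for (rep in seq_len(max(rounds, 1L)))
                sc <- sc + vapply(rr, function(r) {
                    qq <- q
                    qq[["r"]] <- r
                    slik(toPar(qq), sims, scanSeed + rep * 100000L)
                }, 0)
            sc <- sc / max(rounds, 1L)
            ## start at the sharply determined lower edge of the score
            ## plateau: below it the score collapses steeply (too little
            ## activator cannot carry the transmitted fluctuations),
            ## above it the profile is nearly flat and the sampler's
            ## level-shift moves explore upward far more readily than
            ## downward
            edgeDrop <- 12
            i1 <- min(which(sc > max(sc) - edgeDrop))
            q[["r"]] <- if (i1 > 1L) {
                drop0 <- max(sc) - sc[i1 - 1L]
                drop1 <- max(sc) - sc[i1]
                frac <- (drop0 - edgeDrop) / max(drop0 - drop1, 1e-9)
                exp(log(rr[i1 - 1L]) +
                    min(max(frac, 0), 1) *
                    (log(rr[i1]) - log(rr[i1 - 1L])))
            } else rr[1L]
        } else {
            ## no profile requested: a mid-saturation heuristic
            q[["r"]] <- max(q[["B"]], 0.02)
        }
        out <- toPar(q)
        set.seed(scanSeed + 101L)   # leave a reproducible stream behind
        return(out[fit])
    }
    fitMean(fit, base)$par[fit]
}

#' Simulation-based MCMC for partially observed delayed networks
#'
#' Metropolis-Hastings-within-Gibbs sampler for the kinetic and delay
#' parameters of a delayed reaction network observed through noisy
#' measurements of a subset of species.  Each iteration
#' \enumerate{
#'   \item proposes, independently for every trajectory (cell), fresh
#'     latent reaction counts by simulating the model with delayed
#'     tau-leaping at the current parameters -- either the whole path or
#'     only the tail from a random restart time, conditional on the
#'     incumbent prefix -- accepting with probability equal to the
#'     observation-likelihood ratio (the count-likelihood factor cancels
#'     against the simulation proposal, so no proposal tuning is
#'     needed); local level-shift Metropolis moves (see
#'     \code{shiftMoves}) then let the latent copy-number scale drift;
#'   \item draws every free rate parameter from its conjugate Gamma
#'     conditional given the accepted counts;
#'   \item updates every free delay rate parameter by a log-scale
#'     random-walk Metropolis step against the Poisson count likelihood
#'     (step size adapted toward ~0.3 acceptance during burn-in only,
#'     then frozen to preserve detailed balance).
#' }
#' Delay shapes, Michaelis constants and the observation noise are held
#' fixed (an optional random-walk update of sigmaE can be enabled).
#'
#' For the two-step activation model, identifiability requires fixing
#' the Michaelis constant \code{KM} and the maturation-delay
#' distribution; with short, pre-steady-state trajectories the dilution
#' rate \code{B} must be fixed as well (see the vignette).
#'
#' @param net A \linkS4class{DelayedNetwork}; fixed parameters keep the
#'   network's values.
#' @param obs An \linkS4class{ObservationSet}, or a list with one
#'   numeric vector/matrix of observed-species measurements per
#'   trajectory, on the grid 0..T.
#' @param nIter,burnIn,thin Chain length, discarded initial iterations,
#'   thinning interval.
#' @param seed Integer seed governing the whole run.
#' @param free Character vector of free parameter labels; defaults to
#'   the network's current free mask.
#' @param priors Named list of Gamma hyperparameters \code{c(a0, b0)}
#'   (or \code{"improper"}) per free label, with optional
#'   \code{default} entry (default \code{c(0.01, 0.01)}, weakly
#'   informative).
#' @param om \linkS4class{ObservationModel} (or sigmaE value).
#' @param initial Starting values for the free parameters.  The default
#'   \code{"auto"} fits the deterministic mean dynamics to the average
#'   observed trajectory (\code{\link{momentInit}}), which places the
#'   chain inside the posterior's basin; a named numeric overrides
#'   individual entries; \code{NULL} uses generic values (rates at 1,
#'   delay rates at their shape, i.e. mean delay of one time unit).
#'   Starting values never copy the network's own parameter values, so
#'   recovery runs do not silently start at the generative truth.
#' @param updateSigmaE Enable the optional random-walk update of the
#'   observation noise offset (off by default: the observation model is
#'   normally calibrated separately).
#' @param delayStepSize Initial log-scale random-walk step for delay
#'   rates.
#' @param maxDelaySupport Cap (time units) on the delay support used
#'   when discretising proposed delay distributions.
#' @param shiftMoves Number of local level-shift Metropolis moves per
#'   cell per iteration (+-1 on a single per-interval count, shifting
#'   the reconstructed suffix); defaults to T.  These moves supplement
#'   the simulation-based proposals along their slow direction -- the
#'   overall latent copy-number scale.  Set to 0 to disable.
#' @param progress Print a progress line every 1000 iterations.
#' @return A \linkS4class{PosteriorSamples} holding the free parameters,
#'   derived quantities (\code{mu_tau*} mean delays; \code{AX_over_KM}
#'   when the two-step labels are present) and the total observation
#'   log-likelihood, plus acceptance bookkeeping.
#' @seealso \code{\link{summarizePosterior}}
#' @export
runMCMC <- function(net, obs, nIter = 10000L, burnIn = floor(nIter / 2),
                    thin = 1L, seed = NULL,
                    free = freeParameters(net),
                    priors = list(default = c(0.01, 0.01)),
                    om = observationModel(10), initial = "auto",
                    updateSigmaE = FALSE, delayStepSize = 0.15,
                    maxDelaySupport = 600, shiftMoves = NULL,
                    progress = FALSE) {
    stopifnot(is(net, "DelayedNetwork"), nIter >= 1, burnIn < nIter)
    if (!is.null(seed)) set.seed(seed)
    obsL <- .asObservationList(obs)
    nT <- length(obsL)
    T <- ncol(obsL[[1L]]) - 1L
    for (m in obsL) stopifnot(ncol(m) == T + 1L)
    if (all(unlist(obsL) == 0))
        warning("observations are identically zero: low-information run")
    sigmaE <- .asSigmaE(om)

    v <- length(net@reactions)
    rateLabels <- vapply(net@reactions, slot, "", "rateLabel")
    delayRateLabels <- unique(unlist(lapply(net@reactions, slot,
                                            "delayRateLabels")))
    freeRate <- intersect(free, unique(rateLabels))
    freeDelay <- intersect(free, delayRateLabels)
    bad <- setdiff(free, c(freeRate, freeDelay))
    if (length(bad))
        stop("unsupported free parameter(s): ",
             paste(bad, collapse = ", "),
             " (only rate and delay-rate parameters can be sampled; ",
             "fix Michaelis constants and delay shapes)")
    net <- `freeParameters<-`(net, free)

    ## starting values: moment-matching when available, else generic
    start <- c()
    for (lab in freeRate) start[lab] <- 1
    for (lab in freeDelay)
        start[lab] <- net@params@values[[.pairedShapeLabel(net, lab)]]
    if (identical(initial, "auto")) {
        mi <- momentInit(net, obsL, free, sigmaE = sigmaE)
        start[names(mi)] <- mi
    } else if (!is.null(initial)) {
        start[names(initial)] <- initial
    }
    if (length(start)) net <- setParameterValues(net, start)
    vals <- net@params@values

    cmp <- .compileNetwork(net)
    affectedBy <- lapply(freeDelay, function(lab)
        which(vapply(net@reactions, function(rx)
            lab %in% rx@delayRateLabels, NA)))
    names(affectedBy) <- freeDelay
    affectedAny <- sort(unique(unlist(affectedBy)))
    obsIdx <- which(net@observed)
    kLabShape <- lapply(net@reactions, slot, "delayShapeLabels")
    kLabRate <- lapply(net@reactions, slot, "delayRateLabels")

    makeWeights <- function(vv, which = seq_len(v), base = NULL) {
        w <- if (is.null(base)) vector("list", v) else base
        for (k in which) {
            shapes <- unname(vv[kLabShape[[k]]])
            rates <- unname(vv[kLabRate[[k]]])
            d <- if (length(shapes) == 0L) noDelay()
                 else if (length(shapes) == 1L) gammaDelay(shapes, rates)
                 else gammaSumDelay(shapes, rates)
            w[[k]] <- delayWeights(d, maxSupport = maxDelaySupport)
        }
        w
    }
    weights <- makeWeights(vals)

    ## rate-free initiation propensities along a trajectory (K is fixed)
    hUnit <- function(traj) {
        H <- matrix(0, v, ncol(traj))
        for (k in seq_len(v)) {
            rx <- net@reactions[[k]]
            H[k, ] <- switch(rx@propensityForm,
                constant = rep(1, ncol(traj)),
                mass_action_linear = traj[rx@substrate, ],
                michaelis_menten = {
                    z <- traj[rx@substrate, ]
                    z / (vals[[rx@kLabel]] + z)
                })
        }
        H
    }
    trajObsLL <- function(traj, yobsM, sig = sigmaE) {
        ll <- 0
        for (i in seq_along(obsIdx)) {
            y <- traj[obsIdx[i], ]
            ll <- ll + sum(dnorm(yobsM[i, ], mean = y,
                                 sd = sqrt(y + sig), log = TRUE))
        }
        ll
    }
    simOnce <- function(c = 0L, from = 0L) {
        if (from > 0L)
            cpp_tau_leap(cmp$reactant, cmp$netchange, cmp$propType,
                         unname(vals[rateLabels]), cmp$K, cmp$subs,
                         weights, cmp$z0, T, startFrom = from,
                         prevTraj = stTraj[[c]],
                         prevCounts = stCounts[[c]])
        else
            cpp_tau_leap(cmp$reactant, cmp$netchange, cmp$propType,
                         unname(vals[rateLabels]), cmp$K, cmp$subs,
                         weights, cmp$z0, T)
    }
    ## Poisson log-likelihood of the stored counts for the reactions
    ## whose delay is being updated (log r! terms cancel in ratios).
    delayCountLL <- function(fuList) {
        ll <- 0
        for (c in seq_len(nT)) {
            fu <- fuList[[c]]
            for (k in affectedAny) {
                f <- vals[[rateLabels[k]]] * fu[k, ]
                r <- stCounts[[c]][k, ]
                pos <- f > 0
                if (any(!pos & r > 0)) return(-Inf)
                ll <- ll + sum(r[pos] * log(f[pos])) - sum(f)
            }
        }
        ll
    }

    ## chain state
    stCounts <- vector("list", nT)
    stTraj <- vector("list", nT)
    stHU <- vector("list", nT)
    stFU <- vector("list", nT)
    llObs <- numeric(nT)
    for (c in seq_len(nT)) {
        sim <- simOnce()
        stCounts[[c]] <- sim$counts
        stTraj[[c]] <- sim$traj
        stHU[[c]] <- hUnit(sim$traj)
        stFU[[c]] <- cpp_fhat(stHU[[c]], weights)
        llObs[c] <- trajObsLL(sim$traj, obsL[[c]])
    }

    keepIts <- seq(burnIn + 1L, nIter, by = thin)
    derivedDelay <- vapply(freeDelay, .muName, "")
    hasRatio <- all(c("AX", "KM") %in% names(vals)) && "AX" %in% freeRate
    cols <- c(freeRate, freeDelay, unname(derivedDelay),
              if (hasRatio) "AX_over_KM",
              if (updateSigmaE) "sigmaE", "logObsLik")
    draws <- matrix(NA_real_, length(keepIts), length(cols),
                    dimnames = list(NULL, cols))
    nShift <- if (is.null(shiftMoves)) as.integer(T) else
        as.integer(shiftMoves)
    accShift <- 0
    accCounts <- integer(nT)
    accDelay <- setNames(numeric(length(freeDelay)), freeDelay)
    lstep <- setNames(rep(delayStepSize, length(freeDelay)), freeDelay)
    accSigma <- 0L
    sstep <- 0.2
    row <- 0L

    for (it in seq_len(nIter)) {
        ## 1. simulation-based count proposals, one block per trajectory:
        ## a mixture of full re-simulations and partial re-simulations
        ## from a uniformly drawn restart time (the retained prefix
        ## cancels from both likelihood and proposal, so the acceptance
        ## ratio is unchanged while short tails refresh often).
        for (c in seq_len(nT)) {
            from <- if (runif(1L) < 0.1) 0L else
                sample.int(T, 1L) - 1L
            sim <- simOnce(c, from)
            ll <- trajObsLL(sim$traj, obsL[[c]])
            if (is.finite(ll) && log(runif(1L)) < ll - llObs[c]) {
                stCounts[[c]] <- sim$counts
                stTraj[[c]] <- sim$traj
                stHU[[c]] <- hUnit(sim$traj)
                stFU[[c]] <- cpp_fhat(stHU[[c]], weights)
                llObs[c] <- ll
                accCounts[c] <- accCounts[c] + 1L
            }
        }
        ## 1b. local level-shift Metropolis moves on the counts: +-1 on
        ## a single per-interval count shifts the reconstructed suffix,
        ## letting the latent levels drift while keeping the incumbent's
        ## data-matched path shape (the slow direction of the
        ## simulation-based proposals, e.g. the activator copy-number
        ## scale, which the observations constrain only weakly)
        if (nShift > 0L) {
            for (c in seq_len(nT)) {
                stTraj[[c]] <- stTraj[[c]] + 0L     # private copies:
                stCounts[[c]] <- stCounts[[c]] + 0L # mutated in place
                stHU[[c]] <- stHU[[c]] + 0
                stFU[[c]] <- stFU[[c]] + 0
                res <- cpp_level_moves(
                    cmp$reactant, cmp$netchange, cmp$propType,
                    unname(vals[rateLabels]), cmp$K, cmp$subs, weights,
                    stTraj[[c]], stCounts[[c]], stHU[[c]], stFU[[c]],
                    obsIdx - 1L, obsL[[c]], sigmaE, nShift)
                accShift <- accShift + res$accepted
                llObs[c] <- trajObsLL(stTraj[[c]], obsL[[c]])
            }
        }
        ## 2. conjugate Gamma updates of free rates
        for (lab in freeRate) {
            ks <- which(rateLabels == lab)
            n <- 0
            E <- 0
            for (c in seq_len(nT)) {
                n <- n + sum(stCounts[[c]][ks, ])
                E <- E + sum(stFU[[c]][ks, ])
            }
            pr <- .priorFor(priors, lab)
            if (!pr$proper && E <= 0)
                stop("zero exposure with an improper prior for '", lab, "'")
            vals[lab] <- rgamma(1L, shape = pr$a + n, rate = pr$b + E)
        }
        ## 3. log-scale random walk on free delay rates
        for (lab in freeDelay) {
            cur <- vals[[lab]]
            prop <- cur * exp(lstep[lab] * rnorm(1L))
            ## keep the implied mean delay within a sane window
            shp <- vals[[.pairedShapeLabel(net, lab)]]
            if (!is.finite(prop) || shp / prop < 0.02 ||
                shp / prop > maxDelaySupport) next
            llCur <- delayCountLL(stFU)
            vProp <- vals
            vProp[lab] <- prop
            wProp <- makeWeights(vProp, which = affectedBy[[lab]],
                                 base = weights)
            if (any(!is.finite(unlist(wProp[affectedBy[[lab]]])))) next
            fuProp <- stFU
            for (c in seq_len(nT))
                fuProp[[c]] <- cpp_fhat(stHU[[c]], wProp)
            llProp <- delayCountLL(fuProp)
            pr <- .priorFor(priors, lab)
            logAlpha <- (llProp + .logPrior(pr, prop) + log(prop)) -
                (llCur + .logPrior(pr, cur) + log(cur))
            if (is.finite(logAlpha) && log(runif(1L)) < logAlpha) {
                vals[lab] <- prop
                weights <- wProp
                stFU <- fuProp
                accDelay[lab] <- accDelay[lab] + 1
            }
            if (it <= burnIn) {
                acc <- min(1, exp(logAlpha))
                if (!is.finite(acc)) acc <- 0
                lstep[lab] <- min(max(lstep[lab] *
                                      exp(it^(-0.6) * (acc - 0.3)),
                                      1e-3), 2)
            }
        }
        ## 4. optional observation-noise update
        if (updateSigmaE) {
            prop <- sigmaE * exp(sstep * rnorm(1L))
            llCur <- sum(llObs)
            llProp <- sum(vapply(seq_len(nT), function(c)
                trajObsLL(stTraj[[c]], obsL[[c]], sig = prop), 0))
            pr <- .priorFor(priors, "sigmaE")
            logAlpha <- (llProp + .logPrior(pr, prop) + log(prop)) -
                (llCur + .logPrior(pr, sigmaE) + log(sigmaE))
            if (is.finite(logAlpha) && log(runif(1L)) < logAlpha) {
                sigmaE <- prop
                llObs <- vapply(seq_len(nT), function(c)
                    trajObsLL(stTraj[[c]], obsL[[c]]), 0)
                accSigma <- accSigma + 1L
            }
            if (it <= burnIn) {
                acc <- min(1, exp(logAlpha))
                if (!is.finite(acc)) acc <- 0
                sstep <- sstep * exp(it^(-0.6) * (acc - 0.3))
            }
        }
        ## 5. record
        if (it > burnIn && (it - burnIn - 1L) %% thin == 0L) {
            row <- row + 1L
            for (lab in freeRate) draws[row, lab] <- vals[[lab]]
            for (lab in freeDelay) {
                draws[row, lab] <- vals[[lab]]
                draws[row, .muName(lab)] <-
                    vals[[.pairedShapeLabel(net, lab)]] / vals[[lab]]
            }
            if (hasRatio)
                draws[row, "AX_over_KM"] <- vals[["AX"]] / vals[["KM"]]
            if (updateSigmaE) draws[row, "sigmaE"] <- sigmaE
            draws[row, "logObsLik"] <- sum(llObs)
        }
        if (progress && it %% 1000L == 0L)
            message(sprintf("iteration %d / %d", it, nIter))
    }

    new("PosteriorSamples",
        draws = draws[seq_len(row), , drop = FALSE],
        acceptance = list(
            counts = accCounts / nIter,
            shift = if (nShift > 0L)
                accShift / (as.numeric(nIter) * nT * nShift) else NULL,
            delay = accDelay / max(1L, nIter),
            sigmaE = if (updateSigmaE) accSigma / nIter else NULL),
        config = list(nIter = nIter, burnIn = burnIn, thin = thin,
                      seed = seed, free = free, priors = priors,
                      sigmaE = sigmaE, nTrajectories = nT, T = T,
                      start = start, delayStep = lstep))
}
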