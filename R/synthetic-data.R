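#' @include inference.R
NULL

#' Configuration of a synthetic benchmark experiment
#'
#' Bundles the generative parameters of the two-step activation model
#' with the design of a synthetic single-cell experiment.  Two named
#' regimes are built in: \code{"steady_state"} (40 trajectories measured
#' at t = 0..100 min, long enough to reach steady state) and
#' \code{"short"} (40 trajectories, t = 0..50 min, stopping well before
#' steady state -- the regime in which the dilution rate becomes
#' unidentifiable).  Use \code{regime = "custom"} to change \code{T} or
#' \code{nTraj}.
#'
#' @param regime \code{"steady_state"}, \code{"short"} or
#'   \code{"custom"}.
#' @param AX,AY,KM,B Generative kinetic parameters (defaults: 10, 60,
#'   100, 0.05; rates in 1/min).
#' @param tauX,tauY Generative regulation and maturation delay
#'   distributions (defaults Gamma(18/5, 3/5), mean 6 min each).
#' @param sigmaE Observation noise offset (default 10): measurements are
#'   the true Y counts plus N(0, Y(t) + sigmaE) noise.
#' @param nTraj,T Number of trajectories and final time; fixed by the
#'   named regimes, required for \code{"custom"}.
#' @param seed Base seed; trajectory i uses stream seed + i - 1.
#' @return A list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(regime = c("steady_state", "short", "custom"),
                             AX = 10, AY = 60, KM = 100, B = 0.05,
                             tauX = gammaDelay(18 / 5, 3 / 5),
                             tauY = gammaDelay(18 / 5, 3 / 5),
                             sigmaE = 10, nTraj = NULL, T = NULL,
                             seed = 1L) {
    regime <- match.arg(regime)
    fixed <- switch(regime,
                    steady_state = c(T = 100L, nTraj = 40L),
                    short = c(T = 50L, nTraj = 40L),
                    custom = NULL)
    if (!is.null(fixed)) {
        if ((!is.null(T) && T != fixed[["T"]]) ||
            (!is.null(nTraj) && nTraj != fixed[["nTraj"]]))
            stop("regime '", regime, "' fixes T = ", fixed[["T"]],
                 " and nTraj = ", fixed[["nTraj"]],
                 "; use regime = 'custom' to override")
        T <- fixed[["T"]]
        nTraj <- fixed[["nTraj"]]
    }
    if (is.null(T) || is.null(nTraj))
        stop("custom regime requires explicit T and nTraj")
    structure(list(regime = regime, AX = AX, AY = AY, KM = KM, B = B,
                   tauX = tauX, tauY = tauY, sigmaE = sigmaE,
                   nTraj = as.integer(nTraj), T = as.integer(T),
                   seed = as.integer(seed)),
              class = "ExperimentConfig")
}

#' Generate a synthetic benchmark dataset
#'
#' Simulates the two-step activation model exactly (delayed SSA -- the
#' generative process is deliberately distinct from the tau-leaping
#' approximation used inside the inference engine) and corrupts the
#' observed reporter series with independent Gaussian noise of variance
#' Y(t) + sigmaE at every grid point, including t = 0.  Noise is applied
#' only to the observed species; ground-truth trajectories and reaction
#' counts are returned for recovery scoring.  Measurements are left
#' unbounded (they can undershoot 0 at low counts).
#'
#' @param cfg An \code{\link{experimentConfig}}.
#' @return List with elements \code{observations}
#'   (\linkS4class{ObservationSet} of noisy Y series), \code{trajectories}
#'   (list of ground-truth species x time matrices), \code{counts} (list
#'   of ground-truth reaction-count matrices), \code{net} (the generative
#'   \linkS4class{DelayedNetwork}) and \code{config}.
#' @examples
#' cfg <- experimentConfig("custom", nTraj = 2, T = 20, seed = 1)
#' ds <- generateDataset(cfg)
#' ds$observations
#' @export
generateDataset <- function(cfg) {
    stopifnot(inherits(cfg, "ExperimentConfig"))
    net <- buildTwoStepModel(cfg$AX, cfg$AY, cfg$KM, cfg$B,
                             delayX = cfg$tauX, delayY = cfg$tauY)
    obsIdx <- which(net@observed)
    obs <- vector("list", cfg$nTraj)
    trajs <- vector("list", cfg$nTraj)
    counts <- vector("list", cfg$nTraj)
    for (i in seq_len(cfg$nTraj)) {
        sim <- simulateDelayedSSA(net, cfg$T, seed = cfg$seed + i - 1L)
        trajs[[i]] <- sim$trajectory
        counts[[i]] <- sim$counts
        y <- sim$trajectory[obsIdx, , drop = FALSE]
        obs[[i]] <- y + matrix(rnorm(length(y), sd = sqrt(y + cfg$sigmaE)),
                               nrow(y))
    }
    observations <- new("ObservationSet", data = obs,
                        species = net@species[obsIdx],
                        times = 0:cfg$T)
    list(observations = observations, trajectories = trajs,
         counts = counts, net = net, config = cfg)
}

#' Paired datasets exposing the production/Michaelis-constant degeneracy
#'
#' Generates two datasets identical in every respect except that the
#' second scales both the activator production rate and the Michaelis
#' constant by a common factor.  Because the reporter production
#' propensity depends on these parameters essentially through their
#' ratio, the resulting measurement distributions are statistically
#' indistinguishable -- the degeneracy that forces fixing the Michaelis
#' constant during inference.
#'
#' @param scale Positive scale factor applied to both parameters.
#' @param cfg Base \code{\link{experimentConfig}}.
#' @return List with elements \code{base}, \code{scaled} (datasets as
#'   from \code{\link{generateDataset}}) and \code{scale}.
#' @export
degeneracyDataset <- function(scale,
                              cfg = experimentConfig("steady_state")) {
    stopifnot(is.numeric(scale), scale > 0)
    cfg2 <- cfg
    cfg2$AX <- cfg$AX * scale
    cfg2$KM <- cfg$KM * scale
    list(base = generateDataset(cfg), scaled = generateDataset(cfg2),
         scale = scale)
}

#' Paired datasets with the same total delay split differently
#'
#' The reporter dynamics depend on the regulation and maturation delays
#' only through their sum.  This generator produces one dataset with the
#' delay split evenly (Gamma(3.6, 0.6) + Gamma(3.6, 0.6): 6 + 6 min) and
#' one with the same total mean split unevenly (Gamma(1.2, 0.6) +
#' Gamma(6.0, 0.6): 2 + 10 min).  With equal Gamma rates the two summed
#' delay distributions are exactly equal (Gamma additivity), so the
#' datasets agree in distribution -- only the sum of the delays is
#' identifiable.
#'
#' @param cfg Base \code{\link{experimentConfig}} (its \code{tauX},
#'   \code{tauY} are overridden).
#' @return List with elements \code{even} and \code{uneven}, each a
#'   dataset as from \code{\link{generateDataset}}.
#' @export
delaySplitDataset <- function(cfg = experimentConfig("steady_state")) {
    cfgE <- cfg
    cfgE$tauX <- gammaDelay(3.6, 0.6)
    cfgE$tauY <- gammaDelay(3.6, 0.6)
    cfgU <- cfg
    cfgU$tauX <- gammaDelay(1.2, 0.6)
    cfgU$tauY <- gammaDelay(6.0, 0.6)
    list(even = generateDataset(cfgE), uneven = generateDataset(cfgU))
}
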