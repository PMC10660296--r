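#' @include simulate.R
NULL

#' Gaussian observation model with count-dependent variance
#'
#' Measurements of an observed species with true count y carry additive
#' Gaussian noise with mean 0 and variance y + sigmaE: the Poisson-like
#' part scales with the signal, and sigmaE is a constant noise floor
#' (count^2 units).
#'
#' @slot sigmaE Nonnegative noise offset.
#' @export
setClass("ObservationModel", representation(sigmaE = "numeric"))

setValidity("ObservationModel", function(object) {
    if (length(object@sigmaE) != 1L || !is.finite(object@sigmaE) ||
        object@sigmaE < 0)
        return("sigmaE must be a single nonnegative number")
    TRUE
})

#' @rdname ObservationModel-class
#' @param sigmaE Nonnegative noise offset (count^2 units).
#' @return \code{observationModel} returns an
#'   \linkS4class{ObservationModel}.
#' @export
observationModel <- function(sigmaE = 10) {
    new("ObservationModel", sigmaE = sigmaE)
}

.asSigmaE <- function(om) {
    if (is(om, "ObservationModel")) om@sigmaE else as.numeric(om)
}

#' Interpolated completion propensity along a trajectory
#'
#' The completion propensity of a delayed reaction is the delay-weighted
#' average of past initiation propensities.  On the unit measurement
#' grid it is approximated by linearly interpolating the initiation
#' propensity between grid states and integrating against the delay
#' distribution over each interval, which reduces to a lag-weight
#' convolution: \code{fhat_k(i) = sum_j w_k[j+1] h_k(z(i-j))} with
#' weights from \code{\link{delayWeights}} (trapezoid rule
#' \code{(h(z(i-1)) + h(z(i)))/2} for an undelayed reaction).  Delay mass
#' at lags beyond \code{i} is dropped for early intervals, since
#' initiations cannot predate time 0.
#'
#' @param net A \linkS4class{DelayedNetwork}.
#' @param trajectory Species x (T+1) count matrix on the grid 0..T.
#' @param weights Optional precomputed per-reaction lag weights.
#' @return Reactions x T matrix of completion propensities; the entry
#'   for interval i is also the integral of the interpolated propensity
#'   over (i-1, i], so row sums give each reaction's cumulative hazard.
#' @export
completionPropensity <- function(net, trajectory, weights = NULL) {
    stopifnot(is(net, "DelayedNetwork"))
    if (is.null(weights))
        weights <- lapply(net@reactions, function(rx)
            delayWeights(realizedDelay(rx, net@params)))
    H <- .propensityMatrix(net, trajectory)
    out <- cpp_fhat(H, weights)
    dimnames(out) <- .countDimnames(net, ncol(trajectory) - 1L)
    out
}

#' Approximate log-likelihood of per-interval reaction counts
#'
#' The approximate likelihood of the kinetic and delay parameters given a
#' discretely observed trajectory treats the completion counts of each
#' reaction in each unit interval as Poisson with mean equal to the
#' interpolated completion propensity, subject to the indicator that the
#' trajectory is exactly the stoichiometric reconstruction of the counts.
#' Because the per-interval propensity already integrates the
#' interpolated completion propensity over its interval, the total
#' cumulative hazard is simply the sum of all per-interval propensities,
#' and the likelihood is an exact product of Poisson probabilities.
#'
#' @param counts Reactions x T completion-count matrix.
#' @param trajectory Species x (T+1) count matrix consistent with
#'   \code{counts} (otherwise the log-likelihood is \code{-Inf}).
#' @param net A \linkS4class{DelayedNetwork}.
#' @param weights,fhat Optional precomputed lag weights / completion
#'   propensity matrix.
#' @return Log-likelihood (\code{-Inf} when the indicator fails or a
#'   zero-propensity cell has a positive count).
#' @export
approxLogLikelihood <- function(counts, trajectory, net, weights = NULL,
                                fhat = NULL) {
    if (!chiConsistent(net, counts, trajectory)) return(-Inf)
    if (is.null(fhat))
        fhat <- completionPropensity(net, trajectory, weights)
    stopifnot(identical(dim(fhat), dim(counts)))
    r <- as.numeric(counts)
    f <- as.numeric(fhat)
    zero <- f <= 0
    if (any(zero & r > 0)) return(-Inf)
    keep <- !zero
    sum(r[keep] * log(f[keep]) - lgamma(r[keep] + 1)) - sum(f)
}

#' Log-likelihood of noisy observations given a trajectory
#'
#' Independent Gaussian noise at every grid point (including t = 0) with
#' variance y(t) + sigmaE, summed over all observed species and times.
#'
#' @param y True counts of the observed species: numeric vector or
#'   species x time matrix.
#' @param yobs Noisy measurements, same shape as \code{y}.
#' @param om An \linkS4class{ObservationModel} or a bare sigmaE value.
#' @return Log-likelihood.
#' @export
observationLogLikelihood <- function(y, yobs, om) {
    sigmaE <- .asSigmaE(om)
    y <- as.numeric(y)
    yobs <- as.numeric(yobs)
    stopifnot(length(y) == length(yobs))
    v <- y + sigmaE
    if (any(v <= 0))
        stop("degenerate observation variance: y + sigmaE must be positive")
    sum(dnorm(yobs, mean = y, sd = sqrt(v), log = TRUE))
}

#' Joint log-likelihood of counts and noisy observations
#'
#' Reconstructs the latent trajectories of all species from the reaction
#' counts (the counts determine the trajectory uniquely, so the sum over
#' latent trajectories collapses to one term) and returns the sum of the
#' observation log-likelihood of the observed species and the
#' approximate count log-likelihood; \code{-Inf} if the reconstruction
#' hits a negative state.
#'
#' @inheritParams approxLogLikelihood
#' @param yobs Observed-species x (T+1) matrix (or vector for a single
#'   observed species) of noisy measurements.
#' @param om An \linkS4class{ObservationModel} or a sigmaE value.
#' @return Log-likelihood.
#' @export
jointLogLikelihood <- function(counts, net, yobs, om, weights = NULL) {
    z <- reconstructTrajectory(net, counts)
    if (any(z < 0L)) return(-Inf)
    y <- z[net@observed, , drop = FALSE]
    if (!is.matrix(yobs)) yobs <- matrix(yobs, nrow = 1L)
    observationLogLikelihood(y, yobs, om) +
        approxLogLikelihood(counts, z, net, weights = weights)
}
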