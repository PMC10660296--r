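#' @include network.R
NULL

.trajDimnames <- function(net, T) {
    list(net@species, as.character(0:T))
}

.countDimnames <- function(net, T) {
    list(vapply(net@reactions, slot, "", "name"), as.character(seq_len(T)))
}

#' Exact simulation of a delayed reaction network (delayed SSA)
#'
#' Event-driven simulation: initiation times are exponential in the total
#' initiation propensity; initiating a delayed reaction consumes its
#' reactants immediately and schedules product delivery after a random
#' delay on a pending queue (simultaneous completions are processed in
#' initiation order).  Undelayed reactions fire instantly.  The state is
#' sampled on the integer grid 0..T and completions are binned into the
#' unit intervals (i-1, i].  Reactions still pending at T never complete
#' within the observation window and are reported separately.
#'
#' @param net A \linkS4class{DelayedNetwork}.
#' @param T Final time (positive integer, in grid units).
#' @param nTraj Number of independent trajectories.
#' @param seed Optional integer; trajectory \code{i} uses stream
#'   \code{seed + i - 1} so parallel generation is reproducible.
#' @return For \code{nTraj = 1} a list with elements \code{trajectory}
#'   (species x time matrix on 0..T), \code{counts} (reactions x T
#'   per-interval completion counts), \code{eventLog} (data.frame with
#'   \code{t_init}, \code{t_complete}, \code{reaction}) and
#'   \code{pending} (reactions in flight at T).  For \code{nTraj > 1}, a
#'   list of such lists.
#' @examples
#' net <- buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0.05)
#' sim <- simulateDelayedSSA(net, T = 20, seed = 1)
#' sim$trajectory[, 1:6]
#' @export
simulateDelayedSSA <- function(net, T, nTraj = 1L, seed = NULL) {
    stopifnot(is(net, "DelayedNetwork"), T >= 1, T == round(T))
    cmp <- .compileNetwork(net)
    one <- function(i) {
        if (!is.null(seed)) set.seed(seed + i - 1L)
        res <- cpp_ssa(cmp$reactant, cmp$netchange, cmp$propType, cmp$rate,
                       cmp$K, cmp$subs, cmp$delayShapes, cmp$delayRates,
                       cmp$z0, as.integer(T))
        dimnames(res$traj) <- .trajDimnames(net, T)
        dimnames(res$counts) <- .countDimnames(net, T)
        list(trajectory = res$traj, counts = res$counts,
             eventLog = data.frame(t_init = res$event_init,
                                   t_complete = res$event_complete,
                                   reaction = res$event_type),
             pending = data.frame(t_init = res$pending_init,
                                  t_complete = res$pending_complete,
                                  reaction = res$pending_type))
    }
    if (nTraj == 1L) one(1L) else lapply(seq_len(nTraj), one)
}

#' Approximate simulation by delayed tau-leaping on the measurement grid
#'
#' For each unit interval and reaction, the number of completions is
#' drawn from a Poisson distribution whose mean is the interpolated
#' completion propensity (the same quantity the approximate likelihood
#' uses), evaluated from the trajectory simulated so far.  Counts that
#' would drive a species negative are redrawn from the Poisson truncated
#' to the feasible range, so the reconstruction indicator always holds.
#' Delayed reactions must be pure production (no reactants); the delayed
#' SSA has no such restriction.
#'
#' @inheritParams simulateDelayedSSA
#' @param weights Optional precomputed per-reaction lag weights (list of
#'   numeric vectors from \code{\link{delayWeights}}); computed from the
#'   network's current parameters when omitted.
#' @return As \code{\link{simulateDelayedSSA}} but without an event log:
#'   elements \code{trajectory} and \code{counts}.
#' @export
simulateTauLeaping <- function(net, T, nTraj = 1L, seed = NULL,
                               weights = NULL) {
    stopifnot(is(net, "DelayedNetwork"), T >= 1, T == round(T))
    cmp <- .compileNetwork(net, weights = is.null(weights))
    if (!is.null(weights)) cmp$weights <- weights
    for (k in seq_along(net@reactions)) {
        rx <- net@reactions[[k]]
        if (length(rx@delayShapeLabels) && any(rx@reactants > 0L))
            stop("tau-leaping supports delayed reactions only without ",
                 "reactants (reaction '", rx@name, "')")
    }
    one <- function(i) {
        if (!is.null(seed)) set.seed(seed + i - 1L)
        res <- cpp_tau_leap(cmp$reactant, cmp$netchange, cmp$propType,
                            cmp$rate, cmp$K, cmp$subs, cmp$weights,
                            cmp$z0, as.integer(T))
        dimnames(res$traj) <- .trajDimnames(net, T)
        dimnames(res$counts) <- .countDimnames(net, T)
        list(trajectory = res$traj, counts = res$counts)
    }
    if (nTraj == 1L) one(1L) else lapply(seq_len(nTraj), one)
}

#' Reconstruct a trajectory from per-interval reaction counts
#'
#' Applies the cumulative net stoichiometric change of the completion
#' counts to the initial state: z(i) = z(0) + sum over reactions of
#' (products - reactants) times the cumulative counts up to interval i.
#'
#' @param net A \linkS4class{DelayedNetwork}.
#' @param counts Reactions x T matrix of completion counts.
#' @return Species x (T+1) integer matrix.
#' @seealso \code{\link{chiConsistent}}
#' @export
reconstructTrajectory <- function(net, counts) {
    S <- netChangeMatrix(net)                  # reactions x species
    T <- ncol(counts)
    cum <- apply(counts, 1L, cumsum)           # T x reactions
    if (T == 1L) cum <- matrix(cum, nrow = 1L)
    z <- t(cum %*% S)                          # species x T
    z <- cbind(net@initState, z + net@initState)
    storage.mode(z) <- "integer"
    dimnames(z) <- .trajDimnames(net, T)
    z
}

#' Reconstruction indicator between counts and a trajectory
#'
#' TRUE when the trajectory is exactly the stoichiometric reconstruction
#' of the counts and every reconstructed state is nonnegative -- the
#' indicator factor of the approximate count likelihood.
#'
#' @inheritParams reconstructTrajectory
#' @param trajectory Species x (T+1) matrix to compare against.
#' @return Logical scalar.
#' @export
chiConsistent <- function(net, counts, trajectory) {
    z <- reconstructTrajectory(net, counts)
    all(z >= 0L) && all(z == trajectory)
}

## Initiation propensities H (reactions x 0..T) along a trajectory.
.propensityMatrix <- function(net, trajectory) {
    v <- length(net@reactions)
    H <- matrix(0, v, ncol(trajectory))
    for (k in seq_len(v))
        H[k, ] <- reactionPropensity(net, k, trajectory)
    H
}
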