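#' @include delay-distributions.R
NULL

#' Define a reaction for a delayed network
#'
#' Helper building a \linkS4class{Reaction} together with default
#' parameter values.  Rate-type arguments may be given either as a bare
#' number (a parameter label is generated from the reaction name) or as
#' a named length-1 numeric (the name becomes the shared parameter
#' label), so that several reactions can be tied to one parameter, e.g. a
#' common dilution rate.
#'
#' @param name Reaction name.
#' @param reactants,products Named integer vectors of stoichiometric
#'   coefficients (names = species); species omitted get coefficient 0.
#' @param form Propensity form: \code{"constant"} (h = rate),
#'   \code{"mass_action_linear"} (h = rate * z\[substrate\]) or
#'   \code{"michaelis_menten"} (h = rate * z / (K + z)).
#' @param rate Rate parameter (number or named number).
#' @param K Michaelis constant (only for \code{"michaelis_menten"}).
#' @param substrate Substrate species name (required unless
#'   \code{form == "constant"}).
#' @param delay A \linkS4class{DelayDistribution}; defaults to no delay.
#'   Component shapes/rates may be named via \code{delayLabels}.
#' @param delayLabels Optional character matrix-like list with elements
#'   \code{shapes} and \code{rates}: labels for the delay components.
#' @return A list with elements \code{reaction} (the
#'   \linkS4class{Reaction}) and \code{defaults} (named numeric of
#'   parameter values introduced by this reaction), consumed by
#'   \code{\link{delayedNetwork}}.
#' @export
reaction <- function(name, reactants = c(), products = c(),
                     form = c("constant", "mass_action_linear",
                              "michaelis_menten"),
                     rate, K = NULL, substrate = NULL,
                     delay = noDelay(), delayLabels = NULL) {
    form <- match.arg(form)
    lab <- function(x, default) {
        if (!is.null(names(x)) && nzchar(names(x)[1L])) names(x)[1L]
        else default
    }
    defaults <- c()
    rateLabel <- lab(rate, paste0(name, ".rate"))
    defaults[rateLabel] <- unname(rate)
    kLabel <- character(0)
    if (form == "michaelis_menten") {
        if (is.null(K)) stop("michaelis_menten requires K")
        kLabel <- lab(K, paste0(name, ".K"))
        defaults[kLabel] <- unname(K)
    }
    dsl <- character(0)
    drl <- character(0)
    if (delay@family != "dirac_zero") {
        nc <- length(delay@shapes)
        if (is.null(delayLabels)) {
            sfx <- if (nc > 1L) seq_len(nc) else ""
            dsl <- paste0(name, ".delay.shape", sfx)
            drl <- paste0(name, ".delay.rate", sfx)
        } else {
            dsl <- delayLabels$shapes
            drl <- delayLabels$rates
            stopifnot(length(dsl) == nc, length(drl) == nc)
        }
        defaults[dsl] <- delay@shapes
        defaults[drl] <- delay@rates
    }
    rx <- list(name = name, propensityForm = form, rateLabel = rateLabel,
               kLabel = kLabel, delayShapeLabels = dsl,
               delayRateLabels = drl)
    list(reaction = rx, defaults = defaults,
         reactantSpec = reactants, productSpec = products,
         substrateSpec = substrate)
}

.stoichVector <- function(spec, species, what, name) {
    v <- integer(length(species))
    names(v) <- species
    if (length(spec)) {
        if (is.null(names(spec)) || any(!nzchar(names(spec))))
            stop(sprintf("reaction '%s': %s must be a named vector", name,
                         what))
        unknown <- setdiff(names(spec), species)
        if (length(unknown))
            stop(sprintf("reaction '%s': unknown species %s", name,
                         paste(unknown, collapse = ", ")))
        if (any(spec < 0) || any(spec != round(spec)))
            stop(sprintf("reaction '%s': %s must be nonnegative integers",
                         name, what))
        v[names(spec)] <- as.integer(spec)
    }
    v
}

#' Assemble a delayed reaction network
#'
#' @param species Character vector of species names.
#' @param reactions List of reaction specs from \code{\link{reaction}}.
#' @param initState Named (or positional) integer vector of initial copy
#'   numbers; defaults to all zero (induction at time 0 with an empty
#'   pending-reaction queue).
#' @param observed Character vector naming the observed species.
#' @param params Optional named numeric overriding reaction defaults.
#' @return A \linkS4class{DelayedNetwork}.
#' @examples
#' net <- delayedNetwork(
#'   species = "Z",
#'   reactions = list(
#'     reaction("birth", products = c(Z = 1), form = "constant", rate = 5),
#'     reaction("death", reactants = c(Z = 1), form = "mass_action_linear",
#'              rate = 0.1, substrate = "Z")),
#'   observed = "Z")
#' @export
delayedNetwork <- function(species, reactions, initState = NULL,
                           observed = species, params = c()) {
    u <- length(species)
    vals <- c()
    rxs <- vector("list", length(reactions))
    for (i in seq_along(reactions)) {
        spec <- reactions[[i]]
        r <- spec$reaction
        substrate <- integer(0)
        if (r$propensityForm != "constant") {
            if (is.null(spec$substrateSpec))
                stop(sprintf("reaction '%s': substrate required", r$name))
            idx <- match(spec$substrateSpec, species)
            if (is.na(idx))
                stop(sprintf("reaction '%s': unknown substrate '%s'",
                             r$name, spec$substrateSpec))
            substrate <- idx
        }
        rx <- new("Reaction", name = r$name,
                  reactants = .stoichVector(spec$reactantSpec, species,
                                            "reactants", r$name),
                  products = .stoichVector(spec$productSpec, species,
                                           "products", r$name),
                  propensityForm = r$propensityForm,
                  rateLabel = r$rateLabel, kLabel = r$kLabel,
                  substrate = substrate,
                  delayShapeLabels = r$delayShapeLabels,
                  delayRateLabels = r$delayRateLabels)
        clash <- intersect(names(spec$defaults), names(vals))
        for (lb in clash)
            if (vals[lb] != spec$defaults[lb])
                stop(sprintf("conflicting default values for shared '%s'", lb))
        vals[setdiff(names(spec$defaults), names(vals))] <-
            spec$defaults[setdiff(names(spec$defaults), names(vals))]
        rxs[[i]] <- rx
    }
    vals[names(params)] <- params
    if (is.null(initState)) initState <- integer(u)
    if (!is.null(names(initState))) {
        z0 <- integer(u)
        names(z0) <- species
        z0[names(initState)] <- as.integer(initState)
        initState <- z0
    }
    ps <- new("ParameterSet", values = vals,
              free = setNames(rep(FALSE, length(vals)), names(vals)))
    net <- new("DelayedNetwork", species = species,
               observed = species %in% observed, reactions = rxs,
               initState = as.integer(initState), params = ps)
    validObject(net)
    net
}

#' Built-in two-step activation model
#'
#' The canonical partially observed gene-regulation motif: an unobserved
#' activator X is produced at constant rate \code{AX} and diluted at rate
#' \code{B}; X drives production of an observed reporter Y through a
#' Michaelis-Menten propensity \code{AY * X / (KM + X)}; each initiated Y
#' molecule becomes observable only after the regulation delay
#' (\code{delayX}) plus the maturation delay (\code{delayY}), composed as
#' one delayed reaction whose delay is the sum of the two independent
#' Gamma delays; Y is diluted at the same rate \code{B}.  X production is
#' undelayed: upstream sequential steps are absorbed into the regulation
#' delay.
#'
#' Parameter labels are \code{AX}, \code{AY}, \code{KM}, \code{B},
#' \code{alphaX}/\code{betaX} and \code{alphaY}/\code{betaY} (Gamma shape
#' and rate of the two delay components).
#'
#' @param AX Production rate of X (1/min).
#' @param AY Maximal production rate of Y (1/min).
#' @param KM Michaelis constant (copy number).
#' @param B Shared dilution rate (1/min).
#' @param delayX,delayY \linkS4class{DelayDistribution}s for the
#'   regulation and maturation delay (single Gamma components).
#' @param x0,y0 Initial copy numbers.
#' @return A \linkS4class{DelayedNetwork} with species \code{X}
#'   (unobserved) and \code{Y} (observed).
#' @examples
#' net <- buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0.05,
#'                          delayX = gammaDelay(18/5, 3/5),
#'                          delayY = gammaDelay(18/5, 3/5))
#' net
#' @export
buildTwoStepModel <- function(AX, AY, KM, B,
                              delayX = gammaDelay(18 / 5, 3 / 5),
                              delayY = gammaDelay(18 / 5, 3 / 5),
                              x0 = 0, y0 = 0) {
    for (v in c(AX = AX, AY = AY, KM = KM, B = B))
        if (!is.finite(v) || v <= 0)
            stop("all rates must be finite and strictly positive")
    if (x0 < 0 || y0 < 0 || x0 != round(x0) || y0 != round(y0))
        stop("initial counts must be nonnegative integers")
    stopifnot(is(delayX, "DelayDistribution"), is(delayY, "DelayDistribution"),
              delayX@family %in% c("gamma", "dirac_zero"),
              delayY@family %in% c("gamma", "dirac_zero"))
    dSum <- combineDelays(delayX, delayY)
    labs <- list(shapes = c("alphaX", "alphaY")[
                     c(delayX@family == "gamma", delayY@family == "gamma")],
                 rates = c("betaX", "betaY")[
                     c(delayX@family == "gamma", delayY@family == "gamma")])
    delayedNetwork(
        species = c("X", "Y"),
        reactions = list(
            reaction("prodX", products = c(X = 1), form = "constant",
                     rate = c(AX = AX)),
            reaction("degX", reactants = c(X = 1),
                     form = "mass_action_linear", rate = c(B = B),
                     substrate = "X"),
            reaction("prodY", products = c(Y = 1),
                     form = "michaelis_menten", rate = c(AY = AY),
                     K = c(KM = KM), substrate = "X",
                     delay = dSum, delayLabels = labs),
            reaction("degY", reactants = c(Y = 1),
                     form = "mass_action_linear", rate = c(B = B),
                     substrate = "Y")),
        initState = c(X = x0, Y = y0),
        observed = "Y")
}

## ---- accessors ----------------------------------------------------------

#' @rdname DelayedNetwork-class
#' @export
setMethod("speciesNames", "DelayedNetwork", function(x) x@species)

#' @rdname DelayedNetwork-class
#' @export
setMethod("observedSpecies", "DelayedNetwork",
          function(x) x@species[x@observed])

#' @rdname DelayedNetwork-class
#' @export
setMethod("reactions", "DelayedNetwork", function(x) x@reactions)

#' @rdname DelayedNetwork-class
#' @export
setMethod("initialState", "DelayedNetwork",
          function(x) setNames(x@initState, x@species))

#' Parameter access for delayed networks
#'
#' \code{parameters} returns the \linkS4class{ParameterSet};
#' \code{parameterValues} its named numeric values;
#' \code{freeParameters} the names of free parameters.  The replacement
#' forms update values (positivity enforced) and the free mask.
#'
#' @param x A \linkS4class{DelayedNetwork} or \linkS4class{ParameterSet}.
#' @name parameters
NULL

#' @rdname parameters
#' @export
setMethod("parameters", "DelayedNetwork", function(x) x@params)

#' @rdname parameters
#' @export
setMethod("parameters<-", "DelayedNetwork", function(x, value) {
    stopifnot(is(value, "ParameterSet"))
    x@params <- value
    validObject(x)
    x
})

#' @rdname parameters
#' @export
setMethod("parameterValues", "DelayedNetwork", function(x) x@params@values)

#' @rdname parameters
#' @export
setMethod("parameterValues", "ParameterSet", function(x) x@values)

#' @rdname parameters
#' @export
setMethod("freeParameters", "DelayedNetwork",
          function(x) names(which(x@params@free)))

#' @rdname parameters
#' @export
setMethod("freeParameters<-", "DelayedNetwork", function(x, value) {
    unknown <- setdiff(value, names(x@params@values))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    x@params@free <- setNames(names(x@params@values) %in% value,
                              names(x@params@values))
    x
})

#' Update parameter values of a network
#'
#' @param net A \linkS4class{DelayedNetwork}.
#' @param ... Named scalar values, or a single named numeric vector.
#' @return The network with updated parameter values.
#' @export
setParameterValues <- function(net, ...) {
    upd <- c(...)
    unknown <- setdiff(names(upd), names(net@params@values))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    if (any(upd <= 0) || any(!is.finite(upd)))
        stop("parameter values must be finite and strictly positive")
    net@params@values[names(upd)] <- upd
    net
}

## ---- propensities and delays -------------------------------------------

#' Delay distribution of a reaction under given parameters
#'
#' @param rx A \linkS4class{Reaction}.
#' @param ps A \linkS4class{ParameterSet}.
#' @return The realized \linkS4class{DelayDistribution}.
#' @export
realizedDelay <- function(rx, ps) {
    if (length(rx@delayShapeLabels) == 0L) return(noDelay())
    shapes <- unname(ps@values[rx@delayShapeLabels])
    rates <- unname(ps@values[rx@delayRateLabels])
    if (length(shapes) == 1L) gammaDelay(shapes, rates)
    else gammaSumDelay(shapes, rates)
}

#' Initiation propensity of a reaction at a state
#'
#' Evaluates h_k(z) for the three supported propensity forms.  The
#' Michaelis-Menten form \code{A * z / (K + z)} is 0 at z = 0 and tends
#' to A as z grows.
#'
#' @param net A \linkS4class{DelayedNetwork}.
#' @param k Reaction index or name.
#' @param state Numeric state vector (copy numbers), or a matrix with one
#'   state per column.
#' @return Propensity value(s), nonnegative.
#' @export
reactionPropensity <- function(net, k, state) {
    if (is.character(k))
        k <- match(k, vapply(net@reactions, slot, "", "name"))
    rx <- net@reactions[[k]]
    ps <- net@params@values
    rate <- ps[[rx@rateLabel]]
    if (is.matrix(state)) z <- state[if (length(rx@substrate)) rx@substrate
                                     else 1L, ]
    else z <- state[if (length(rx@substrate)) rx@substrate else 1L]
    unname(switch(rx@propensityForm,
                  constant = rep(rate, length(z)),
                  mass_action_linear = rate * z,
                  michaelis_menten = rate * z / (ps[[rx@kLabel]] + z)))
}

## Human-readable reaction equation, for show().
reactionEquation <- function(net, rx) {
    side <- function(coef) {
        nz <- which(coef > 0L)
        if (!length(nz)) return("0")
        paste(ifelse(coef[nz] > 1L, paste0(coef[nz], " "), ""),
              net@species[nz], sep = "", collapse = " + ")
    }
    paste(side(rx@reactants), "->", side(rx@products))
}

## Net stoichiometric change matrix (reactions x species).
netChangeMatrix <- function(net) {
    matrix(unlist(lapply(net@reactions,
                         function(rx) rx@products - rx@reactants)),
           nrow = length(net@reactions), byrow = TRUE,
           dimnames = list(vapply(net@reactions, slot, "", "name"),
                           net@species))
}

## Compiled representation handed to the C++ simulators: resolves labels
## to numbers and delay distributions to component vectors / lag weights.
.compileNetwork <- function(net, weights = FALSE, step = 0.01,
                            tol = 1e-8, maxSupport = 1000) {
    ps <- net@params@values
    v <- length(net@reactions)
    u <- length(net@species)
    formCode <- c(constant = 0L, mass_action_linear = 1L,
                  michaelis_menten = 2L)
    out <- list(
        reactant = matrix(0L, v, u), netchange = matrix(0L, v, u),
        propType = integer(v), rate = numeric(v), K = numeric(v),
        subs = integer(v), delayShapes = vector("list", v),
        delayRates = vector("list", v), weights = vector("list", v))
    for (k in seq_len(v)) {
        rx <- net@reactions[[k]]
        out$reactant[k, ] <- rx@reactants
        out$netchange[k, ] <- rx@products - rx@reactants
        out$propType[k] <- formCode[[rx@propensityForm]]
        out$rate[k] <- ps[[rx@rateLabel]]
        out$K[k] <- if (length(rx@kLabel)) ps[[rx@kLabel]] else 0
        out$subs[k] <- if (length(rx@substrate)) rx@substrate - 1L else 0L
        d <- realizedDelay(rx, net@params)
        out$delayShapes[[k]] <- d@shapes
        out$delayRates[[k]] <- d@rates
        if (weights)
            out$weights[[k]] <- delayWeights(d, step = step, tol = tol,
                                             maxSupport = maxSupport)
    }
    out$z0 <- net@initState
    out
}
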