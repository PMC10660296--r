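#' @include AllGenerics.R
NULL

#' Delay distribution of a reaction
#'
#' Describes the random time between initiation and completion of a
#' reaction.  Supported families are \code{"dirac_zero"} (no delay: the
#' Dirac measure at 0), \code{"gamma"} (a single Gamma component) and
#' \code{"sum_of_gammas"} (the sum of independent Gamma components, e.g.
#' a regulation delay followed by a maturation delay).
#'
#' @slot family Character scalar, one of \code{"dirac_zero"},
#'   \code{"gamma"}, \code{"sum_of_gammas"}.
#' @slot shapes,rates Numeric vectors of per-component Gamma shape and
#'   rate parameters (length 0 for \code{"dirac_zero"}, 1 for
#'   \code{"gamma"}).
#'
#' @seealso \code{\link{gammaDelay}}, \code{\link{gammaSumDelay}},
#'   \code{\link{noDelay}}, \code{\link{delayMean}}, \code{\link{delayCDF}}
#' @export
setClass("DelayDistribution",
         representation(family = "character",
                        shapes = "numeric",
                        rates  = "numeric"))

setValidity("DelayDistribution", function(object) {
    fam <- object@family
    if (length(fam) != 1L ||
        !fam %in% c("dirac_zero", "gamma", "sum_of_gammas"))
        return("family must be one of 'dirac_zero', 'gamma', 'sum_of_gammas'")
    ns <- length(object@shapes)
    if (ns != length(object@rates))
        return("shapes and rates must have equal length")
    if (fam == "dirac_zero" && ns != 0L)
        return("dirac_zero carries no Gamma components")
    if (fam == "gamma" && ns != 1L)
        return("gamma family requires exactly one (shape, rate) pair")
    if (fam == "sum_of_gammas" && ns < 2L)
        return("sum_of_gammas requires at least two components")
    if (ns > 0L && (any(!is.finite(object@shapes)) ||
                    any(!is.finite(object@rates)) ||
                    any(object@shapes <= 0) || any(object@rates <= 0)))
        return("all Gamma shapes and rates must be finite and > 0")
    TRUE
})

#' Kinetic and delay parameters with a free/fixed mask
#'
#' A flat table of strictly positive scalars keyed by label (e.g.
#' \code{"AX"}, \code{"B"}, \code{"betaX"}), shared across reactions that
#' reference the same label, together with a logical mask marking which
#' entries are free during inference.  Fixed entries never change.
#'
#' @slot values Named numeric vector of parameter values.
#' @slot free Named logical vector over the same names.
#' @export
setClass("ParameterSet",
         representation(values = "numeric", free = "logical"))

setValidity("ParameterSet", function(object) {
    nm <- names(object@values)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
        return("parameter values must have unique non-empty names")
    if (!identical(sort(nm), sort(names(object@free))))
        return("free mask must cover exactly the parameter names")
    if (any(!is.finite(object@values)) || any(object@values <= 0))
        return("all parameters must be finite and strictly positive")
    TRUE
})

#' A single (possibly delayed) reaction
#'
#' Reactions are defined by nonnegative integer reactant and product
#' stoichiometries, an initiation propensity of one of three forms
#' (\code{"constant"}, \code{"mass_action_linear"},
#' \code{"michaelis_menten"}), and a delay distribution between
#' initiation and completion.  Numeric parameters are referenced by label
#' into the network's \linkS4class{ParameterSet}, so that several
#' reactions can share one parameter (e.g. a common dilution rate).
#'
#' @slot name Reaction name.
#' @slot reactants,products Integer stoichiometry vectors (length = number
#'   of species in the network).
#' @slot propensityForm One of \code{"constant"},
#'   \code{"mass_action_linear"}, \code{"michaelis_menten"}.
#' @slot rateLabel Label of the rate parameter (the constant rate, the
#'   mass-action rate, or the Michaelis-Menten maximal rate).
#' @slot kLabel Label of the Michaelis constant (\code{character(0)}
#'   unless Michaelis-Menten).
#' @slot substrate Index of the substrate species (\code{integer(0)} for
#'   constant propensity).
#' @slot delayShapeLabels,delayRateLabels Labels of the Gamma shape and
#'   rate parameters of the delay components (\code{character(0)} for an
#'   undelayed reaction).
#' @export
setClass("Reaction",
         representation(name = "character",
                        reactants = "integer",
                        products = "integer",
                        propensityForm = "character",
                        rateLabel = "character",
                        kLabel = "character",
                        substrate = "integer",
                        delayShapeLabels = "character",
                        delayRateLabels = "character"))

setValidity("Reaction", function(object) {
    if (length(object@name) != 1L || object@name == "")
        return("reaction needs a non-empty name")
    if (length(object@reactants) != length(object@products))
        return("reactant and product stoichiometries differ in length")
    if (any(object@reactants < 0L) || any(object@products < 0L))
        return("stoichiometric coefficients must be nonnegative integers")
    form <- object@propensityForm
    if (length(form) != 1L ||
        !form %in% c("constant", "mass_action_linear", "michaelis_menten"))
        return("unknown propensity form")
    if (length(object@rateLabel) != 1L)
        return("exactly one rate label required")
    if (form == "michaelis_menten" && length(object@kLabel) != 1L)
        return("michaelis_menten requires a Michaelis-constant label")
    if (form != "constant" && length(object@substrate) != 1L)
        return("state-dependent propensities need a substrate index")
    if (length(object@delayShapeLabels) != length(object@delayRateLabels))
        return("delay shape and rate labels differ in length")
    TRUE
})

#' A delayed biochemical reaction network
#'
#' Species, reactions, initial state and parameters of a stochastic
#' chemical kinetics model in which reactions may complete after random
#' Gamma-distributed delays.  Each species is flagged observed or
#' unobserved; the flags induce the partition of trajectories used by the
#' observation model and the inference machinery.
#'
#' @slot species Character vector of species names.
#' @slot observed Logical vector flagging observed species.
#' @slot reactions List of \linkS4class{Reaction} objects.
#' @slot initState Integer vector of initial copy numbers.
#' @slot params A \linkS4class{ParameterSet} with values for every label
#'   referenced by the reactions.
#'
#' @seealso \code{\link{delayedNetwork}}, \code{\link{buildTwoStepModel}},
#'   \code{\link{simulateDelayedSSA}}, \code{\link{simulateTauLeaping}}
#' @export
setClass("DelayedNetwork",
         representation(species = "character",
                        observed = "logical",
                        reactions = "list",
                        initState = "integer",
                        params = "ParameterSet"))

setValidity("DelayedNetwork", function(object) {
    u <- length(object@species)
    if (u == 0L) return("network needs at least one species")
    if (anyDuplicated(object@species)) return("species names must be unique")
    if (length(object@observed) != u)
        return("observed flags must match the number of species")
    if (!any(object@observed))
        return("at least one species must be flagged observed")
    if (length(object@initState) != u || any(object@initState < 0L))
        return("initState must be nonnegative and match the species")
    if (length(object@reactions) == 0L)
        return("network needs at least one reaction")
    for (rx in object@reactions) {
        if (!is(rx, "Reaction")) return("reactions must be Reaction objects")
        if (length(rx@reactants) != u)
            return(sprintf("reaction '%s': stoichiometry length != %d",
                           rx@name, u))
        labs <- c(rx@rateLabel, rx@kLabel, rx@delayShapeLabels,
                  rx@delayRateLabels)
        missing <- setdiff(labs, names(object@params@values))
        if (length(missing))
            return(sprintf("reaction '%s': no value for parameter(s) %s",
                           rx@name, paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(vapply(object@reactions, slot, "", "name")))
        return("reaction names must be unique")
    TRUE
})

#' Noisy observations of the observed species
#'
#' Per-trajectory real-valued measurements of the observed species on the
#' discrete unit-step time grid 0..T.  Values may be negative: Gaussian
#' observation noise on small counts can undershoot zero.
#'
#' @slot data List (one element per trajectory) of numeric matrices,
#'   observed species x time points.
#' @slot species Names of the observed species (matrix row order).
#' @slot times Integer time grid 0..T shared by all trajectories.
#' @seealso \code{\link{readObservations}}, \code{\link{generateDataset}}
#' @export
setClass("ObservationSet",
         representation(data = "list", species = "character",
                        times = "integer"))

setValidity("ObservationSet", function(object) {
    if (length(object@data) == 0L) return("no trajectories")
    nt <- length(object@times)
    if (!identical(object@times, seq(object@times[1L],
                                     by = 1L, length.out = nt)))
        return("times must be consecutive integers")
    for (m in object@data) {
        if (!is.matrix(m) || !is.numeric(m))
            return("each trajectory must be a numeric matrix")
        if (nrow(m) != length(object@species) || ncol(m) != nt)
            return("trajectory matrix dimensions must be species x times")
    }
    TRUE
})

#' Posterior draws from the simulation-based MCMC
#'
#' Post burn-in, thinned draws of all free parameters together with
#' derived quantities (e.g. the mean regulation delay and the
#' production-to-Michaelis-constant ratio for the two-step model),
#' acceptance bookkeeping and a snapshot of the run configuration.
#'
#' @slot draws Numeric matrix, one row per retained draw.
#' @slot acceptance Named list of acceptance rates (per-trajectory count
#'   proposals, delay-parameter random walk).
#' @slot config List: run settings (iterations, burn-in, thinning, seed,
#'   fixed parameters, priors).
#' @seealso \code{\link{runMCMC}}, \code{\link{summarizePosterior}}
#' @export
setClass("PosteriorSamples",
         representation(draws = "matrix", acceptance = "list",
                        config = "list"))

setValidity("PosteriorSamples", function(object) {
    if (!is.numeric(object@draws) || is.null(colnames(object@draws)))
        return("draws must be a numeric matrix with column names")
    if (any(!is.finite(object@draws)))
        return("draws must be finite")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "DelayDistribution", function(object) {
    if (object@family == "dirac_zero") {
        cat("DelayDistribution: none (Dirac at 0)\n")
    } else {
        comps <- paste(sprintf("Gamma(%.4g, %.4g)", object@shapes,
                               object@rates), collapse = " + ")
        cat("DelayDistribution:", comps,
            sprintf("| mean %.4g\n", sum(object@shapes / object@rates)))
    }
})

setMethod("show", "ParameterSet", function(object) {
    cat("ParameterSet with", length(object@values), "parameters\n")
    df <- data.frame(value = object@values,
                     free = object@free[names(object@values)])
    print(df)
})

setMethod("show", "Reaction", function(object) {
    cat(sprintf("Reaction '%s' [%s], rate label '%s'%s\n",
                object@name, object@propensityForm, object@rateLabel,
                if (length(object@delayShapeLabels))
                    sprintf(", %d delay component(s)",
                            length(object@delayShapeLabels)) else ""))
})

setMethod("show", "DelayedNetwork", function(object) {
    cat(sprintf("DelayedNetwork: %d species (%s), %d reactions\n",
                length(object@species),
                paste0(object@species,
                       ifelse(object@observed, "*", ""), collapse = ", "),
                length(object@reactions)))
    cat("  (* = observed)   initial state:",
        paste(object@initState, collapse = ", "), "\n")
    for (rx in object@reactions) {
        d <- realizedDelay(rx, object@params)
        cat(sprintf("  %-8s %s  h: %s  delay mean: %.3g\n", rx@name,
                    reactionEquation(object, rx), rx@propensityForm,
                    delayMean(d)))
    }
})

setMethod("show", "ObservationSet", function(object) {
    cat(sprintf("ObservationSet: %d trajectories of %s over t = %d..%d\n",
                length(object@data),
                paste(object@species, collapse = ", "),
                object@times[1L], object@times[length(object@times)]))
})

setMethod("show", "PosteriorSamples", function(object) {
    cat(sprintf("PosteriorSamples: %d draws of %d quantities\n",
                nrow(object@draws), ncol(object@draws)))
    print(summarizePosterior(object))
})
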