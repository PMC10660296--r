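#' @include DelayedKinetics-package.R
NULL

#' Mean of a delay distribution
#'
#' For Gamma-type delays the mean is the sum of shape/rate over the
#' independent components; a degenerate (no-delay) distribution has mean 0.
#'
#' @param d A \linkS4class{DelayDistribution}.
#' @return Mean delay, in the time units of the model (minutes throughout
#'   the built-in examples).
#' @examples
#' delayMean(gammaDelay(3.6, 0.6))   # 6 minutes
#' @export
setGeneric("delayMean", function(d) standardGeneric("delayMean"))

#' Cumulative distribution function of a delay distribution
#'
#' For a single Gamma component this is the regularised lower incomplete
#' gamma function; for a sum of independent Gamma components the CDF is
#' evaluated by numerical convolution quadrature.  By convention the CDF
#' is 0 for negative times; the degenerate no-delay distribution has
#' CDF 1 for all t >= 0.
#'
#' @param d A \linkS4class{DelayDistribution}.
#' @param t Numeric vector of times.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' delayCDF(gammaDelay(1, 0.5), 2)   # exponential special case, 1 - exp(-1)
#' @export
setGeneric("delayCDF", function(d, t) standardGeneric("delayCDF"))

#' Draw random delays
#'
#' @param d A \linkS4class{DelayDistribution}.
#' @param n Number of draws.
#' @return Numeric vector of length \code{n}; uses R's global RNG stream.
#' @export
setGeneric("sampleDelay", function(d, n = 1L) standardGeneric("sampleDelay"))

#' @rdname DelayedNetwork-class
#' @param x A \linkS4class{DelayedNetwork}.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname DelayedNetwork-class
#' @export
setGeneric("observedSpecies", function(x) standardGeneric("observedSpecies"))

#' @rdname DelayedNetwork-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname DelayedNetwork-class
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' @rdname parameters
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' @rdname parameters
#' @param value Replacement value.
#' @export
setGeneric("parameters<-", function(x, value) standardGeneric("parameters<-"))

#' @rdname parameters
#' @export
setGeneric("parameterValues", function(x) standardGeneric("parameterValues"))

#' @rdname parameters
#' @export
setGeneric("freeParameters", function(x) standardGeneric("freeParameters"))

#' @rdname parameters
#' @export
setGeneric("freeParameters<-",
           function(x, value) standardGeneric("freeParameters<-"))
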