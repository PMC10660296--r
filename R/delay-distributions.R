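#' @include AllClasses.R
NULL

#' Construct delay distributions
#'
#' \code{noDelay()} is the Dirac measure at 0 (instantaneous completion).
#' \code{gammaDelay(shape, rate)} is a single Gamma component;
#' \code{gammaSumDelay(shapes, rates)} the sum of independent Gamma
#' components, e.g. a transcription/translation delay followed by a
#' maturation delay.
#'
#' @param shape,rate,shapes,rates Strictly positive Gamma parameters, in
#'   units compatible with the model time unit (rates in 1/min when time
#'   is in minutes).
#' @return A \linkS4class{DelayDistribution}.
#' @examples
#' gammaDelay(18 / 5, 3 / 5)                      # mean 6 min
#' gammaSumDelay(c(3.6, 3.6), c(0.6, 0.6))        # mean 12 min
#' @export
gammaDelay <- function(shape, rate) {
    new("DelayDistribution", family = "gamma",
        shapes = as.numeric(shape), rates = as.numeric(rate))
}

#' @rdname gammaDelay
#' @export
gammaSumDelay <- function(shapes, rates) {
    new("DelayDistribution", family = "sum_of_gammas",
        shapes = as.numeric(shapes), rates = as.numeric(rates))
}

#' @rdname gammaDelay
#' @export
noDelay <- function() {
    new("DelayDistribution", family = "dirac_zero",
        shapes = numeric(0), rates = numeric(0))
}

#' Combine two delay distributions into the delay of their sum
#'
#' The sum of independent Gamma-type delays is again a (sum of) Gamma
#' delay; combining with a no-delay distribution is the identity.
#' @param d1,d2 \linkS4class{DelayDistribution} objects.
#' @return A \linkS4class{DelayDistribution} for the summed delay.
#' @export
combineDelays <- function(d1, d2) {
    stopifnot(is(d1, "DelayDistribution"), is(d2, "DelayDistribution"))
    shapes <- c(d1@shapes, d2@shapes)
    rates <- c(d1@rates, d2@rates)
    if (length(shapes) == 0L) return(noDelay())
    if (length(shapes) == 1L) return(gammaDelay(shapes, rates))
    gammaSumDelay(shapes, rates)
}

#' @rdname delayMean
#' @export
setMethod("delayMean", "DelayDistribution", function(d) {
    if (d@family == "dirac_zero") 0 else sum(d@shapes / d@rates)
})

#' @rdname sampleDelay
#' @export
setMethod("sampleDelay", "DelayDistribution", function(d, n = 1L) {
    if (d@family == "dirac_zero") return(rep(0, n))
    out <- numeric(n)
    for (i in seq_along(d@shapes))
        out <- out + rgamma(n, shape = d@shapes[i], rate = d@rates[i])
    out
})

## Composite Simpson weights for an odd number of equally spaced points.
.simpsonWeights <- function(n, step) {
    stopifnot(n %% 2L == 1L, n >= 3L)
    w <- rep(c(2, 4), length.out = n)
    w[1L] <- 1
    w[n] <- 1
    w * step / 3
}

## Density of a sum of independent Gamma components on a uniform grid
## starting at 0, by iterated discrete (trapezoid-corrected) convolution.
## Components are convolved in order of decreasing shape so that the most
## singular component is folded in last; shapes < 1 (density unbounded at
## 0) are not supported on the convolution side.
.sumGammaDensity <- function(shapes, rates, grid, step) {
    ord <- order(shapes, decreasing = TRUE)
    shapes <- shapes[ord]
    rates <- rates[ord]
    if (any(shapes < 1))
        stop("numerical convolution requires every Gamma shape >= 1 ",
             "(density must be bounded at 0)")
    dens <- dgamma(grid, shape = shapes[1L], rate = rates[1L])
    n <- length(grid)
    L <- stats::nextn(2L * n, 2L)      # power-of-2 padding keeps fft fast
    for (i in seq_along(shapes)[-1L]) {
        comp <- dgamma(grid, shape = shapes[i], rate = rates[i])
        a <- c(dens, numeric(L - n))
        b <- c(comp, numeric(L - n))
        a[1L] <- a[1L] / 2             # trapezoid endpoint weights
        b[1L] <- b[1L] / 2
        dens <- Re(stats::fft(stats::fft(a) * stats::fft(b),
                              inverse = TRUE))[seq_len(n)] / L * step
        dens[dens < 0] <- 0            # round-off
    }
    dens
}

#' @rdname delayCDF
#' @export
setMethod("delayCDF", "DelayDistribution", function(d, t) {
    t <- as.numeric(t)
    out <- numeric(length(t))
    neg <- t < 0
    if (d@family == "dirac_zero") {
        out[!neg] <- 1
        return(out)
    }
    if (d@family == "gamma") {
        out[!neg] <- pgamma(t[!neg], shape = d@shapes, rate = d@rates)
        return(out)
    }
    ## sum of independent Gammas: F(t) = int eta_rest(s) F_last(t - s) ds,
    ## with the smallest-shape component kept exact (pgamma) and the rest
    ## folded into a grid density, integrated by composite Simpson.
    iLast <- which.min(d@shapes)
    sR <- d@shapes[-iLast]
    rR <- d@rates[-iLast]
    step <- 0.0025
    Q <- sum(qgamma(1 - 1e-10 / length(sR), shape = sR, rate = rR))
    n <- ceiling(Q / step)
    if (n %% 2L == 1L) n <- n + 1L
    grid <- seq(0, by = step, length.out = n + 1L)
    eta <- if (length(sR) == 1L) {
        dgamma(grid, shape = sR, rate = rR)
    } else {
        .sumGammaDensity(sR, rR, grid, step)
    }
    w <- .simpsonWeights(n + 1L, step) * eta
    tp <- t[!neg]
    out[!neg] <- vapply(tp, function(ti) {
        sum(w * pgamma(ti - grid, shape = d@shapes[iLast],
                       rate = d@rates[iLast]))
    }, numeric(1))
    pmin(pmax(out, 0), 1)
})

#' Unit-interval interpolation weights of a delay distribution
#'
#' Discretises a delay distribution into the lag-weight vector used by
#' the interpolated completion propensity on the unit measurement grid:
#' the completion propensity of interval \code{(i-1, i]} is
#' \code{sum_j w[j+1] * h(z(i-j))}, where \code{h} is the initiation
#' propensity and \code{z} the trajectory.  The weights are obtained by
#' integrating the delay density against the piecewise-linear
#' interpolation kernel over each unit interval (composite Simpson on a
#' fine grid), truncating at the \code{1 - tol} quantile, and
#' renormalising the truncated mass into the covered support.  For the
#' no-delay distribution the weights reduce exactly to the trapezoid rule
#' \code{c(1/2, 1/2)}.
#'
#' @param d A \linkS4class{DelayDistribution}.
#' @param step Quadrature step (min) for the delay-density grid.
#' @param tol Truncated tail mass.
#' @param maxSupport Hard cap (min) on the delay support used for the
#'   discretisation; guards against pathological parameter proposals
#'   during inference.
#' @return Numeric lag-weight vector \code{w}, summing to 1;
#'   \code{w[j+1]} multiplies the initiation propensity \code{j} grid
#'   steps back.
#' @export
delayWeights <- function(d, step = 0.01, tol = 1e-8, maxSupport = Inf) {
    stopifnot(is(d, "DelayDistribution"))
    if (d@family == "dirac_zero") return(c(0.5, 0.5))
    nc <- length(d@shapes)
    Q <- sum(qgamma(1 - tol / nc, shape = d@shapes, rate = d@rates))
    Q <- min(Q, maxSupport)
    M <- max(1L, ceiling(Q))
    nseg <- round(1 / step)             # points per unit segment
    if (nseg %% 2L == 1L) nseg <- nseg + 1L
    step <- 1 / nseg
    grid <- seq(0, M + 1, by = step)
    eta <- if (nc == 1L) {
        dgamma(grid, shape = d@shapes, rate = d@rates)
    } else {
        .sumGammaDensity(d@shapes, d@rates, grid, step)
    }
    simp <- .simpsonWeights(nseg + 1L, step)
    W0 <- numeric(M + 1L)
    W1 <- numeric(M + 1L)
    for (m in 0:M) {
        ## segment s in [m, m+1]
        ib <- (m * nseg + 1L):((m + 1L) * nseg + 1L)
        sB <- grid[ib] - m
        W0[m + 1L] <- sum(simp * eta[ib] * (1 - sB^2) / 2)
        W1[m + 1L] <- sum(simp * eta[ib] * (1 - sB)^2 / 2)
        if (m >= 1L) {
            ## segment s in [m-1, m]
            ia <- ((m - 1L) * nseg + 1L):(m * nseg + 1L)
            sA <- grid[ia] - (m - 1L)   # in [0, 1]; s + 1 - m = sA
            W0[m + 1L] <- W0[m + 1L] + sum(simp * eta[ia] * sA^2 / 2)
            W1[m + 1L] <- W1[m + 1L] +
                sum(simp * eta[ia] * (1 - (1 - sA)^2) / 2)
        }
    }
    w <- c(W1, 0) + c(0, W0)
    s <- sum(w)
    if (!is.finite(s) || s <= 1e-10) {
        ## essentially no completion mass inside the supported window
        ## (pathologically long delay): represent as zero weights
        return(c(0, 0))
    }
    ## renormalise the truncated 1e-8 tail into the covered support, but
    ## never inflate weights when maxSupport cut off substantial mass
    if (s >= 0.99) w / s else w
}
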