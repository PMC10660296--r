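## Independent oracles and small fixture builders shared across tests.

twoStepFig <- function(...) {
    buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0.05,
                      delayX = gammaDelay(18 / 5, 3 / 5),
                      delayY = gammaDelay(18 / 5, 3 / 5), ...)
}

birthNet <- function(A = 5, delay = noDelay()) {
    delayedNetwork(
        species = "Z",
        reactions = list(
            reaction("birth", products = c(Z = 1), form = "constant",
                     rate = c(A = A), delay = delay)),
        observed = "Z")
}

birthDeathNet <- function(A = 10, B = 0.05, delay = noDelay()) {
    delayedNetwork(
        species = "Z",
        reactions = list(
            reaction("birth", products = c(Z = 1), form = "constant",
                     rate = c(A = A), delay = delay),
            reaction("death", reactants = c(Z = 1),
                     form = "mass_action_linear", rate = c(B = B),
                     substrate = "Z")),
        observed = "Z")
}

## Brute-force interpolated completion propensity by nested adaptive
## quadrature: independent of the lag-weight convolution used by the
## package.  h is the vector of initiation propensities at the grid
## states z(0..T); the delay is a single Gamma(shape, rate).
bruteForceFhat <- function(i, h, shape, rate) {
    total <- 0
    for (m in 0:(i - 1L)) {
        h0 <- h[i - m]          # h(z(i-1-m))
        h1 <- h[i - m + 1L]     # h(z(i-m))
        inner <- function(tv) vapply(tv, function(tt) {
            lo <- max(tt - 1, 0)
            if (lo >= tt) return(0)
            stats::integrate(function(s)
                dgamma(s, shape = shape, rate = rate) *
                    ((s + 1 - tt) * h0 + (tt - s) * h1),
                lo, tt, rel.tol = 1e-10, abs.tol = 1e-13)$value
        }, 0)
        total <- total +
            stats::integrate(inner, m, m + 1, rel.tol = 1e-9)$value
    }
    total
}

## Exact event-history log-likelihood for a pure-birth process with a
## constant initiation rate A and delay distribution d, observed as a
## completion-event log on (0, T]: product of completion propensities
## A * F(t_j) at the completion times, times exp(-A * int_0^T F).
exactBirthEventLogLik <- function(completionTimes, A, d, T) {
    intF <- stats::integrate(function(s) delayCDF(d, s), 0, T,
                             subdivisions = 2000L)$value
    sum(log(A * delayCDF(d, completionTimes))) - A * intF
}
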