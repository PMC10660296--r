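# DelayedKinetics

Simulation-based Bayesian inference for stochastic reaction networks
with distributed time delays, aimed at partially observed gene
regulatory networks: systems where a reaction initiates at a
state-dependent rate but completes only after a random, Gamma-distributed
lag standing in for unmodelled sequential steps (transcription,
translation, folding, maturation, target search), and where only some
species — typically a fluorescent reporter — are measured, at discrete
times, with noise.

The core model is the **two-step activation motif**: an unobserved
activator X is produced at rate $A_X$ and diluted at rate $B$; X drives
production of an observed reporter Y with Michaelis–Menten propensity
$A_Y X/(K_M+X)$, each initiated molecule appearing only after the
regulation delay $\tau_X \sim \Gamma(\alpha_X,\beta_X)$ plus the
maturation delay $\tau_Y \sim \Gamma(\alpha_Y,\beta_Y)$; Y is diluted at
the same rate $B$; measurements are $Y_\text{obs}(t) = Y(t) + \epsilon(t)$
with $\epsilon(t) \sim N(0,\, Y(t)+\sigma_e)$ on the grid
$t = 0,1,\dots,T$ minutes.

What the package provides:

* an exact **delayed stochastic simulation algorithm** and a delayed
  **tau-leaping** scheme on the measurement grid;
* the approximate **Poisson likelihood of per-interval reaction
  completion counts** $r_{ki}$, built from the interpolated completion
  propensity $\hat f_k(i) = \sum_j w_k[j]\, h_k(z(i-j))$ (delay-density
  lag weights; trapezoid rule for undelayed reactions), combined with
  the Gaussian observation likelihood;
* a **Metropolis–Hastings-within-Gibbs sampler** whose latent counts
  are proposed by simulating the model itself (the count-likelihood
  factor cancels from the acceptance ratio), supplemented by partial
  re-simulation and local level-shift moves, with conjugate Gamma
  updates for rate parameters and a random-walk step for free delay
  rates;
* a data-driven initialiser combining a deterministic mean fit with a
  synthetic-likelihood profile of the $A_X/K_M$ identifiability ridge;
* synthetic benchmark generators (steady-state and short regimes,
  degeneracy and delay-split pairs) with ground truth for recovery
  scoring.

See the vignette (`vignettes/delayed-kinetics-methods.Rmd`) for the
model, the likelihood discretisation, the sampler, and an honest
discussion of what is and is not identifiable at desk scale.

## Worked example

Simulate a small synthetic experiment from the two-step model, then fit
it with the delay and kinetic parameters free:

```r
library(DelayedKinetics)

net <- buildTwoStepModel(AX = 10, AY = 60, KM = 100, B = 0.05,
                         delayX = gammaDelay(3.6, 0.6),
                         delayY = gammaDelay(3.6, 0.6))
net
#> DelayedNetwork: 2 species (X, Y*), 4 reactions
#>   (* = observed)   initial state: 0, 0
#>   prodX    0 -> X  h: constant  delay mean: 0
#>   degX     X -> 0  h: mass_action_linear  delay mean: 0
#>   prodY    0 -> Y  h: michaelis_menten  delay mean: 12
#>   degY     Y -> 0  h: mass_action_linear  delay mean: 0

cfg <- experimentConfig("custom", nTraj = 10, T = 100, seed = 7)
ds  <- generateDataset(cfg)          # exact delayed SSA + noise
ps  <- runMCMC(ds$net, ds$observations, nIter = 4000, burnIn = 2000,
               seed = 7, free = c("AX", "AY", "B", "betaX"))
summarizePosterior(ps, truth = c(AX_over_KM = 0.1, mu_tauX = 6,
                                 B = 0.05, AY = 60))
#>    parameter        mean           sd       q2.5       q97.5 truth  normMean
#> 1         AX 15.29897107 0.2324725690 14.8333992 15.71974258    NA        NA
#> 2         AY 48.44573094 0.7431459587 46.9760717 49.86188185 60.00 0.8074288
#> 3          B  0.04601495 0.0007197738  0.0445649  0.04727198  0.05 0.9202989
#> 4      betaX  0.52307546 0.0192376192  0.4859086  0.56098108    NA        NA
#> 5    mu_tauX  6.89170701 0.2544416897  6.4173287  7.40880127  6.00 1.1486178
#> 6 AX_over_KM  0.15298971 0.0023247257  0.1483340  0.15719743  0.10 1.5298971
```

Reading the rows: `mu_tauX` (mean regulation delay, minutes; generative
value 6) and `B` (shared dilution rate, 1/min; 0.05) are recovered
within about 8--15% even at this very small scale of ten cells.
`AX_over_KM` (the identifiable production-to-Michaelis-constant ratio;
0.1) and the anti-correlated `AY` (maximal reporter rate, 1/min; 60)
are determined only up to the broad identifiability plateau discussed
in the vignette: the estimate sits above the generative ratio with
`AY` correspondingly low, and the single-chain credible intervals
understate that ridge uncertainty.

A thin command-line interface over the same functions lives at
`inst/scripts/delayed-kinetics-cli.R` (subcommands `generate`,
`simulate`, `loglik`, `infer`, `summarize`).

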