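# aloccu

Autologistic multi-season occupancy models for camera-trap surveys.

## The problem

Long-term camera-trap monitoring programs ask whether species' occurrence is
stable, and how disturbance (illegal hunting, resource extraction) affects
it. The raw data are detection/nondetection histories: each site `i` is
sampled on occasions `j` (blocks of trap-days) in each year `k`, and a
non-detection may mean either true absence or a missed animal. Dynamic
(multi-season) occupancy models separate those, but the standard
colonization/extinction parameterization is awkward when covariates are
thought to act on occupancy itself rather than on its components.

`aloccu` fits the autologistic variant, in which occurrence probability
carries the previous year's state in its intercept:

    logit(psi[i,1]) = alpha2 + alphaS*SNARES[i,1] + alphaE*ELEV[i] + alphaE2*ELEV2[i]
    logit(psi[i,k]) = alpha0 + alpha1*z[i,k-1] + alphaS*SNARES[i,k]
                      + alphaE*ELEV[i] + alphaE2*ELEV2[i] + alphaB*BAN[k]
    z[i,k] ~ Bernoulli(psi[i,k])
    y[i,j,k] ~ Bernoulli(p[i] * z[i,k]),  logit(p[i]) = beta0 + betaB*BORDER[i]

so `plogis(alpha0)` is the colonization probability, `plogis(alpha0 +
alpha1)` the persistence probability, and covariate effects read directly as
effects on occurrence. All continuous covariates are standardized; the
quadratic elevation term is the square of standardized elevation.

The latent chain `z[i,]` is never sampled during fitting: each site's
likelihood is marginalized exactly with a two-state forward recursion, which
makes the same likelihood usable for adaptive random-walk Metropolis MCMC,
for maximum-likelihood fits, and for oracle tests against brute-force
enumeration. Derived quantities (yearly mean occupancy over the monitored
sites) come from forward-filtering backward-sampling of `z` conditional on
the data; goodness of fit is a posterior-predictive Bayesian p-value on a
Pearson discrepancy over site-year detection counts.

The package also includes a synthetic camera-trap survey generator
(elevation gradient, border distance collinear with elevation, snare counts
declining over years, a mid-series management ban) so the entire pipeline is
testable without any field data, plus CSV readers for daily or
occasion-level detection records and a small command line
(`inst/cli/aloccu.R`: `simulate`, `fit`, `gof`, `summarize`).

## Worked example

Simulate a widespread, persistent antelope-like species (true colonization
0.71, persistence 0.88, snare effect -0.49, detection ~0.5) and fit it with
the reduced MCMC protocol:

```r
library(aloccu)
sc  <- preset("harvey", seed = 1)
sim <- simulate_dataset(sc)
sim$survey
#> Camera-trap survey: 60 sites x 7 occasions x 8 years
#>   sampled occasions: 3227  detections: 1258

ch <- run_mcmc(sim$survey, sim$covariates, attr(sc, "spec"),
               mcmc_config(n_chains = 3, n_iter = 5000, n_burnin = 1000,
                           thin = 5, seed = 1))
print(summary(ch), digits = 3)
#>   parameter    mean     sd    q2.5    q50   q97.5 rhat
#> 1    alpha2  0.5385 0.3889 -0.3211  0.564  1.2230 1.03
#> 2    alpha0  1.0276 0.3333  0.4100  1.013  1.7429 1.01
#> 3    alpha1  1.1956 0.2876  0.6302  1.206  1.7436 1.00
#> 4    alphaS -0.3382 0.1512 -0.6230 -0.342 -0.0409 1.01
#> 5    alphaE -0.3538 0.1302 -0.6184 -0.352 -0.1072 1.01
#> 6   alphaE2 -0.1236 0.1385 -0.3837 -0.124  0.1537 1.04
#> 7    alphaB -0.2726 0.3343 -0.9482 -0.262  0.3660 1.00
#> 8     beta0  0.0112 0.0426 -0.0725  0.012  0.0980 1.00
#> 9     betaB  0.2804 0.0414  0.2020  0.280  0.3641 1.00

cp <- colonization_persistence(ch)
#> colonization 0.73 (0.60-0.85), persistence 0.90 (0.83-0.95)

bayes_p(ch, seed = 1)
#> Bayesian p-value: 0.677 (adequate fit, 2400 draws)
```

The posterior recovers the generating values: colonization and persistence
land on 0.73 and 0.90 against truths of 0.71 and 0.88; the snare effect is
estimated negative with an interval excluding zero; all Rhat values are
below 1.1; and the posterior-predictive check flags no misfit.
`mean_occupancy_by_year(ch)` then gives the yearly mean occupancy of the 60
monitored sites with 95% credible intervals.

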