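# fossildiv

Bayesian inference of origination and extinction dynamics from the fossil
record, with the preservation (fossil sampling) process modelled jointly.
The package is aimed at palaeobiologists analysing stage-binned occurrence
tables of extinct clades — the setting of Permo–Triassic insects, where
per-taxon data are a handful of dated occurrences and everything else
(true lifespans, rates, sampling intensity) must be inferred.

## The models

For each taxon the times of origination (`Ts`) and extinction (`Te`, Ma
before present, `Ts > Te`) are latent. Fossils accumulate over the
lifespan by a Poisson process with rate `q` (occurrences/taxon/Myr):
constant (HPP), hump-shaped over the lifespan (NHPP), or piecewise by
geological stage (TPP), optionally with gamma-distributed rate
heterogeneity across taxa. Lineages originate and die by a birth–death
process with piecewise-constant rates `lambda(t)`, `mu(t)`; the
complete-observation log-likelihood is

    sum_i log lambda(Ts_i) + sum_{i extinct} log mu(Te_i)
      - int (lambda + mu)(t) D(t) dt,    D(t) = lineages alive at t.

Rate shifts are either fixed at stage boundaries (BDCS) or sampled by
reversible jump (RJMCMC) with log Bayes factors > 6 flagging significant
shifts. Lineages that never fossilise are handled by data augmentation so
rate estimates are not biased by the missing short-lived taxa. On top of
the core samplers:

* **Age-dependent extinction** (`run_ade`): Weibull taxon longevities;
  shape > 1 means old lineages die faster, shape 1 is age-independent
  extinction.
* **Covariate-driven rates** (`run_mbd`): `lambda(t) = lambda0 exp(sum G_j
  x_j(t))` with a horseshoe prior on the correlation parameters;
  shrinkage weights > 0.5 flag credible drivers.
* **Guild diversity dependence** (`run_mcdd`): per-guild baselines
  modulated linearly by every guild's normalised standing diversity;
  positive interaction parameters are competition-like, negative ones
  facilitation-like.
* Post-processing: diversity trajectories, extinction-event severity
  (percent of genera lost), fold changes over background rates, effective
  sample sizes.
* A forward simulator (`simulate_scenario`, `simulate_clade`,
  `simulate_preservation`, `simulate_guild_system`) generating fossil
  records with known ground truth for every fitted model.

## Worked example

Simulate a clade that suffers a sustained five-fold extinction-rate
increase at 252 Ma, fossilise it at one occurrence per taxon-Myr, and ask
the reversible-jump sampler what happened:

```r
library(fossildiv)

sc     <- simulate_scenario("pulse", seed = 2)
series <- true_age_series(sc$occurrences)
series
#> Taxon series (replicate 0): 335 taxa, 1822 occurrences

cfg  <- mcmc_config(n_generations = 80000, sampling_interval = 200,
                    window = c(283.5, 242), edge_window = c(281.5, 244),
                    seed = 99)
post <- run_rjmcmc(series, cfg = cfg)
post
#> RJMCMC posterior: 360 samples, 335 taxa, window 283.50-242.00 Ma
#>   shift count modes: lambda 0, mu 1
#>   mean q = 1.040; min ESS = 169

significant_shifts(post, rate = "mu")
#>       time   log_bf significant
#> 1 252.3487 10.18884        TRUE
```

The sampler finds no origination shifts, exactly one extinction shift —
placed 0.35 Myr from the true onset at 252 Ma with a log Bayes factor of
10.2 (decisive; the significance rule is log BF > 6) — and recovers the
preservation rate (truth 1.0). Severity of the event and its magnitude
over background:

```r
severity(lifespan_estimates(post), event_window("pulse onset", 254, 250))
#> pulse onset: 246 taxa present, 151 extinct (61.4%), 95 survivors (38.6%)

rtt <- summarize_rates(post)
fold_change(rtt, event_window("pulse onset", 253, 251), rate = "mu",
            background_windows = matrix(c(281, 256), 1))
#> [1] 7.45
```

So 61% of genera present at the onset died during it, and peak extinction
ran about 7-fold above the pre-event background estimate. Real analyses
start from `read_occurrences()` + `resample_ages()` (ten age-resampled
replicates, pooled), or from a single YAML configuration via
`run_pipeline()`; `vignettes/fossil-diversification-methods.Rmd` documents
every model, prior and numerical choice.

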