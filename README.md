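# socprime

Does fresh carbon input build soil organic carbon (SOC), or does it burn it
down? Adding plant-derived substrate to soil *replenishes* the SOC stock
(part of the added carbon is retained after microbial respiration) but can
also *prime* extra decomposition of pre-existing old SOC. `socprime` is a
data–model synthesis pipeline for isotope-labelled soil incubation
experiments that quantifies both fluxes and their net effect, for
biogeochemists working with substrate-addition incubation data.

## What it does

An isotope-labelled incubation yields three cumulative CO₂ series: from old
SOC in an unamended control, from old SOC under substrate addition, and
from the added (labelled) substrate. `socprime`:

1. **simulates** four compartmental decomposition models with full isotope
   and source-resolved CO₂ bookkeeping — conventional first-order
   (12 parameters, two parameter sets), interactive two-pool (6),
   Michaelis–Menten (8) and reverse Michaelis–Menten (7). The interactive
   model represents priming by making the old-pool decay rate depend on the
   substrate level:

   dN/dt = I − K_N·N,  dO/dt = r·K_N·N − (K_O + K_p·N^p)·O

2. **calibrates** any model to a study's three series with an adaptive
   Metropolis–Hastings sampler (uniform priors, Gaussian likelihood over
   the cumulative series, reflection at prior bounds, covariance adaptation
   during burn-in, first half discarded);
3. **selects** the parsimonious model by weighted DIC and the model
   likelihood L = exp(−0.5·(DIC_w − DIC_min)) with threshold 0.5, plus
   within-sample regression and fixed/random out-of-sample validation;
4. **accounts fluxes** at a standardized 1-year horizon: replenishment
   (labelled C left in soil pools), priming (treatment-minus-control old-C
   CO₂), net = replenishment − priming, each as % of added C with posterior
   uncertainty;
5. **runs scenario experiments**: spin-up to steady state under
   0.8 mg C kg⁻¹ d⁻¹, then a year of step (0.88) or gradually increasing
   (0.8004 → 0.9596) input — both inject 29.2 mg C kg⁻¹ of extra C — with
   optional warming (+15% on rates), drying (−10%) and wetting (+10%);
6. **synthesizes** study-level effects as weighted means with 95% CIs
   (W* = n/s², CI = M ± 1.96·√V), overall and by substrate N:C category.

Because the underlying literature compilation is not redistributable, the
package includes a synthetic-incubation generator with known truth
(`generate_collection()`), and the whole pipeline is validated by recovery
experiments against it. See the methods vignette
(`vignettes/soc-replenishment-priming.Rmd`) for the models, the sampler,
all defaults, and known limitations.

## Worked example

Calibrate the interactive model to one synthetic study and summarize its
1-year fluxes:

```r
library(socprime)

st <- generate_study(synth_config(noise_cv = 0.05, seed = 1), seed = 7)
st$obs
#> <soc_obs> study synth1: SOC 17.95491, added 1.920724 mg C/g (10.7% of SOC),
#>           N:C low, 30 observations

chain <- fit_study(model_spec("interactive"), st$obs,
                   config = mcmc_config(S = 20000, seed = 42), dt = 0.1)
chain
#> <soc_chain> 10000 retained samples, acceptance 0.25, max log-lik -0.5

standardized_summary(chain)[, c("metric", "mean", "lo95", "hi95")]
#>          metric      mean       lo95     hi95
#> 1 replenishment 33.197789 26.9448158 37.94704
#> 2       priming  8.195886  0.6014795 20.60948
#> 3           net 25.001903 11.4491661 34.98576
#> 4          loss 66.802211 62.0529632 73.05518

st$truth$flux_365
#> replenishment       priming           net          loss 
#>     32.223826      5.393272     26.830555     67.776174
```

One year after the addition the posterior puts replenishment near 33% of
the added carbon and priming near 8%, a net SOC gain of ~25% of the
addition; the generator's true values (32.2 / 5.4 / 26.8) sit inside the
posterior bands.

The `analysis/` directory holds the numbered drivers for the full study:
`01_simulate_collection.R` (synthetic collection),
`02_fit_and_select.R` (four-model calibration and DIC selection),
`03_synthesis_vs_truth.R` (weighted-mean fluxes vs known truth),
`04_scenario_experiment.R` (continuous-input scenarios),
`05_validation.R` (fixed- and random-mode validation). Each writes its
tables under `results/`.

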