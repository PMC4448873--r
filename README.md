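# flocknet

Social network inference for fission-fusion animal societies tracked by
automated detection systems. `flocknet` turns a timestamped stream of
individual detections (e.g. PIT-tag reads at feeding stations) into
gathering events, a weighted association network, and a verdict on
whether phenotypic assortment in that network is driven by **social**
decisions (who joins whom) or **spatial** structure (who lives where).
It is aimed at behavioural ecologists working with RFID feeder grids,
camera-trap arrays, or any detection design where groups must be
inferred from bursts of closely spaced visits.

## What it computes

* **Group inference** — each location-day's detection times are modelled
  as a 1-D Gaussian mixture (number of components selected by BIC); each
  detection is hard-assigned to a component, giving a group-by-individual
  matrix.
* **Association network** — the simple-ratio index for every dyad,
  `SRI = x / (x + y_a + y_b)` (co-occurrences over events involving
  either individual), and weighted assortativity

  `r = (Σᵢ eᵢᵢ − Σᵢ aᵢbᵢ) / (1 − Σᵢ aᵢbᵢ)`

  for discrete traits (mixing matrix `e`, marginals `a`, `b`), with a
  weighted-Pearson analogue for continuous traits.
* **Group statistics** — lagged stability
  `S = G_jk / (G_j!k + G_k!j + G_jk)` averaged in log-spaced lag bins;
  mean/max/typical group size (`Σn² / Σn`); ≥5% group-size classes;
  per-class composition proportions; binomial composition probabilities
  `C(n,k) pᵏ (1−p)ⁿ⁻ᵏ`; kurtosis size-assortment; within-sex body-size
  PC1.
* **Two permutation null models** — a phenotypic node-label permutation
  and a spatio-temporally restricted data-stream permutation (swaps of
  individuals between groups at the same feeder and sampling period,
  preserving group sizes and individual observation counts). Observed
  outside both ⇒ social; outside the node null only ⇒ spatial; inside
  both ⇒ none.
* **Saturation models** — linear vs three-parameter logistic fits of
  group size on local population size, compared by AIC, with the fitted
  asymptote `K`.
* **Synthetic data** — a generator with planted social preferences,
  spatial segregation and a planted size asymptote, so the whole pipeline
  is testable without field data.

## Worked example

```r
library(flocknet)

cfg <- run_config(
  seed = 7,
  simulate = list(n_individuals = 50, n_feeders = 6, n_periods = 1,
                  gatherings_per_feeder_day = 6, home_range_sd = 200,
                  within_burst_sd = 20, detections_per_member = 4),
  infer = list(k_max = 10),
  nulls = list(node_iter = 200, stream_iter = 20000, sample_every = 200))
report <- run_pipeline(cfg)
report
```

```
<run_report>
  seed: 7 
  groups: 78, mean size 6.28, typical 8.30
  verdicts:
    sex        r outside node null: FALSE, stream null: FALSE -> none
    age_class  r outside node null: FALSE, stream null: FALSE -> none
    residency  r outside node null: FALSE, stream null: FALSE -> none
```

78 gathering events were inferred from the simulated stream; groups
average 6.3 members while the *typical* group size — the size experienced
by the average individual — is 8.3. The generator here is neutral (no
planted preference or segregation), and all three traits are correctly
classified `none`: the observed network assortativity sits inside the
95% envelopes of both the node-label and the data-stream permutations.
Planting a mixed-sex preference
(`simulate = list(social_preference = c(same_sex = 0.3), ...)`) flips the
sex verdict to `social`; displacing immigrant home ranges
(`spatial_segregation_strength = 500`) flips residency to `spatial`.

Individual stages are plain functions on tibbles and pipe together:

```r
sim <- simulate_detections(sim_config(n_individuals = 60, n_feeders = 9,
                                      n_periods = 2, seed = 1))
inf <- infer_groups(sim$detections)
net <- build_network(inf$matrix)
network_density(net)
stability_curve(inf$matrix) |> autoplot()
local_population_table(inf$matrix) |> fit_saturation("mean") |> glance()
```

Results carry `tidy()`, `glance()` and `autoplot()` methods.

## Package layout

* `R/simulate.R` — synthetic detection-stream generator
* `R/segment.R`, `R/group-matrix.R` — Gaussian-mixture group inference
* `R/network.R` — simple-ratio network, assortativity, density, GraphML
* `R/group-stats.R` — stability, size classes, composition, kurtosis, PC1
* `R/nulls.R` — the two permutation null models and effect classification
* `R/saturation.R` — linear vs logistic group-size models
* `R/pipeline.R`, `R/io.R` — end-to-end runner and validated CSV formats
* `vignettes/fission-fusion-methods.Rmd` — models, assumptions, design
  choices and limitations
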