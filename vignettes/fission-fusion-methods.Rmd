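---
title: "Inferring fission-fusion structure and attributing phenotypic assortment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fission-fusion structure and attributing phenotypic assortment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

## The problem

Winter flocks of woodland songbirds are a classic fission-fusion system:
individuals move between ephemeral foraging groups whose membership turns
over within minutes, yet season-long association networks built from those
groups show consistent phenotypic structure. Automated feeding stations
fitted with RFID antennae produce a timestamped stream of individual
detections from which groups are never observed directly — they must be
inferred from bursts of temporally clustered visits.

Once groups are inferred, the central inferential problem is attribution:
does assortment by a phenotype (sex, age class, residency status, body
size) arise from *social* decisions — individuals preferring or avoiding
certain phenotypes when joining groups — or from *spatial* structure —
phenotypes being unevenly distributed over the landscape, so that groups
passively mirror local availability? `flocknet` implements a complete
pipeline for this question: group inference, network construction,
group-level statistics, and a pair of contrasting permutation null models
whose joint outcome separates the two explanations.

## Pipeline and models

### Group inference

Each feeder-day's detection times are modelled as a one-dimensional
Gaussian mixture: a gathering event contributes a burst of reads around
its centre time. `segment_stream()` fits mixtures with 1 to `k_max`
components and selects the number of components by BIC; each detection is
then hard-assigned to its maximum-responsibility component, and a group's
member set is the set of individuals among its detections. The default
`k_max` allows one component per 10 minutes of the day's span, matching
the timescale over which group stability decays.

The fit uses `mclust` (EM with deterministic model-based hierarchical
initialisation), so segmentation needs no random restarts and is exactly
reproducible; both equal-variance and varying-variance one-dimensional
models compete within the BIC selection. The selection rule lives behind
a single function so an alternative backend (e.g. a variational mixture)
could be swapped in. Components holding less than `min_component_weight`
of a day's detections can be merged into their nearest neighbour to guard
against stray reads forming spurious singleton groups; the default (0)
performs no merging. Antennae at one feeder are pooled: the feeder is the
observation unit.

Degenerate inputs are handled explicitly: an empty stream yields no
groups, a single detection yields a singleton gathering, and identical
times yield one gathering of spread zero. Ties in responsibility are
broken toward the earlier component, which keeps assignment
deterministic.

### The association network

From the group-by-individual matrix, every dyad's edge weight is the
simple-ratio index `x / (x + y_a + y_b)` — the fraction of gathering
events involving either individual in which both were present. The
sampling unit is the gathering event (gambit of the group). Assortativity
uses the weighted mixing-matrix coefficient

    r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)

with each undirected edge contributing half its weight to each
orientation, and a weighted-Pearson analogue over ordered dyads for
continuous traits; on binary traits coded 0/1 the two coincide (a tested
equivalence). Individuals with unknown phenotype stay in the network but
carry no weight in assortativity, mirroring field practice where
never-caught birds are detected but unsexed. Dyads never observed
together hold zero weight and therefore contribute nothing to the mixing
matrix; no structural zeros are imputed.

### Group statistics

* **Lagged stability.** For two groups that both contain a focal
  individual, separated by lag tau, stability is the proportion of
  non-focal individuals retained across the pair. The package reads the
  "at least one common member" restriction as at least one *non-focal*
  common member (`min_shared = 1`), since the focal is shared by
  construction; setting `min_shared = 0` recovers the vacuous reading.
  Pairs are pooled across focals with equal weight within log-spaced lag
  bins (`per_focal = TRUE` averages per focal first); pairs are formed
  across feeders by default because cross-feeder movement is part of the
  phenomenon, with `within_feeder = TRUE` exposed. The observed curve is
  interpreted through its ratio to the same curve computed on the final
  matrix of a long data-stream permutation chain — the conventional
  choice for statistics too expensive to sample along the chain.
* **Size classes.** Composition statistics are reported per group size;
  sizes of 14 and above are merged greedily upward until each class holds
  at least 5% of all group memberships, with any trailing remainder
  absorbed into the previous class.
* **Composition and assortment.** Per size class the package reports the
  mean within-group proportion of a focal class; the mean binomial
  probability of each group's composition given the class share among
  unique individuals at that size (values near 0.5 indicate even,
  disassorted mixes; near 0, single-class groups); and the Pearson
  kurtosis (`m4 / m2^2`, normal reference 3, population moments) of
  group-mean trait values, where a peaked distribution indicates size
  assortment. Kurtosis is undefined and flagged for classes with fewer
  than four groups or zero variance.
* **Body size.** Wing and tarsus are standardized within sex (males are
  larger in both measures, so a pooled axis would mostly encode sex), the
  first principal component is taken, oriented to correlate positively
  with wing, and rescaled to mean 0, variance 1 within sex.

### The two null models and the attribution rule

1. **Phenotypic node-label permutation** (`node_permutation_null()`):
   phenotype rows are reshuffled across individuals — whole rows, so
   trait covariance is preserved — while the observation stream is fixed.
   1000 iterations by default.
2. **Spatio-temporally restricted data-stream permutation**
   (`datastream_permutation_null()`): repeatedly swaps two individuals
   between two groups observed at the same feeder in the same sampling
   period, each individual absent from the other group. Group sizes,
   each individual's membership count, each group's time and place — and,
   because swaps stay within strata, each individual's per-stratum
   observation count — are preserved exactly; only the detailed pattern
   of co-membership is randomized. The chain is cumulative and sampled
   every `sample_every` successful swaps; failed candidate draws are
   counted but do not advance the chain. Strata are chosen with
   probability proportional to their number of group pairs, which mixes
   dense strata in proportion to the work they require (uniform stratum
   choice would over-randomize sparse strata). An optional `burn_in`
   discards early samples; the default keeps the cumulative convention.

The observed statistic "differs" from a null when it falls outside the
central 95% interval of the permuted values (scalar statistics), or
outside the entire permuted range in any bin (multi-bin profiles, where
simultaneous comparisons make interval-wise tests misleading and
Bonferroni corrections are inappropriate for non-independent bins).
Differing from both nulls indicates a social effect; only from the
node-label null, a spatial effect; from neither, no effect. Differing
only from the data-stream null has no interpretation under this logic and
is flagged `ambiguous`.

### Saturation of group size

`fit_saturation()` compares a straight line against a three-parameter
logistic `K / (1 + exp(-(x - x0)/s))` for mean or maximum group size as a
function of local population size (unique individuals per feeder and
sampling period), by Gaussian-likelihood AIC. The logistic's lower
asymptote is fixed at zero: observed sizes are at least 1 and the fit is
least-squares, so the extra parameter is not worth its cost at these
sample sizes. Initialisation is `K = 1.05 max(y)`, `x0 = median(x)`,
`s = sd(x)/2`, with two fallback starts; non-convergence (e.g. constant
response) is reported with diagnostics while the linear fit is still
returned. The week-effect companion (`week_effect_check()`) is a
deliberately plain fixed-effects regression of residual group size on
sampling period, labelled descriptive: it is not a mixed model and does
not account for repeated measures of feeders.

## The synthetic-data generator

No detection data are bundled; `simulate_detections()` generates streams
with known structure so that every downstream stage can be tested against
planted truth.

* **Design.** The default configuration emulates the motivating study
  design: 65 feeders on a 250-unit stratified grid, 13 two-day sampling
  periods, about 40 gatherings per feeder-day with 30 s within-burst
  spread, roughly 10 reads per member per gathering, and a population of
  1000 birds (49% male, 47% juvenile, 35% immigrant).
* **Space.** Each bird's home-range centre is a uniformly chosen feeder
  plus isotropic Gaussian jitter; availability at a feeder decays as a
  Gaussian kernel of distance (the simplest monotone kernel with one
  parameter). The default `home_range_sd = 100` is below the 250-unit
  feeder spacing, so each bird effectively uses a handful of neighbouring
  feeders; this keeps per-feeder pools near the logistic midpoint, giving
  an overall mean group size near 5 while the expected size still
  saturates at `group_size_asymptote = 8` where pools are large — the two
  size regularities the generator is meant to emulate. Immigrant
  segregation displaces immigrant centres along +x by
  `spatial_segregation_strength` distance units (zero by default).
* **Groups.** Gathering times are uniform over daylight (06:00-18:00);
  sizes are zero-truncated negative binomial with mean tied to the local
  availability pool through a logistic map with asymptote
  `group_size_asymptote`, so a saturating size-density relationship is
  planted and recoverable. Members are drawn sequentially: availability
  times the product of pairwise social-preference weights against members
  already in the group (`same_sex`, `same_age`, `same_residency`; weights
  below 1 plant avoidance of like, hence disassortment). Every member
  emits at least one read at times normal around the gathering centre.
* **What it does not emulate.** Movement ecology, patch depletion,
  dominance queues, weather, diurnal activity ramps, or tag failure.
  Passing tests on this generator show the *inference machinery* is
  correct under its assumptions — bursty mixtures, set-valued groups,
  availability-driven membership — not that real detection streams meet
  those assumptions.

Every stage draws from a sub-stream derived from the global seed plus a
stage tag, so a configuration and seed fix the whole stream byte for
byte.

## Numerical and design choices

* BIC-selected EM with deterministic initialisation replaces the
  variational mixture formulation the group-inference literature also
  uses; the two agree on well-separated bursts, and the model-selection
  rule is isolated for swapping.
* The stability prefactor is read as the count of qualifying
  (focal, pair) contributions in a lag bin; each of a pair's shared
  individuals contributes one qualifying focal observation.
* Kurtosis uses population moments without the normal-reference
  subtraction, so 3 is the neutral reference.
* Swap candidate draws that find no exchangeable pair are skipped and
  counted, never counted as iterations; a matrix with no legal swap at
  all raises an error rather than returning a degenerate null.
* Envelopes use the exact-level order-statistic convention: with m
  permuted values, the central 95% interval is `[x_(k), x_(m+1-k)]` for
  `k = floor(0.025 (m + 1))`, so the probability of an exchangeable
  observed value falling outside is at most 5% in finite samples. The
  full permuted range is carried alongside for the profile criterion.

## Problem sizes

Tests and the bundled examples run a desk-scale slice of the design —
typically 60-80 birds, a 9-feeder grid, 1-3 sampling periods, around
300-600 groups — chosen so that permutation chains (10^5 restricted
swaps, sampled every 10^3) mix many times over relative to the ~2000-5000
memberships they permute. Verdict-recovery checks run the attribution
machinery on the generator's true group memberships, isolating the
question "does the two-null logic recover planted effects?" from
segmentation noise, which is validated separately via co-membership
accuracy on separable bursts. Paper-scale settings (10^6 iterations
sampled every 10^3) remain the function defaults' documented convention
for full-size datasets.

## Known limitations

* Hard assignment cannot represent a bird genuinely belonging to two
  overlapping gatherings; overlapping bursts merge or split at the BIC's
  discretion.
* The data-stream null conditions on inferred groups; segmentation errors
  propagate into both observed and permuted statistics and are not
  separately propagated as uncertainty.
* The attribution logic is qualitative (verdicts, not effect sizes) and
  inherits the usual caveats of envelope tests under non-independence.
* `week_effect_check()` is descriptive only; fitting the proper mixed
  model is out of scope.
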