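# morphochron

Dating sequentially initiated plant organs from static observations, and
reconstructing continuous, age-indexed morphogenetic trajectories.

## The problem

Organs like *Arabidopsis* rosette leaves grow over weeks, across four
orders of magnitude in size — far beyond what live imaging can follow.
The practical alternative is destructive sampling: many individuals, each
observed once (a leaf count, a blade length, a segmented contour), at an
unknown developmental stage. `morphochron` recovers chronological time
from such data:

1. **When was organ rank k initiated?** A population of N individuals
   flows one-way through organ-count categories,

   dN₀/dt = −σ₁(t)N₀,  dN_k/dt = σ_k(t)N_{k−1} − σ_{k+1}(t)N_k,
   dN_K/dt = σ_K(t)N_{K−1},

   with logistic per-capita hazards σ_k(t) = c_k/(1 + e^{−b_k(t−a_k)}).
   Empirical category dynamics are reconstructed from the one-shot counts
   under an ergodicity assumption (balanced resampling + backward
   counting), the ODE model is fitted by seeded evolutionary search plus
   local polish, and rank-k initiation is the first time the fitted
   proportion of individuals with ≥ k organs reaches 50%.

2. **How old is an organ of length l?** Per rank, blade length versus age
   is calibrated with an inverse-variance-weighted Hill fit
   l(a) = l_max aⁿ/(t_½ⁿ + aⁿ), and inverted:
   a = t_½ (l/(l_max − l))^{1/n}. Derived features: inflection age
   t_infl = t_½((n−1)/(n+1))^{1/n}, maximal growth rate v_max = l′(t_infl),
   and the relative growth rate v_max/l(t_infl).

3. **What does the average organ look like at age t?** Dated, landmarked
   contours are arc-length resampled, rigidly registered, and combined by
   Gaussian time-weighted vertex averaging (adaptive bandwidth,
   side-balance cap) into mean-shape trajectories, quantified by blade
   aspect ratio and dissection index and by per-tooth width, height and
   aspect, including tooth dating via the same initiation machinery at
   the sub-organ scale.

A synthetic-data generator (`wt_default_config()` and friends) emulates
all three dataset types with known ground truth, so the whole pipeline is
testable end to end.

## Worked example

```r
library(morphochron)

# synthetic static counts: 300 plants, 11 ranks, 24 h plastochron
cfg <- wt_default_config(seed = 11)
counts <- simulate_static_counts(simulate_initiation_schedule(cfg), cfg)

bal <- resample_categories(categorize(counts, category_map("identity")),
                           seed = 2)
emp <- empirical_dynamics(bal)
emp
#> empirical step dynamics: N = 160 individuals, 12 categories (0..11),
#> 300 event times on [1.712, 599.3] h

fit <- fit_initiation_model(emp, seed = 3)
round(fit$initiation_times_h, 1)
#>  [1]  12.1  33.5  58.0  89.4 105.3 133.8 155.8 177.6 210.2 229.9 253.7
mean(initiation_intervals(fit$initiation_times_h)) / 24
#> [1] 1.006379
```

The mean inter-rank interval recovers the generating 24 h plastochron
(1.0 day) to within 1%. Absolute times sit about half a plastochron
early — a structural property of dating transitions from destructive
snapshots (each observation age proxies a transition age, and those ages
spread over the whole category dwell); intervals are unbiased. Growth
calibration then dates organs from size:

```r
lens <- simulate_length_observations(cfg, rank = 7)
shifted <- shift_to_leaf_age(
  data.frame(individual_id = lens$individual_id,
             plant_age_h = lens$plant_age_h,
             length_um = lens$length_um),
  T_h = 7 * 24, quiet = TRUE)
hfit <- fit_hill(shifted, estimate_time_variances(shifted))
hfit
#> Hill growth curve: l_max = 12911.9 um, t_half = 290.831 h, n = 3.939
#> weighted SSE 172.428 on 218 observations
date_organs(hfit$params, T_h = 7 * 24, lengths_um = 6000)
#>   length_um age_since_init_h absolute_age_h
#> 1      6000         280.5704       448.5704
```

(The generating law for rank 7 is l_max = 12400 µm, t_half = 284 h,
n = 4.) A command-line interface wraps the same stages:

```sh
exec/morphochron simulate --preset wt-default --seed 1 -o out/
exec/morphochron pipeline --dir out/ --seed 1 -o run1/
```

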