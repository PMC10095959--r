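---
title: "Dating plant organs and reconstructing morphogenetic trajectories from static data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating plant organs and reconstructing morphogenetic trajectories from static data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphochron)
```

## The problem

Whole-organ morphogenesis in plants spans several orders of magnitude in
space and time: an *Arabidopsis* rosette leaf grows from a primordium of a
few tens of micrometres to a blade of centimetres over weeks, while its
marginal teeth are patterned when the blade is still microscopic. Live
imaging cannot cover such windows, so the data are *static*: every
individual is dissected once, yielding a single snapshot — a leaf count, a
blade length, or a segmented contour — at an unknown developmental stage.
`morphochron` turns collections of such snapshots into age-resolved growth
and shape trajectories in three stages:

1. **Initiation dating** — when was organ rank $k$ initiated?
2. **Growth calibration** — how old is an organ of measured size $l$?
3. **Shape trajectories** — what does the average organ look like at age $t$?

## Stage 1: the organ-apparition model

A population of $N$ individuals acquires organs strictly sequentially. Let
$N_k(t)$ be the number of individuals carrying exactly $k$ organs at time
$t$ (categories $0 \dots K$). Each category feeds the next through a
per-capita transition hazard, giving the compartmental cascade

$$\frac{dN_0}{dt} = -\sigma_1(t)\,N_0,\qquad
\frac{dN_k}{dt} = \sigma_k(t)\,N_{k-1} - \sigma_{k+1}(t)\,N_k,\qquad
\frac{dN_K}{dt} = \sigma_K(t)\,N_{K-1},$$

with $N_0(0) = N$ and logistic hazards
$\sigma_k(t) = c_k / (1 + e^{-b_k (t - a_k)})$. The inflection time $a_k$
(hours) places transition $k$, the slope $b_k$ (1/h) sets how sharply it
switches on, and $c_k$ (1/h) is the saturated rate; the sigmoid form makes
transitions fire in sequence. The system conserves
$\sum_k N_k(t) = N$ and is integrated with a stiff-capable implicit solver
(RADAU IIA via `deSolve`; relative tolerance $10^{-6}$, absolute tolerance
$10^{-9} N$).

### Empirical dynamics from destructive snapshots

$N_k(t)$ is never observed directly: each individual contributes one
(age, count) pair. Treating the cross-section as the time course of a
closed population (an ergodicity assumption), observations are first
balanced so that every category holds the same number $N$ of rows ($N$ =
size of the largest category; smaller categories are upsampled with
replacement under a seed). Counting backwards from late times, with
$C_k(t)$ the cumulative number of category-$k$ observations at ages
$\le t$:

$$N_0(t) = N - C_0(t), \qquad N_k(t) = C_{k-1}(t) - C_k(t), \qquad
N_K(t) = C_{K-1}(t).$$

These step functions conserve $N$ exactly — an algebraic identity that the
test suite checks against a literal event-by-event backward counter.
Sampling noise can make middle categories transiently negative; the values
are kept unclamped (the fitted model is non-negative, and clamping would
bias the cost) and a warning reports the count.

### Fitting and the 50% criterion

The $3K$ parameters minimize the sum of squared differences between
predicted and reconstructed occupancies, evaluated at the observed event
times so the cost lives where the data are. The search is a seeded
differential-evolution stage inside box bounds ($a_k$ in the data age
range, $b_k \in [10^{-3}, 1]$ h$^{-1}$, $c_k \in [10^{-4}, 10]$ h$^{-1}$,
slopes and scales on the log scale), initialized at the empirical
half-crossing ages, followed by an L-BFGS-B polish. Inside the fit the
ODE is solved with `lsoda` at a relative tolerance of $10^{-4}$ — the
cost is a sum over hundreds of points with residuals of order one
individual, so tighter integration buys nothing — while reported
trajectories use the default tolerances. The initiation time of rank $k$
is the first $t$ where the fitted cumulative proportion
$P_{\ge k}(t) = \sum_{j \ge k} \hat N_j(t)/N$ reaches one half, located by
bisection to 0.01 h; one-way flow makes $P_{\ge k}$ monotone, so the
crossing is unique and times are ordered in $k$.

Counts can be tracked per rank (identity map) or binned so that
successive categories open when odd ranks appear (category 0 = counts
0–2, category $j \ge 1$ = counts $2j+1, 2j+2$), which doubles the spacing
between recovered times — useful when only alternate ranks are scored
reliably.

### A known, structural bias — and why intervals are still right

Because each individual is destroyed when observed, the reconstruction
uses the *observation* age of a category-$(k-1)$ individual as a proxy for
its $k$-th transition age. Under near-uniform sampling those ages are
spread across the category's whole occupancy window, so the fitted 50%
crossing lands near the *middle* of that window: absolute initiation
times are systematically early by about half a dwell interval (half a
plastochron for leaf ranks). The offset is common to all ranks, so
*intervals* between successive initiation times — the quantity of
scientific interest, e.g. the plastochron itself — are unbiased. The
acceptance suite documents this honestly: interval recovery is tested
tightly, while the per-rank absolute-time check fails for early ranks
(where half a plastochron is a large relative error) and is left failing
rather than corrected post hoc, since no such correction is part of the
method.

## Stage 2: Hill growth calibration

Blade length against organ age (plant age minus the rank's initiation
time; pre-initiation rows are dropped and logged) is fitted with the Hill
sigmoid

$$l(a) = \frac{l_{max}\,a^n}{t_{1/2}^n + a^n},$$

by Levenberg–Marquardt least squares (`minpack.lm`), weighted by inverse
variances estimated in 24 h age bins (bins with fewer than 3 observations
pool their neighbours; zero-variance bins are weight-capped). Start
values: $l_{max,0} = 1.05\max l$, $t_{1/2,0}$ at the observation nearest
half of that, $n_0 = 2$, with 8 deterministically jittered restarts.
The inverse
$a = t_{1/2} (l/(l_{max}-l))^{1/n}$ dates any organ from its length;
lengths at or above $l_{max}$ (which genuinely occur under noise) either
error or, in clamp mode, are capped at $(1-10^{-3})\,l_{max}$ with a
warning. Derived features — all verified against brute-force numerical
maximization in the tests, since they are easy to get wrong —

$$t_{infl} = t_{1/2}\left(\frac{n-1}{n+1}\right)^{1/n}\!\!,\qquad
v_{max} = l'(t_{infl}),\qquad \mathrm{RGR} = v_{max}/l(t_{infl}),$$

require $n > 1$; otherwise growth rate is maximal at age $0^+$ and the
result is flagged. `compare_sigmoid_models()` ranks Hill against
3-parameter logistic and Gompertz alternatives by AIC on the weighted
residuals. Tooth ages compose subtraction: tooth age = leaf age − tooth
initiation time, with not-yet-initiated teeth flagged and excluded.

Hours are the canonical unit everywhere in files and objects; days appear
only in reports.

## Stage 3: shape trajectories

Contours are closed, simple, counterclockwise polygons (µm) with landmark
indices: base-left, base-right, apex, and per-tooth (sinus, tip, sinus)
triples per side. Before averaging, each margin (base-right→apex,
apex→base-left) is resampled uniformly in arc length to $m$ subdivisions
(default 200; $2m+1$ vertices with landmarks at fixed indices — the
resampling is iterated to its equal-chord fixed point so the operation is
idempotent), and the contour is rigidly registered: base midpoint at the
origin, blade axis along $+y$. No size normalization is applied —
trajectories must carry absolute growth (mean shapes keep their scale).

The mean shape at query age $t$ is the vertex-wise weighted mean with
Gaussian kernel weights $w_i = \exp(-(t_i - t)^2/2h^2)$. Two guards make
this robust to sparse, non-uniform, asymmetric sampling: the bandwidth
adapts as the distance to the 15th-nearest sample age, and the total
weight on either temporal side of the query is capped at 3× the lighter
side. A query with no sample within 5 reference bandwidths (reference =
knn × mean age spacing, deliberately not the adaptive bandwidth, which
would stretch across any gap) errors rather than extrapolating. The
effective sample size $(\sum w)^2/\sum w^2$ is reported per age. Exact
identities hold by construction: a single contour at the query age is
returned unchanged, and the midpoint of two symmetric ages is the plain
vertex average.

Blade measures: length (base midpoint to apex), width (maximal extent
perpendicular to that axis), shoelace area, convex-hull area, aspect
ratio, and dissection index (hull area / area, 1 for convex outlines).
Tooth measures: sinus-to-sinus chord width, perpendicular tip height,
aspect (height/width), and the normalizations width/blade length and
height/blade width. Tooth width–height geometry follows the standard
morphometric reading of sinus/tip landmarks; sides are measured
independently with pooling as an explicit option.

## The synthetic-data generator

The generator emulates all three dataset types with known ground truth,
under a destructive design (one snapshot per synthetic individual —
matching the ergodicity assumption):

* **Initiation schedules**: $T_{i,r} = r\,p + \varepsilon_{i,r}$,
  $\varepsilon \sim N(0, \sigma_j^2)$ truncated to keep ranks strictly
  ordered (resampling violating draws). The `wt-default` preset uses
  $p = 24$ h, $\sigma_j = 6$ h, $K = 11$, 300 individuals, snapshots
  uniform over (0, 600) h — a regime in which all transitions complete
  well inside the window and every category is populated.
* **Counts**: count = number of ranks initiated by the (uniform) sampling
  age.
* **Lengths**: the rank's Hill curve with multiplicative Gaussian noise
  of CV 0.1 by default — spread growing with size is what motivates the
  inverse-variance weighting, and it exercises it. Default blade laws
  grade linearly with rank ($l_{max} = 4000 + 1200r$ µm,
  $t_{1/2} = 200 + 12r$ h, $n = 4$), mimicking the graded, homothetic
  kinetics of successive rosette leaves.
* **Contours**: a lens-shaped blade of two circular arcs joined at a short
  base segment and the apex, length from the rank's Hill curve, width =
  length / AR(age) with a default AR trajectory that elongates, rounds
  (minimum near 260 h), then elongates again. Teeth are raised-cosine
  bumps displaced radially from the margin arc; the sinus-sinus chord and
  perpendicular tip height are imposed *exactly* equal to the tooth width
  and height Hill laws (arc sagitta compensated), so measuring a
  synthetic contour round-trips the generating values up to polygon
  discretization (2% at the default vertex budget). One shared tooth law
  across ranks encodes the registration property: width-versus-tooth-age
  curves of different tooth ranks must collapse once teeth are correctly
  dated. Offsets (60, 132, 210) h give increasing inter-tooth intervals.

What the generator does **not** emulate: measurement error on contours
and landmarks, missed teeth on large blades, non-uniform sampling designs,
genotype-specific growth laws, or any cell-scale mechanism. Passing tests
therefore validate the *inference machinery* — not the biological
adequacy of logistic hazards or Hill kinetics for any particular dataset.

## Numerical choices and problem sizes

* ODE: RADAU IIA default; `lsoda` at rtol $10^{-4}$ inside fitting loops.
* Differential evolution: population 24, 25 generations, best/1/bin with
  $F = 0.7$, $CR = 0.9$; polish capped at 60 L-BFGS-B iterations. These
  budgets suffice because the inflection-time initialization from the
  empirical crossings already lands in the right basin.
* Ties in observation ages are handled by cumulative counting at unique
  ages, which makes the reconstruction independent of within-tie order.
* Test and validation runs use the `wt-default` regime (300 individuals,
  K = 11) for pipeline recovery, K ≤ 4 populations for oracle
  comparisons, an $N = 2000$ event-driven simulation for the stochastic
  check, and 120–240 contours per trajectory experiment — sizes chosen so
  the whole suite exercises every stage at full fidelity on a single CPU.

## Known limitations

* Absolute initiation times carry the half-dwell bias discussed above;
  use intervals, or treat absolute times as consistently shifted.
* The asymptote $l_{max}$ is weakly identified when the data stop before
  $t_{1/2}$; `fit_hill()` flags this (`plateau_seen = FALSE`).
* Mean-contour tooth landmarks are inherited from the highest-weight
  contributor, so tooth measures on mean shapes are only meaningful where
  the contributing contours share their serration pattern; per-contour
  tooth tables are the primary tooth output.
* `hill_inverse` is undefined at and above $l_{max}$: dating saturates for
  organs near final size, a property of the method, not the code.
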