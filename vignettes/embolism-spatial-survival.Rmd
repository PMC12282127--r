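---
title: "Spatial survival modelling of embolism propagation in leaf vein networks"
author: "veinfrail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial survival modelling of embolism propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinfrail)
```

## The problem

During leaf desiccation, gas emboli form in xylem conduits and permanently
block water transport. The optical vulnerability technique images a leaf
throughout a dry-down, producing a binarized vein mask and a stack of frames
of newly embolized pixels, each frame tagged with the leaf water potential
$\Psi$ (MPa) at acquisition. The question veinfrail addresses is how embolism
spreads in space and time across the venation network: does embolism in one
vein segment make embolism in its neighbours more likely, and do thicker
veins embolize earlier?

The unit of observation is the **vein segment** — the stretch of skeletonized
vein between two branching points, or between a branching point and an ending
point. A segment either embolizes during the observation window (an event at
water-potential magnitude $t_i = |\Psi_i|$) or survives to the end
(right-censored at the final $|\Psi|$). The magnitude of water potential
serves as the survival "time" axis: it is positive, and it increases
monotonically as the leaf dries, which is what a survival model needs.
Left-censoring is ignored: measurements begin before appreciable water loss.

## From images to data

**Segmentation.** The mask is thinned to a one-pixel, 8-connected skeleton
(Zhang–Suen thinning followed by removal of 8-redundant pixels, so that pure
L-corners do not masquerade as junctions). Skeleton pixels with at least
three skeleton neighbours are branching points; touching branching pixels are
merged into one junction cluster, because thinning can emit two or three
adjacent branch pixels at a single anatomical junction. Segments are the
connected skeleton components left after removing junction clusters. Segments
shorter than `min_segment_px` (default 3 px) that touch a junction are merged
into their longest neighbour; these are almost always thinning spurs. Counts
produced by other skeletonization software will differ slightly; the
branching-point criterion here (≥ 3 neighbours) is a declared choice, not a
reconstruction of any particular tool.

**Thickness.** Vein thickness is twice the maximum exact Euclidean
distance-transform value over the segment's medial-axis pixels — twice the
radius of the largest circle inscribed in the vein along that segment,
measured between pixel centres. The transform is computed on the full mask;
away from junctions a per-segment crop would give identical maxima.

**Adjacency.** Two segments are neighbours ($e_{ij} = 1$) when they touch a
common junction cluster. The adjacency matrix $E$ is symmetric with zero
diagonal, and $e_{i+} = \sum_j e_{ij}$ counts a segment's neighbours.

**Events.** A segment's candidate event is the first frame whose embolized
pixels fall within the segment's dilated skeleton (radius = thickness/2,
rounded up); dilation makes the assignment robust to ~1 px registration error
between frames and mask. Optical signals can spill a few pixels across
junctions, so a candidate is filtered out when its pixels (a) lie within
`spill_radius` (default 2 px) of a segment holding an accepted same-frame
event and (b) cover less than `spill_frac` (default 0.10) of its own
segment's skeleton. Filtering runs in rounds of simultaneous removal to a
fixed point, which makes the result order-independent and idempotent. The
rule and its defaults are this package's own construction — configurable, and
switchable off entirely (`filter_spillover = FALSE`).

## The survival models

The temporal backbone is a Weibull base survival function

$$S_0(t) = \exp\{-e^{\theta_1} t^{\theta_2}\},$$

with $\theta_1$ the (log) scale — more negative means slower, more spread-out
progression — and $\theta_2 > 0$ the shape: positive shape means segments
become more likely to embolize as desiccation progresses. This
parametrization is declared, and $\theta_2 > 0$ is enforced by sampling
$\log\theta_2$.

Each segment carries a latent frailty $v_i$ on the log-odds scale, acting
proportionally on the odds of survival:

$$S_i(t) = \frac{e^{-\eta_i}\,S_0(t)}{1 + (e^{-\eta_i} - 1)\,S_0(t)},
\qquad \eta_i = v_i \;(\text{+ } \beta x_i \text{ for the thickness model}),$$

so higher frailty means earlier embolism, and $\eta_i = 0$ recovers $S_0$.
Three variants differ in the prior on $v$ and the presence of the thickness
covariate:

| model | frailty prior | thickness |
|---|---|---|
| spatial-independent | IID $N(0, \tau^2)$ | no |
| spatial-dependent | ICAR on $E$ | no |
| spatial-thickness | ICAR on $E$ | yes |

The ICAR prior conditions each frailty on the mean of its neighbours,
$v_i \mid v_{-i} \sim N\!\big(\sum_j e_{ij} v_j / e_{i+},\; \tau^2/e_{i+}\big)$,
encoding the hypothesis that neighbouring segments embolize at similar times;
the reported spatial dependence parameter is the precision $\tau^{-2}$. The
thickness covariate $x_i$ is z-scored within each leaf by default so that
$\beta$ is comparable across leaves and species; raw pixels are available via
`standardize_thickness = FALSE`. Both observed and censored segments enter
the likelihood,
$\sum_i [\delta_i \log f_i(t_i) + (1-\delta_i)\log S_i(t_i)]$, with
$f_i = -dS_i/dt$ in closed form; dropping censored segments would bias the
survival estimate and distort the spatial field around well-connected
censored veins.

### Identifiability and priors

The ICAR prior is improper in the constant direction, so frailties are
recentred to sum to zero within each connected component every sweep; the
overall level of risk is carried by $\theta$. Hyperpriors (all configurable
through `veinfrail_priors()`): $\theta_1 \sim N(0, 10^2)$,
$\log\theta_2 \sim N(0, 1.5^2)$, $\beta \sim N(0, 10^2)$, and
$\tau^{-2} \sim \mathrm{Gamma}(1, 0.01)$ — weakly informative on the MPa
scale of $|\Psi|$. Ties in event times are left as-is; the likelihood is
continuous and needs no tie correction.

### Sampling

Inference is Metropolis-within-Gibbs, implemented in C++ and driven by R's
RNG so that a fit is bit-reproducible given (data, model, seed, chains,
iterations). Frailties get single-site random-walk updates whose acceptance
ratio uses the segment likelihood plus the prior full conditional;
$(\theta_1, \log\theta_2, \beta)$ get a joint random walk; the precision has
a conjugate Gamma update from the pairwise-difference (ICAR) or sum-of-squares
(IID) quadratic form. Proposal scales adapt in batches of 50 during burn-in
only (targets 0.44 single-site, 0.234 joint), so the post-burn-in chain is a
fixed-kernel Markov chain. An adaptive random walk was preferred over
proposals drawn directly from the ICAR full conditionals: the target is
identical, but the random walk remains well-behaved when the likelihood
dominates the prior at strongly informative segments. Defaults are 2 chains
of 10,000 iterations, half burn-in, thinning 5; split-$\hat R$ (threshold
1.05) and effective sample sizes are recorded per scalar parameter, and
non-convergence raises a warning flag in the metadata, never an error.

## Evaluation

- **KM baseline.** Product-limit estimator with a Greenwood log-log 95% band
  (degenerate limits collapse onto the point estimate where the transform is
  undefined).
- **Credible-band area.** For each posterior draw the leaf-level curve is the
  segment-average $\bar S(t) = m^{-1}\sum_i S_i(t)$; the band is the
  pointwise 2.5–97.5% range. Band widths are integrated by the trapezoid rule
  on the union of the two curves' grids (model curve linearly interpolated,
  KM step-interpolated) and reported as the relative change
  $(A_{model} - A_{KM})/A_{KM}$; negative means uncertainty was reduced.
  Using the segment-average as the leaf-level functional is a declared
  interpretation.
- **DIC.** Conditional DIC with focus $(\theta, \beta, v)$:
  $\bar D + p_D$ with $p_D = \bar D - D(\text{posterior means})$. The
  marginal (frailty-integrated) DIC would require an integration the model
  family does not supply in closed form.
- **Temporal 80/20 split and C-index.** The threshold is the 80th percentile
  of observed event times (ties go to training); training data censor all
  later segments administratively at the threshold, and the later events form
  the test set. Risk scores for test segments are the posterior-mean
  frailties (plus $\bar\beta x_i$ for the thickness model) estimated from the
  training fit, and the C-index is the strictly-ordered fraction of
  comparable pairs; score ties count as discordant, and chance level is 0.5.
- **Vulnerability curves.** Percent embolized is $100(1-\bar S(t))$; P50 is
  the linearly interpolated $-t$ at $\bar S = 0.5$, missing when the curve
  never reaches 0.5.
- **Features and correlations.** Connectivity = branching points / segments;
  vein density = skeleton length / area; areoles = enclosed background
  regions / area. Species-level analyses use between-species Pearson
  correlations of per-species means — samples within a species are not
  independent, so the pooled ("total") correlation is deliberately avoided.
  Per-leaf thickness–event correlations are computed on the $|\Psi|$ axis, so
  a *negative* r means thicker veins embolize earlier (the thicker-to-thinner
  propagation pattern).

## The synthetic-data generator

The generator mirrors the model family so every stage is testable without
images. Lattice networks take segments as the edges of a $k \times k$
junction grid (pruned at random, connectivity-preserving, to hit an exact
segment count) with lognormal thickness (median 6 px, log-sd 0.3);
hierarchical networks grow by recursive bifurcation with thickness tapering
by factor 0.7 per level (children always thinner than parents, floored at
the 2 px minimum width) and optional same-depth cross-links that emulate
reticulation and sweep connectivity upward. Frailty fields are drawn IID or
as the constrained ICAR Gaussian (covariance $\tau^2 L^{+}$, per-component
sum-to-zero by construction). Event times invert the proportional-odds
Weibull survival function in closed form — one uniform draw per segment —
with administrative censoring at a configurable $|\Psi|$.

What the generator does *not* emulate: biophysical embolism spreading
(air-seeding through pit membranes), registration error between frames and
mask, measurement noise in $\Psi$, or any real species' venation statistics.
Passing tests therefore demonstrate the correctness of the estimation and
evaluation machinery under the model's own assumptions, not the adequacy of
those assumptions for real leaves.

A rendered lattice can be pushed through the full image pipeline. One
subtlety: a lattice's four corner junctions have exactly two incident
segments, and raster semantics treat a degree-2 point as the interior of a
segment, so re-segmenting a rendered lattice recovers the simulated graph
with its degree-2 junctions contracted. Round-trip checks compare against
that contracted reference.

## Numerical choices and edge cases

- Linear predictors are clamped to $\pm 30$ before exponentiation: beyond
  that the odds factor under/overflows double precision without changing any
  ordering.
- A likelihood that underflows (e.g. an event at a time where $f_i = 0$)
  evaluates to $-\infty$ rather than raising an error, so the sampler simply
  rejects.
- Masks whose skeleton is a single pixel yield one degenerate segment with a
  warning; all-censored tables yield a flat KM curve with a warning; a model
  fit requires at least one observed event.
- The ICAR prior is undefined for isolated (degree-0) segments and errors;
  disconnected networks are handled per connected component.
- The minimum reported thickness is 2 px (a one-pixel-wide vein).

## Problem sizes used in the shipped checks

The package's own simulation studies run at sizes chosen to make Monte-Carlo
directions stable while staying desk-scale: parameter recovery at $m = 400$
segments, 20 replicates, 4,000 iterations per fit; DIC model comparison at
$m = 200$, 10 replicates; chance-level concordance at 200 segments and 1,000
replicates; the thickness-direction study at $m = 150$, 20 replicates; oracle
comparisons on graphs up to 12 nodes and rasters up to $100\times100$.

## Limitations

Vein segments are an imaging-resolution approximation to xylem conduits: one
conduit may span several segments or one segment several conduits, which can
bias the spatial dependence parameter. The spillover rule is a configurable
stand-in, not calibrated against any reference annotation. The IID/ICAR pair
brackets, but does not exhaust, plausible spatial dependence structures; and
the proportional-odds Weibull backbone is one of several reasonable temporal
laws. The sampler is a general-purpose Metropolis scheme: for very large
leaves ($m \gg 10^4$) a specialised sparse-precision sampler would be
preferable.

## A minimal run

```{r example, eval = FALSE}
net <- sim_vein_network(m = 120, kind = "lattice", seed = 1)
fr  <- sim_frailties(net, tau2 = 1, kind = "icar", seed = 2)
ev  <- sim_events(net, fr, theta1 = 0, theta2 = 1.5, beta = 0.8,
                  censor_time = 2.5, seed = 3)
fit <- veinfrail(ev, net, model = "spatial-thickness", seed = 4)
summary(fit)
band_area_relative_change(model_survival_curve(fit), km_estimator(ev))
dic(fit)$dic
evaluate_c_index(ev, net, model = "spatial-thickness", seed = 4)$c_index
vulnerability_from_survival(model_survival_curve(fit))$p50
```
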