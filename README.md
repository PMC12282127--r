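# veinfrail

Bayesian spatial survival modelling of xylem embolism propagation in leaf
vein networks.

## What problem this solves

When a leaf dries, gas emboli form in the xylem and permanently block water
transport. Optical vulnerability experiments image a leaf through a dry-down
and record, frame by frame, which pixels embolize and at what leaf water
potential Ψ (MPa). veinfrail is for plant hydraulics researchers and
biostatisticians who want to go beyond leaf-level vulnerability curves and
ask *spatial* questions of such data: does embolism in a vein segment raise
the risk in its neighbours, and do thicker veins embolize earlier?

The package covers the whole pipeline:

1. **Network extraction** — skeletonize a binarized vein mask, split it into
   vein segments at branching points, measure per-segment thickness from the
   Euclidean distance transform, and build the segment adjacency matrix
   `E = {e_ij}` plus venation features (connectivity, vein density, areoles
   per area).
2. **Event tabulation** — map per-frame embolized pixels onto segments,
   filter optical spillover, and emit right-censored event data: indicator
   `δ_i` and time `t_i = |Ψ|` at the event (or at the end of observation).
3. **Model fitting** — three proportional-odds Weibull survival models with
   per-segment frailties, fitted by MCMC.
4. **Evaluation** — Kaplan–Meier baseline, credible-band-area change, DIC,
   temporal 80/20 split with concordance index, vulnerability curves with
   P50, and between-species correlations.
5. **Simulation** — a generator for vein graphs, ICAR/IID frailty fields and
   embolism events from the same model family.

## The model

The base survival law is Weibull, `S0(t) = exp(−e^{θ1} t^{θ2})`, on the
`t = |Ψ|` axis. Each segment's frailty `v_i` (log-odds scale) scales its odds
of survival uniformly over time:

    S_i(t) = e^{−η_i} S0(t) / (1 + (e^{−η_i} − 1) S0(t)),
    η_i = v_i                     (spatial-independent, spatial-dependent)
    η_i = v_i + β x_i             (spatial-thickness; x_i = segment thickness)

The *spatial-independent* model gives the frailties an IID Gaussian prior
N(0, τ²); the *spatial-dependent* and *spatial-thickness* models use an
intrinsic conditionally autoregressive (ICAR) prior on the vein adjacency
graph, `v_i | v_−i ~ N(Σ_j e_ij v_j / e_i+, τ²/e_i+)`, so neighbouring
segments are pulled toward embolizing at similar times. Estimated parameters:
the Weibull pair (θ1, θ2), the spatial dependence parameter (the precision
τ⁻²), the thickness coefficient β, and the frailty field itself. Censored
segments stay in the likelihood.

## Worked example

```r
library(veinfrail)

# simulate a 120-segment lattice leaf with smooth ICAR frailties and a
# positive thickness effect, censored at |Psi| = 2.5 MPa
net <- sim_vein_network(m = 120, kind = "lattice", seed = 1)
fr  <- sim_frailties(net, tau2 = 1, kind = "icar", seed = 2)
ev  <- sim_events(net, fr, theta1 = 0, theta2 = 1.5, beta = 0.8,
                  censor_time = 2.5, seed = 3)

fit <- veinfrail(ev, net, model = "spatial-thickness", seed = 4)
summary(fit)
#>  parameter   mean    sd  lower  upper  rhat     ess
#>     theta1 -0.087 0.089 -0.269  0.084 1.005 646.895
#>     theta2  1.819 0.184  1.496  2.234 1.023  69.361
#>       tau2  3.949 3.007  0.742 12.172 1.019  56.008
#>       beta  0.703 0.199  0.314  1.089 1.008 178.958
#>  precision  0.428 0.375  0.082  1.347    NA      NA
```

The 95% credible interval for β (0.31, 1.09) covers the generating value
0.8: thicker veins embolize earlier. Evaluation against the non-spatial
baseline:

```r
km <- km_estimator(ev)
mc <- model_survival_curve(fit)
band_area_relative_change(mc, km)      # -0.392: band area 39% below KM
dic(fit)$dic                           # 174.3
vulnerability_from_survival(mc)$p50    # -0.87 (MPa)
evaluate_c_index(ev, net, model = "spatial-thickness", seed = 4)$c_index
#> 0.545  — better-than-chance ordering of held-out later events
thickness_time_correlation(ev, net$segments$thickness)
#> -0.29  — thicker segments embolize at smaller |Psi|
```

A negative band-area change means the spatial model estimates the leaf-level
survival curve with less uncertainty than the Kaplan–Meier baseline; the
C-index is computed on the latest 20% of events after refitting on the first
80% only; a negative thickness–|Ψ| correlation is the thicker-to-thinner
propagation signature.

Real image data enter through `read_vein_mask()` + `skeletonize_and_segment()`
and `read_frame_stack()` + `map_events()`. A command-line wrapper is
installed as `exec/veinfrail` with subcommands `segment`, `events`, `fit`,
`evaluate`, `simulate` and `run`.

## Documentation

The methods vignette (`vignettes/embolism-spatial-survival.Rmd`) documents
the model, priors, sampler, evaluation metrics, the synthetic-data
generator, and the package's design decisions and limitations.
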