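---
title: "A probabilistic static model of L5/S1 spinal loading during lifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic static model of L5/S1 spinal loading during lifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftbn)
```

## The model

liftbn predicts the compressive and shear load on the L5/S1 intervertebral
disc during a symmetric two-handed sagittal-plane lift. It is the classic
*top-down* static link-segment analysis used throughout occupational
biomechanics: starting at the hands, intersegmental reaction forces and
moments are propagated proximally across the forearm, upper-arm and torso
links to the L5/S1 disc.

The kinematic input is five segment angles measured **from the horizontal**
(degrees): ankle (shank), knee (thigh), torso (L5/S1-to-shoulder link),
shoulder (shoulder-to-elbow link) and elbow (forearm/hand line). Because the
analysis is static and every external load is gravitational, the reaction
force at each joint is vertical and equal to the supported weight; only the
horizontal offsets of the loads — set by segment lengths and the cosines of
the segment angles — enter the moments. Moments are *anterior-positive*:
loads in front of a joint produce a positive moment. In the packaged heavy
lifting posture the shoulder link points at 192°, placing the elbow behind
the shoulder, which is why the shoulder moment comes out negative while
elbow and L5/S1 moments are positive.

At L5/S1 the net moment is balanced by a single equivalent erector spinae
muscle acting at a fixed moment arm (default 0.053 m, the standard
recommendation when intra-abdominal pressure is not modelled) with a line of
action perpendicular to the disc:

\[
F_{es} = |M_{L5/S1}| / d .
\]

The disc plane is inclined \(\alpha = 40^\circ + \beta(T, K)\) from the
horizontal, where \(T = 90^\circ - \theta_{torso}\) is the torso angle from
vertical, \(K = 180^\circ - (\theta_{knee} - \theta_{ankle})\) the included
knee angle, and \(\beta\) a quadratic pelvic-rotation regression

\[
\beta = -17.5 - 0.12\,T + 0.23\,K + 0.0012\,TK + 0.005\,T^2 - 0.00075\,K^2 .
\]

Resolving the (vertical, magnitude \(R\)) reaction in the disc frame:

\[
C = F_{es} + R\cos\alpha, \qquad S = R\sin\alpha ,
\]

compression picking up the full muscle force (the muscle is normal to the
disc, so it contributes no shear).

```{r}
res <- linkage(posture(82, 114, 40, 192, -56), hand_load_kg = 53.1,
               subject(1.618, 65.6))
round(unlist(as.data.frame(res)), 1)
```

## Anthropometry: calibrated, not copied

Segment lengths scale with stature, masses with body mass, and segment COMs
with segment length. The limb mass and COM proportions are the standard
cadaver-derived values of the link-segment tradition. The three *link
lengths* that drive the moment levers (elbow–wrist, shoulder–elbow,
L5/S1–shoulder) and the above-L5/S1 torso mass fraction are **calibrated
reconstructions**: the textbook constants behind the published worked
example of this model are not printed with it, so these four values were
solved once from the example's five deterministic outputs and frozen. They
came out anatomically sensible (e.g. upper-arm link 0.1848·stature against
the classic 0.186 proportion; supported mass above L5/S1 = 47.7% of body
mass plus the hand load). Every constant is exposed in
`default_segment_table()` / `segment_table()` and can be overridden from a
scenario config; a "pelvis" row carries the below-L5/S1 trunk mass so that
whole-body mass fractions close to 1 (enforced at ±0.02). The model is
bilaterally symmetric: arm segments are computed once per side and doubled,
and the hand load is split equally between hands.

## The stochastic layer

Joint angles and hand load are modelled as independent untruncated normals;
posture SDs come from published assessment-error studies, converted from
mean absolute errors under normality by `mad_to_sd()` (sd = mae·√(π/2)).
`simulate_lifting()` propagates `n` draws through the deterministic pipeline
(vectorised, so 10⁶ draws take about a second) and returns a `sample_set`
with unit importance weights. Each input variable draws from its own RNG
substream derived from the master seed, so the hand-load draws are identical
whether or not posture is also varied, and every run is bit-reproducible
from `(seed, n, vary)`.

Numerical choices:

* hand-mass draws below zero (probability ≈ 2·10⁻⁵ at the packaged
  parameters) are clamped to zero and counted in an attribute — a truncation
  the physical quantity requires;
* the default n is 10⁶ (10⁷ via config) — the means reported by the
  acceptance machinery have MC standard errors well under 1 N at that size;
* weighted summaries use inverse-CDF quantiles and an (n−1)-style variance
  with weights normalised to sum to n, so uniform weights reproduce
  unweighted `mean`/`sd`/`quantile(type = 1)` exactly.

Because moment levers are cosines of normally distributed angles, the
posture-random compression mean sits a little *below* the deterministic
value (E cos θ = cos μ·e^{−σ²/2}); with only hand load random the model is
affine, so the mean is unchanged and the output SD is |slope|·input SD, with
slope ≈ 39.6 N/kg at the packaged posture.

## Disc injury as evidence: stress–strength interference

Disc prolapse is modelled as structural failure: injury occurs if and only
if compression exceeds a compressive strength drawn, independently of all
inputs, from N(5448, 2366) N (cadaver motion-segment testing in mild
flexion). The prolapse indicator is thus a *descendant* of compression in
the model's graph, and observing it updates everything upstream via Bayes'
theorem.

`condition_on_injury()` performs that update exactly by importance
weighting: evidence "true" multiplies each draw's weight by its analytic
exceedance probability Φ((Cᵢ−μₛ)/σₛ), evidence "false" by the complement.
No draws are discarded or perturbed, so *every* co-sampled quantity —
shear, moments, even the input angles — is conditioned through the shared
draws; this is how evidence at a descendant node shifts the shear
distribution despite the erector muscle contributing no shear directly.
The weighted-mean identity P(I)·E[C|I] + P(¬I)·E[C|¬I] = E[C] holds to
floating precision on one sample set, and the effective sample size
(Σw)²/Σw² is reported (with a warning below 1% of n). A strength-sampling
mode (`method = "sample"`) exists for didactic parity with the graph; it is
unbiased but strictly noisier, so the analytic weights are the default.

As an independent check, `build_discrete_network()` histograms the
compression marginal into equal-probability bins, attaches the injury CPT
(exceedance evaluated at bin midpoints), and `eliminate()` — a small exact
variable-elimination engine standing in for junction-tree propagation —
recovers the posterior over bins. Its only error is discretization, so its
posterior mean must (and does, in the tests) converge to the
importance-weighted mean as bins refine from 10 to 100; bin posteriors are
collapsed using each bin's weighted-mean compression rather than its
midpoint, which converges faster for skewed marginals.

## What the synthetic generator does and does not emulate

The generator *is* the stated world of the packaged scenario: independent
normal measurement error on five angles, a normal hand-load distribution,
fixed anthropometry. It does not emulate correlated posture errors (a real
observer mis-reads adjacent joints together), within-task posture change,
dynamic (inertial) loading, or subject-to-subject anthropometric variation.
A green stochastic test therefore establishes correct propagation of the
stated input uncertainty, not a validated population risk estimate.

## Known limitations and deliberate exclusions

* Intra-abdominal pressure relief of the extensor moment is excluded (the
  moment-arm default assumes this), as are multi-muscle lumbar models,
  EMG-driven estimation and any 3D or dynamic extension.
* Injury is compression-only single-load failure; cyclic-loading fatigue and
  shear-based criteria are out of scope.
* The disc-angle regression and the four calibrated anthropometric constants
  are reconstructions constrained by the published worked example, not
  transcriptions; users with the source tables can override both in config.
* One reference dispersion value (the hand-load-random compression SD of the
  network implementation this model was checked against) is not reproducible
  by any statics consistent with the published moments — the moment levers
  fix the compression/hand-mass slope at ≈39.6 N/kg, i.e. an output SD of
  ≈507 N for a 12.8 kg input SD. The corresponding acceptance check is kept,
  failing, rather than hidden; the posterior-inference experiment, by
  contrast, is reproduced to ~1%.
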