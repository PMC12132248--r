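---
title: "Modelling recombinase-based resource decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recombinase-based resource decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recflip)
```

## The problem and the model

Two reporter modules in one *E. coli* cell — an arabinose-inducible RFP
module and a constitutive GFP module — draw on the same finite pool of
expression machinery. Inducing RFP therefore depresses GFP even though no
regulatory edge connects them. `recflip` models this with a single lumped
resource pool entering every synthesis term as the multiplicative factor

$$\varphi = \frac{1}{1 + w_G u_G + w_R u_R + w_I u_I},$$

where $u_G, u_R, u_I$ are dimensionless promoter activities and the
$w$'s are per-module resource demands. This is the minimal competition
model: $\varphi \in (0, 1]$ always, and raising any module's weighted
activity lowers everyone's output. It deliberately does not distinguish
transcription from translation, nor model ribosome queuing.

The controller is a Bxb1 integrase/excisionase pair. Excisionase is
co-expressed bicistronically with RFP (same promoter activity $u_R$, its
own rate constant $k_X$), binds constitutively expressed integrase by mass
action into a complex, and the complex flips the inducible promoter out of
its RFP-driving (LR) orientation at rate $V_{off}\,C$ per promoter. Free
integrase alone resets BP back to LR at rate $V_{on}\,I$. The orientation
is tracked as a continuous fraction $P_{LR} \in [0,1]$ — a mean-field
description over plasmid copies appropriate for deterministic steady-state
analysis, not a per-copy stochastic switch. The feedforward variant lets
the flipped promoter read through toward GFP with strength $\beta_{FF}$:
$u_G = 1 + \beta_{FF}\, h(L)\, (1 - P_{LR})$.

Four topologies map onto the experimental constructs: no recombinase genes
at all; the flip-disabled open loop (recombinase expressed and consuming
resources, but recombination broken, as the attR central-dinucleotide
mutant realizes experimentally — flip rates zero, $P_{LR}$ pinned);
feedback only; feedback plus feedforward. They reduce onto one another
exactly: `RE_NF` is `RE_NF_FF` with $\beta_{FF}=0$; the open loop is
`RE_NF` with both flip rates zero; the controller-free circuit further
zeroes recombinase synthesis and its resource weight. The test suite
asserts these reductions bit-level on the right-hand side.

Growth-rate and dilution effects are folded into the first-order removal
rates; burden-induced growth changes are not modelled.

## Parameters

All concentrations are in arbitrary fluorescence-equivalent units (a.u.),
time in hours, inducer dose in % w/v L-arabinose. Defaults:

| parameter | default | meaning |
|---|---|---|
| $k_G, k_R$ | 100 a.u./h | reporter synthesis at full activity |
| $k_X, k_I$ | 50, 10 a.u./h | excisionase / integrase synthesis |
| $d_G, d_R, d_I, d_C$ | 1 /h | removal (degradation + dilution) |
| $d_X$ | 1 /h | excisionase turnover — the feedforward tuning knob |
| $K_L$ | $6.25\times10^{-4}$ % | half-activation dose |
| $n_H$, leak | 2, 0 | Hill coefficient, basal activity |
| $w_G, w_R, w_I$ | 1, 1, 0.2 | resource demands |
| $V_{on}$ | 0.1 /(a.u. h) | BP$\to$LR reset per free integrase |
| $V_{off}$ | 0.75 /(a.u. h) | LR$\to$BP flip per complex (feedback strength) |
| $k_{on}, k_{off}$ | 1 /(a.u. h), 1 /h | complex association/dissociation |
| $\beta_{FF}$, copy gain | 1, 1 | feedforward strength, plasmid copy scaling |

$K_L$ sits inside the plate dose ladder (0 to $5\times10^{-3}$ %), so the
ladder spans the response from baseline to saturation. The association
rate $k_{on} = 1$ was chosen so that excisionase partitions between
degradation and complex formation on comparable scales over the swept
turnover window $d_X \in [10^{-2}, 10^2]$ /h: with much faster
association, sequestration into the complex dominates removal everywhere
in that window, excisionase turnover stops controlling feedback strength,
and the controller's tuning curve loses its zero crossing. At $k_{on}=1$
the model reproduces the regime structure the circuits are designed
around — slow turnover accumulates complex, flips promoters down hard and
overcompensates GFP (positive CI); fast turnover starves the complex and
leaves residual negative coupling.

## The Coupling Index

Responses are normalized before scoring: GFP to its uninduced baseline
(so a perfectly decoupled circuit sits at 1), RFP to its maximum (so the
abscissa is the realized operating range). The normalized curve $g(r)$ is
fitted with a shape-preserving piecewise-cubic Hermite interpolant
(Fritsch–Carlson derivative limiting, `stats::splinefun(method =
"monoH.FC")`): it passes through every point, preserves monotone segments
and cannot overshoot them — important when six-dose ladders are all the
data there is. The CI is the mean of $g(r) - 1$ over a uniform grid on
$r \in [0,1]$ (default 201 points). Averaging uniformly in normalized-RFP
space makes the CI a property of the response curve rather than of the
dose spacing. The `direct` method averages the supplied points instead;
the two agree when the points themselves sample $r$ densely and evenly,
and `uniform_response_doses()` constructs such dose grids by inverting a
pilot scan. Sign classification uses a configurable decoupled band of
$\pm 0.02$ — there is no canonical choice; 2% of baseline is below what a
plate reader resolves across replicates.

## Steady states and sweeps

Steady states are found by stiff integration (`deSolve::lsoda`) in
geometrically growing time chunks until the max-norm of the RHS, scaled by
$1 + |x|$, drops below $10^{-8}$ (default; `t_max` 1000 h — promoter
flipping can take many hours), followed by a damped Newton polish on the
algebraic system that is only accepted while it reduces the residual and
stays within a small neighbourhood of the integrated state. The polish
pushes residuals to $\sim 10^{-12}$, which is what lets topology
reductions and the zero-feedback sweep row match their reference scans to
$10^{-8}$. The physical box ($x \ge 0$, $P_{LR} \in [0,1]$) is asserted on
every accepted output point; violations beyond integrator slack abort
rather than clamp silently. Dose scans warm-start each dose from the
previous steady state — also the physical protocol of an induction ladder
— and a test checks warm and cold starts agree to $10^{-6}$.

Default sweep grids: $V_{off}$ on 31 linear points over $[0, 1.5]$
(resolves the plateau of the feedback controller's CI curve); $d_X$ on 25
log points over $[10^{-2}, 10^2]$ /h and $k_I$ on 25 log points spanning
four decades around its default (both resolve their single zero
crossing). Controller tuning brackets the CI sign change and runs
`uniroot` on $\log_{10}$ of the parameter, because both knobs act
multiplicatively.

One structural caveat: with the BP$\to$LR reset proportional to free
integrase, raising integrase synthesis both accelerates the reset and
sequesters free excisionase, so in this model *low* integrase expression
produces the overcompensating (positive-CI) regime and high expression the
negative one. The single zero crossing — the property that makes the knob
tunable — is robust, but the direction of the asymptotes is a
model-structure choice that alternative reset kinetics would reverse.

## The synthetic-data generator

`generate_dataset()` emulates the plate-reader experiment: the six-dose
L-arabinose ladder (0 to $5\times10^{-3}$ % w/v; an extended seventh dose
$8.3\times10^{-3}$ % is available), three replicates per dose, and
arbitrary-unit GFP/RFP reads. Noise is multiplicative lognormal with unit
mean (default CV 10%) plus optional additive Gaussian background, clipped
at zero — the dominant error structure of bulk fluorescence reads. It does
not emulate growth differences between wells, optical-density
normalization artefacts, spectral bleed-through, or cell-to-cell
heterogeneity (no flow-cytometry-style distributions). Tests passing on
these data therefore validate the estimation machinery under idealized,
correctly-specified noise, not robustness to the systematic errors real
plates add.

## Parameter recovery

`fit_parameters()` minimizes squared residuals between log replicate-mean
fluorescence and log model steady states (log residuals are
variance-stabilizing under multiplicative noise), over log-transformed
free parameters within bounds, using bounded Levenberg–Marquardt with a
deterministic multi-start list. `recovery_study()` wraps
generate-then-fit over noise levels. Under the default conditions (6
doses × 3 replicates, feedforward topology, 20 datasets): noiseless
recovery of $\{V_{off}, d_X\}$ is exact to optimizer precision; at 5%
multiplicative CV the median relative error is about 11% for $V_{off}$
and about 25% for $d_X$ — the turnover rate is the sloppy direction of
the fit, its effect on the observable response being partially
exchangeable with feedback strength, and its median error moves by a few
points across seed sets. The recovery study runs on the feedforward
topology because $d_X$ is that controller's operative tuning knob; in the
plain feedback topology it is markedly less identifiable.

## Problem sizes

The shipped analyses and tests use the 6-dose ladder, 31- and 25-point
sweep grids, 200-point dense curves for estimator-equivalence checks, and
20 datasets per noise level in the recovery study — sizes at which every
result in this vignette is recomputed from scratch by the test suite in
about a minute and a half.

## Limitations

Mean-field promoter fraction (no copy-number stochasticity); one lumped
resource pool; no growth feedback; recombination modelled as two
first-order flip channels without cooperativity; the integrase-knob
direction caveat above; the fitting module assumes the model that
generated the data (no model-misspecification study).
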