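# recflip

Deterministic modelling of **resource competition between synthetic gene
modules** and of the **recombinase-based controllers** that decouple them.

When two gene modules share one cell's transcription/translation machinery,
inducing one silently drains the other: an RFP module driven by an
arabinose-inducible promoter pulls resources away from a constitutively
expressed GFP module, so GFP falls as RFP rises even though the two share no
regulatory link. A serine-integrase/excisionase pair (Bxb1) can close a
feedback loop on this burden: excisionase is co-expressed bicistronically
with RFP, complexes with constitutively expressed integrase, and the complex
flips the inducible promoter out of its RFP-driving (LR) orientation —
expression load turns the load-generating promoter off. A feedforward
extension lets the flipped (BP) promoter drive GFP instead, actively
compensating GFP's loss. `recflip` implements the ODE model of these
circuits, the statistic used to score them, and the synthetic-data
machinery to validate parameter estimation — for anyone designing or
analysing burden-aware synthetic circuits.

## Model

State: GFP `G`, RFP `R`, free excisionase `X`, free integrase `I`, complex
`C` (a.u.), and the fraction `P_LR` of promoter copies in the RFP-driving
orientation. With Hill induction
`h(L) = leak + (1-leak) L^n / (K_L^n + L^n)`, promoter activities
`u_R = h·P_LR`, `u_G = 1 + β_FF·h·(1−P_LR)` (feedforward topology only,
else 1), `u_I ∈ {0,1}`, and a shared resource factor

```
φ = 1 / (1 + w_G u_G + w_R u_R + w_I u_I)
```

the dynamics are

```
dG/dt = c k_G u_G φ − d_G G
dR/dt = c k_R u_R φ − d_R R
dX/dt = c k_X u_R φ − d_X X − k_on X I + k_off C
dI/dt = c k_I u_I φ − d_I I − k_on X I + k_off C
dC/dt = k_on X I − (k_off + d_C) C
dP_LR/dt = V_on I (1 − P_LR) − V_off C P_LR
```

with `c` the plasmid copy gain. Four topologies: `NO_CONTROLLER` (no
recombinase genes), `OPEN_LOOP_MUT` (recombinase expressed, flipping
disabled — the central-dinucleotide-mutant control), `RE_NF` (negative
feedback), `RE_NF_FF` (feedback + feedforward).

The **Coupling Index (CI)** scores a response curve: GFP normalized to its
uninduced baseline, RFP to its maximum, the curve g(r) fitted with a
shape-preserving piecewise-cubic Hermite interpolant (PCHIP), and

```
CI = mean over r ∈ [0,1] of ( g(r) − 1 )
```

CI = 0 is perfect decoupling; negative/positive values are under-/over-
compensation. A `direct` point-average variant is provided for dense
simulated curves.

## Worked example

```r
library(recflip)
p <- circuit_parameters()            # default parameterization

open_loop <- dose_response_scan(p, "OPEN_LOOP_MUT")   # plate dose ladder
compute_ci(normalize_responses(open_loop))
#> <coupling_result> CI = -0.154589 (negative; pchip_fit, n = 201)

re_nf <- dose_response_scan(p, "RE_NF")
compute_ci(normalize_responses(re_nf))
#> <coupling_result> CI = -0.0324323 (negative; pchip_fit, n = 201)

find_decoupling_value(p, "RE_NF_FF", "d_X", bracket = c(1e-2, 1e2))
#> tuned_value: 19.187  (|CI| = 2.3e-15 at the optimum)
```

Reading: the flip-disabled open loop loses ~31% of its GFP across the
induction ladder (CI ≈ −0.155); the negative-feedback controller recovers
most of it (CI ≈ −0.032) but can never overshoot zero; the feedforward
controller overcompensates at its default excisionase turnover and is tuned
to near-perfect decoupling at `d_X* ≈ 19 /h`.

The numbered drivers under `analysis/` run the full study — dose responses
per topology (`01`), the feedback-strength sweep (`02`), feedforward tuning
over excisionase turnover and integrase expression (`03`), and
parameter recovery from synthetic plate data (`04`) — writing tables under
`results/`.

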