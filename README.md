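# kvgating

Kinetic modelling and analysis of voltage-gated K⁺ (Kv) channel **gating
currents**, for ion-channel biophysicists who want to simulate, analyse, or
generate realistic synthetic patch-clamp data for tetrameric channels —
including 3:1 heterotetramers that carry one *electrically silent* subunit
(the Kv2.1/Kv6.4 configuration).

## The model and the statistics at its core

Each subunit's voltage sensor is a single closed→activated transition with
log-linear rates

    alpha(V) = alpha0 * exp( z_a*d_a * V / V_T )
    beta(V)  = beta0  * exp(-z_b*d_b * V / V_T ),   V_T = kB*T/e0,

three identical "common" subunits plus one (possibly distinct) fourth
subunit, aggregated into a 9-state Markov ladder with a final concerted,
voltage-independent, charge-neutral opening step. Occupancies are propagated
with matrix exponentials (the Q-matrix method); gating current is the net
charge flux over the ladder's edges.

The analysis pipeline implements the standard gating-current workflow:

* ON-charge integration and Q–V construction, normalized to maximal charge;
* Boltzmann fits `y = 1/[1 + exp(-(V - Q1/2)/k)]`, single and two-component
  (with ordering constraint and mixing fraction);
* apparent gating charge from the slope, `z = kB*T/(k*e0)`;
* decay fitting with 1–2 exponentials, reported as amplitude-weighted time
  constants τ_w, and τ–V curves with local-maximum location;
* decay trace-crossing detection, Cole–Moore activation delays, G–V curves
  from peak ionic currents;
* a synthetic recording generator: Gaussian noise, 4-pole Bessel-type
  low-pass filtering, leak/capacitance artifacts, P/8 subtraction, mixed
  homo/hetero channel populations, Gillespie single-channel simulation —
  all with ground truth attached and seed-reproducible.

## Worked example

Simulate a 3:1 heterotetramer with the silent subunit calibrated to a
hyperpolarized charge component, run the standard gating protocol (60 ms
steps, −140…+40 mV after a −140 mV prepulse), and re-measure the Q–V:

```r
library(kvgating)
pc  <- physical_constants()            # 298.15 K, V_T = 25.693 mV
het <- preset_heterotetramer(pc)       # common: -21.8/5.8 mV; silent: -93.2/9.4 mV

prot   <- make_gating_protocol(sample_interval_ms = 0.005)
traces <- simulate_protocol(het, prot, "gating", pc)
fit    <- fit_double_boltzmann(build_qv(traces))
print(fit)
#> <double_boltzmann_fit> A1 = 0.170: Q1/2 = -92.9 mV (k 9.33); Q1/2 = -21.8 mV (k 5.75); SSE = 2.09e-05

charge_from_slope(fit$slope_k_1, pc)   # 2.75 e0 (silent subunit)
charge_from_slope(fit$slope_k_2, pc)   # 4.47 e0 (per Kv2.1-like subunit)

tau_voltage_curve(traces)$local_maxima
#> [1] -90 -20
```

The double-Boltzmann fit recovers the two calibrated components: ~17% of
the gating charge moves around −93 mV (the silent subunit's voltage sensor)
and the rest around −22 mV, and the τ–V relation shows the corresponding
two bells. The same round trip for the homotetramer returns −26.2 mV /
4.66 mV against the calibration targets −26.5 mV / 4.6 mV.

A command-line interface covers the same workflow
(`exec/kvgate simulate|analyze|reproduce|make-synthetic`, e.g.
`Rscript exec/kvgate simulate --model heterotetramer --out out/`).

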