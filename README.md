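# mrochannel

Exact information rates of a single synaptic release site under
short-term depression.

## The problem

Chemical synapses transmit spikes stochastically: a presynaptic action
potential releases a vesicle only with some probability *p*, vesicles are
also released asynchronously or spontaneously with probability *q*, and
after every release both probabilities are depressed and then slowly
recover. How many bits per second does such a site convey about its input
spike train, how many bits does it buy per vesicle (the dominant metabolic
cost), and does depression help or hurt? `mrochannel` answers these
questions exactly, for computational neuroscientists studying synaptic
information efficacy, energy-efficient neural coding, and short-term
plasticity.

## The model

The release site is a binary asymmetric channel with memory. Input
`X_i ~ Bernoulli(α)` is the spike indicator (a discretized Poisson train,
time step Δ = 10 ms); the output `Y_i` indicates a release, drawn with
probability `p_i` after a spike and `q_i` otherwise. Each release
multiplies the probabilities by depression factors (`p ← c·p`, `q ← d·q`);
each quiescent step relaxes them toward their resting values
(`p ← p + e·(p0 − p)`), with `e = 1 − exp(−Δ/τ)` for a recovery time
constant τ. The channel state is the last `L` release outcomes, an
integer `j` with 2^L values, giving per-state probabilities `p(j)`, `q(j)`
and a sparse two-successor Markov chain over histories.

Conditional on the state, the channel is memoryless, with rate

    R_j = h( (1−α)·q(j) + α·p(j) ) − (1−α)·h(q(j)) − α·h(p(j))     [bits/step]

(`h` = binary entropy), and the exact information rate under depression is
the stationary average `R_D = Σ_j R_j π_j`. At one unit of energy per
vesicle, the energy-normalized rate divides by the stationary release rate
`Σ_odd j π_j`. Closed-form baselines `R_0`, `R_0^(E)` cover the
no-depression case. The package also provides Monte-Carlo simulation of
spike/release traces, parameter sweeps (capacity, optimal input rate,
effective memory length, functional categories of depression), a
quantized single-step alternative formulation, and presets for three
experimentally characterized synapses (hippocampal autapse, calyx of
Held, corticostriatal synapse under dopamine).

## Worked example

A hippocampal autapse driven at 5 Hz: synchronous release `p0 = 0.4`
depressing to 75% per release and recovering with τ = 250 ms;
asynchronous release `q0 = 0.04`, undepressed:

```r
library(mrochannel)
m <- mro(rate_hz = 5, p0 = 0.4, q0 = 0.04, c_sync = 0.75, d_async = 1,
         tau_sync_ms = 250, f_async = 0.1, L = 20)
m
#> Release-site channel with a memory of 20 release outcomes ( 1048576 states )
#> Release-site parameters (time unit 10 ms, memory L = 20)
#>   input spike rate     alpha = 0.05     (5 Hz)
#>   synchronous release  p0 = 0.4    c = 0.75   e = 0.03921
#>   asynchronous release q0 = 0.04   d = 1      f = 0.1
#>   R_D = 2.978 bps, R_D^(E) = 54.63 bps/E  (with depression)
#>   R_0 = 4.073 bps, R_0^(E) = 70.22 bps/E  (without depression)
```

Without depression this site would transmit 4.07 bits/s at 70.2 bits per
second per unit energy; depression lowers both to 2.98 bps and 54.6 bps/E
— asynchronous release does not rescue the temporally encoded
information. A whole case study at once:

```r
run_case_study("calyx", L = 20)
#>  variant alpha     q0 R_0_bps R_D_bps R_0E_bps R_DE_bps
#>  minimum   0.1 0.0033    9.95  7.5595  284.631  280.467
#>  average   0.1 0.0380    5.14  3.1739   77.644   72.920
#>  maximum   0.1 0.2500    0.16  0.0293    0.621    0.298
```

Reading the calyx table: higher asynchronous release (`q0`) floods the
channel with spike-independent releases and collapses the rate, while the
energy-normalized rate barely changes between the depressed and
undepressed site (280.5 vs 284.6 bps/E at the minimum) — information per
vesicle is robust to depression there. `summary(m)` adds the functional
category and state diagnostics, `plot(m)` shows the state-space
clustering, `simulate(m, n_steps = 1e5, seed = 1)` draws traces.

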