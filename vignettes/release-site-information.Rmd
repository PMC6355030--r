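---
title: "Information transfer at a depressing release site: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transfer at a depressing release site: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrochannel)
```

## The model

A single synaptic release site is treated as a binary asymmetric channel.
Time is discretized into steps of $\Delta$ milliseconds (10 ms by default).
The channel input $X_i \in \{0, 1\}$ indicates a presynaptic spike in step
$i$; spikes arrive as independent Bernoulli draws with probability
$\alpha$, the discretization of a homogeneous Poisson train ($\alpha =
\nu\,\Delta$ for a rate of $\nu$ Hz). The output $Y_i \in \{0, 1\}$
indicates a vesicle release: a spike releases with the *synchronous*
probability $p_i$, a quiescent step releases with the *asynchronous*
(including spontaneous) probability $q_i$, so the per-step release
probability is $r_i = \bar\alpha q_i + \alpha p_i$ with
$\bar\alpha = 1 - \alpha$.

Short-term depression makes $p_i$ and $q_i$ history dependent. After each
release both probabilities drop multiplicatively ($p \leftarrow c\,p$,
$q \leftarrow d\,q$); during quiescence they relax geometrically toward
their resting defaults ($p \leftarrow p + e\,(p_0 - p)$, and likewise with
$f$ and $q_0$). A step applies either the drop or the recovery, never
both — the discrete counterpart of impulsive depression with continuous
recovery in the classical differential-equation description
$\dot p_r = (p_0 - p_r)/\tau - u\,p_r\,\delta(t - t_r)$. The two pictures
are linked by $c = 1 - u$ and $e = 1 - e^{-\Delta/\tau}$; with that choice
one recovery step is the exact one-step solution of the relaxation ODE,
which is why the package converts time constants with
`recovery_coefficient()` (250 ms $\to$ 0.039, 406 ms $\to$ 0.024,
4.2 s $\to$ 0.0024 at $\Delta = 10$ ms).

The channel's state is the vector of the last $L$ release outcomes,
encoded as the integer
$j = Y_{i-1} + 2\,Y_{i-2} + \dots + 2^{L-1}Y_{i-L}$ (bit 0 is the most
recent outcome, so odd $j$ means "released last step"). Replaying the $L$
recorded outcomes from the resting defaults yields the per-state
probabilities $p(j)$ and $q(j)$; `build_state_table()` does this for all
$2^L$ states at once with a doubling recursion, and
`release_prob_from_history()` exposes the scalar replay. From state $j$
the chain moves to $2(j \bmod 2^{L-1}) + 1$ on a release (probability
$r(j)$) and to $2(j \bmod 2^{L-1})$ otherwise, a sparse two-successor
structure.

## Information measures

Conditional on being in state $j$, the channel is memoryless and binary
asymmetric, with per-step mutual information
$$R_j = h(\bar\alpha q(j) + \alpha p(j)) - \bar\alpha h(q(j)) -
\alpha h(p(j)),$$
where $h$ is the binary entropy. The information rate of the depressing
site is the stationary average $R_D = \sum_j R_j \pi_j$, with $\pi$ the
stationary distribution of the history chain. With one unit of metabolic
energy per vesicle release, the energy-normalized rate divides by the
stationary release rate, $R_D^{(E)} = R_D / \sum_{\text{odd } j} \pi_j$.
Setting $c = d = 1$ collapses every state onto the default channel and
gives the closed-form no-depression baselines $R_0$ and $R_0^{(E)}$
(`rates_without_depression()`).

Two unit conventions are reported for energy-normalized rates, because
both are in circulation. Dimensionally, $R^{(E)}$ is bits per release
(`R_E_per_release`). The published case-study tables that the package
reproduces instead print bits-per-second divided by the expected number of
releases per *time step* (`R_E_bps`, labelled "bps/E"); the two differ by
the factor $1000/\Delta$. Both are always filled in, and nothing is
silently renormalized.

```{r rates-example}
m <- mro(alpha = 0.05, p0 = 0.4, q0 = 0.04, c_sync = 0.75, d_async = 1,
         e_sync = 0.039, f_async = 0.1, L = 12)
m
```

## Parameters and their meaning

| Parameter | Meaning | Typical range | Unit |
|---|---|---|---|
| `alpha` | spike probability per step | 0.05–0.5 | – |
| `p0`, `q0` | resting synchronous / asynchronous release probability | 0.1–0.7 / 0–0.25 | – |
| `c_sync`, `d_async` | depression multiplier per release | 0.1–1 | – |
| `e_sync`, `f_async` | recovery fraction per quiescent step | 0.002–0.3 | – |
| `L` | memory length | 8–24 | steps |
| `delta_ms` | time unit $\Delta$ | 10 | ms |

All probabilities are per time step; `rate_hz`, `tau_sync_ms` and
`tau_async_ms` convert physical units. The constructor requires the core
parameters to lie strictly inside $(0, 1)$ but deliberately admits the
boundary cases $c = 1$ or $d = 1$ (an undepressed release mode — both the
hippocampal and corticostriatal presets need $d = 1$) and $q_0 = 0$ or
arbitrarily small (a site without asynchronous release, used in
limiting-case analyses). When a mode is undepressed its recovery
coefficient is inert; presets set it to 0.1 purely as a placeholder.

## Numerical choices

* **Stationary solver.** Power iteration with a uniform start, max-norm
  tolerance $10^{-12}$ and a cap of $10^5$ iterations. The kernel never
  forms a matrix: every state has exactly two predecessors
  ($\lfloor s/2 \rfloor$ and $\lfloor s/2 \rfloor + 2^{L-1}$), so one
  iteration is a handful of vectorized operations of length $2^L$. The
  case-study chains ($L = 20$, about $10^6$ states) converge in a few
  hundred iterations. The iteration is deterministic; `--seed` in the
  reproduction script exists only for interface uniformity.
* **State-space guard.** `build_state_table()` refuses $L$ above 24
  ($1.7 \times 10^7$ states) unless the caller raises the cap, bounding
  memory use.
* **Entropy boundaries and clamps.** $h(0) = h(1) = 0$ by continuity so
  $q_0 \to 0$ sweeps are safe; per-state rates clamp tiny negative
  floating-point residue to zero (mutual information is non-negative).
* **Grid conventions.** Spike-rate sweeps report the optimal $\alpha$ at
  grid resolution, without interpolation, so results are deterministic and
  comparable across runs. The default grid is 99 points from 0.01 to 0.99.
* **Category ties.** The functional classification (does depression raise
  the information rate and/or the energy-normalized rate?) treats a zero
  difference as "no increase", matching the strict reading of an
  *increase*. The impossible fourth sign pattern (rate gain without
  efficiency gain) is checked at tolerance $10^{-9}$ and raised as an
  error, since it can only arise from an implementation defect.
* **Effective memory seeds.** The seed value $u_0$ replayed from beyond
  the memory window defaults to $\{0.1\,p_0,\; p_0,\;
  \min(0.99, 1.9\,p_0)\}$ applied to the synchronous mode, with the
  asynchronous seed scaled proportionally ($u_0 q_0 / p_0$) so both modes
  are perturbed coherently. The exact probe set is a free choice (any
  spread of seeds works) and is configurable.

## The simulator and what passing tests show

`simulate_release_site()` draws spike/release traces with the
*unbounded-memory* recurrence — the running probabilities are never
truncated to $L$ outcomes — and discards a burn-in of $10 L$ steps by
default. It emulates a stationary Poisson input driving a single site with
pooled asynchronous/spontaneous release. It does not emulate rate-modulated
inputs, multiple release sites, vesicle-pool exhaustion, facilitation, or
postsynaptic nonlinearity, so agreement between simulation and theory
validates the analytic machinery on the model's own terms, not the model
against biological recordings.

Because the simulator carries unbounded memory while the chain truncates
at $L$, concordance tests use fast-forgetting parameter sets (strong
depression, fast recovery) where the truncation bias is orders of
magnitude below Monte-Carlo error, and compare windowed occupancy
frequencies against the corresponding *marginal* of $\pi$. Release-rate
checks use three binomial standard errors at $4 \times 10^5$ to
$4 \times 10^6$ steps; occupancy checks use total-variation distance
(0.005 at $4 \times 10^6$ steps for an 8-step window). These problem sizes
were chosen so the whole suite runs comfortably on a laptop while keeping
the statistical power to detect systematic bias.

## The quantized single-step formulation

An alternative formulation tracks only the current probability pair
$(p_i, q_i)$ and the last outcome instead of the full $L$-step history.
For an exact finite-chain analysis the probabilities must be quantized to
a finite set. The package uses uniform grids of `n_levels` points on
$[0, p_0]$ and $[0, q_0]$ (each containing its default), nearest-level
snapping after every update, and the reachable closure of level pairs from
the resting state. This particular grid is a reconstruction — the original
quantization underlying the formulation is not fully specified — and its
only claimed validation is convergence toward the history-based channel as
the grid refines, which the tests check. Since the probability pair
carries unbounded memory, the natural comparison point is the
history-based channel at long memory; at 64 levels the two agree to within
a few percent for moderate depression.

## Case studies

Three presets transcribe published parameter estimates for experimentally
characterized synapses (10 ms time unit, $L = 20$):

* **Hippocampal autapse** at 5/10/20 Hz: $p_0 = 0.4$, $c = 0.75$,
  $e = 0.039$ ($\tau = 250$ ms), undepressed asynchronous release
  ($d = 1$) whose resting level grows with input rate
  ($q_0 = 0.04, 0.08, 0.12$).
* **Calyx of Held** at 10 Hz: $p_0 = 0.32$, $c = 0.53$, $d = 0.5$,
  $e = 0.0024$ ($\tau = 4.2$ s), $f = 0.0153$, with the observed minimum,
  average and maximum asynchronous release ($q_0 = 0.0033, 0.038, 0.25$).
* **Corticostriatal synapse (nucleus accumbens)** at 25 Hz: $p_0 = 0.42$,
  $c = 0.75$, $e = 0.024$ ($\tau = 406$ ms), $d = 1$, with $q_0 = 0.04$
  (control) and $q_0 = 0.01$ (75 µM dopamine).

$L = 20$ (200 ms of memory) is adopted as the common default because it is
the memory length used for the published parameter studies; the reference
tables themselves do not state their memory length. `run_case_study(...,
convergence = TRUE)` reports $|R_D(L) - R_D(L-2)|$ so users can judge the
truncation. Two caveats surfaced by that check are worth knowing. First,
for the corticostriatal synapse the synchronous recovery constant (406 ms)
exceeds the 200 ms window, so $R_D$ still moves by several percent between
$L = 20$ and $L = 24$; the published no-dopamine row is consistent with
the longer memory. Second, the published dopamine-condition values cannot
be reproduced from the stated $q_0 = 0.01$ at any memory length, while an
intermediate $q_0 \approx 0.02$ (close to what the stated 46% reduction of
$q_0 = 0.04$ would give) reproduces them closely; the preset keeps the
explicitly stated $q_0 = 0.01$ and the mismatch is reported rather than
hidden. The hippocampal and calyx tables reproduce to their printed
precision at $L = 20$.

```{r case-study}
run_case_study("hippocampus", L = 12)
```

(The reproduction script under `scripts/` runs the same pipelines at
$L = 20$.)

## Known limitations

The model addresses one release site with at most one vesicle per step; a
synapse with many sites, distinct vesicle pools, facilitation,
rate-modulated (inhomogeneous) inputs, or postsynaptic receptor dynamics
is outside its scope. The information rate is exact for the channel as
defined — the state is observable from past outputs — but it is not a
general hidden-state channel capacity, and no entropy-rate estimation from
raw traces is attempted (empirical validation goes through release rates
and occupancies instead). Energy accounting assigns one unit per release
and ignores the costs of spiking and housekeeping.
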