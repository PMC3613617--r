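---
title: "Rare correlations, eligibility traces and delayed reward: the rchp model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare correlations, eligibility traces and delayed reward: the rchp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a reward arrives seconds after the cue or action that caused it, and
unrelated stimuli keep arriving in between, a learning network must decide
which of its recent activity patterns deserves the credit. rchp implements a
rate-based solution built on three interacting mechanisms: a Hebbian rule
that fires only for the *rare* synapses whose activity strongly correlates, a
slowly decaying synapse-specific *eligibility trace* seeded by those rare
events, and a fast-decaying global *modulation* driven by reward that
converts surviving traces into weight changes.

The combinatorial intuition is exposed by the package's population model
(`toy_config()`, `run_toy()`): with 100,000 synapses, correlations tagging 1%
of them per second, and traces that matter for about 3 s, roughly 3,000
synapses are eligible at any reward. Only the synapse that actually triggers
rewards is eligible at *every* episode; bystanders survive k consecutive
episodes at rate 0.03^k, so about 90 survive twice and at most a handful
survive four times. Five episodes essentially isolate the causal synapse.
`expected_eligible()` and `expected_consecutive()` give these closed forms;
`run_toy()` checks them by simulation.

## The neural substrate

`build_network()` constructs 800 excitatory and 200 inhibitory rate neurons
with directed random connectivity (each ordered pair connected with
probability 0.1, no self-connections). Neuron states and outputs follow

$$u_i(t) = \sum_j w_{ji}\, v_j(t)\, \kappa_j, \qquad
  v_i(t+\Delta t) = \begin{cases}
  \tanh(\gamma u_i(t)) + \xi_i(t) & u_i \ge 0\\
  \xi_i(t) & u_i < 0\end{cases}$$

with $\kappa = +1$ for excitatory and $-5$ for inhibitory presynaptic
neurons, fresh uniform noise $\xi \in [-0.1, 0.1]$ per neuron and step, and a
sampling step $\Delta t = 0.2$ s that doubles as the propagation time, so the
plasticity rule's correlation window is exactly one step. Stimuli and actions
are carried by disjoint groups of 60 randomly chosen excitatory neurons; an
active stimulus adds +10 to each member's state. Input-group members receive
no recurrent connections and output-group members project none, which keeps
persistent stimuli from igniting self-sustained recurrent activity.

Within a step the order is: external drive, then synaptic accumulation, then
the noisy transfer function; plasticity then sees the presynaptic output of
the previous step against the postsynaptic output of the current one. The
compiled engine and the exported R operations (`step_network()`,
`detect_correlations()`, `update_traces()`, `update_modulation()`,
`apply_weight_update()`, `update_thresholds()`) implement the identical
sequence; a test holds them to agreement within 1e-12 over hundreds of steps
on a shared RNG stream.

## The plasticity cascade

Each existing synapse (j, i) compares the lagged product
$v_j(t-\Delta t)\,v_i(t)$ against adaptive thresholds: strictly above
$\theta_{hi}$ emits $+\alpha$, strictly below $\theta_{lo}$ emits $-\beta$
(both 0.1; ties emit nothing). Events feed traces and a reward r(t) feeds the
modulation,

$$\dot c_{ji} = -c_{ji}/\tau_c + \mathrm{RCHP}_{ji}(t), \qquad
  \dot m = -m/\tau_m + \lambda r(t) + b, \qquad
  \dot w_{ji} = m\, c_{ji},$$

integrated with explicit Euler steps; event values land at full magnitude at
the event step, traces are unclipped, and weight updates apply to plastic
synapses only (afferents of excitatory neurons), clipped to [0, 1]. With
$\tau_c = 4$ s and $\tau_m = 1$ s, traces outlive the reward delay while
modulation acts briefly, so a delayed reward multiplies what remains of the
traces created by the causing stimulus.

Both thresholds adapt homeostatically: first-in-first-out queues hold the
event counts of the last 10 s; when the windowed mean rate (fraction of
monitored synapses per second) leaves the band [0.1, 2.5] %/s around the
0.5 %/s target, the threshold magnitude moves by 0.002 per second, floored
at zero. The controller is deliberately crude — an integral controller with
a dead band — and its operating point depends on the input regime: in a
free-running network it settles just above the noise-product shelf
(about 0.01) and holds the rate in band essentially always, which is the
regime the homeostasis property test asserts (10-min runs, 3-min burn-in,
three seeds). Under bursty stimulation the rate transiently leaves the band
during stimulus onsets; the queue's 10-s memory then raises the thresholds
between trials, and the long-run operating point in the conditioning
scenarios sits near 0.1-0.2.

## Scenarios

**Classical conditioning** (`run_classical()`): nine binary stimuli appear
independently at 0.15 %/s, last 3-30 s, and one of them (the CS) triggers a
reward of magnitude 1 after a uniform 0-5 s delay. Over a 2-h run the CS
pathway — the mean weight from the CS group to the output group — grows to
saturation while the eight disturbing pathways stay low; output activity of
at least 0.5 during a CS-only interval is flagged as a conditioned response.
The brief variant shortens stimuli to 1-2 s and delays the reward relative
to stimulus *offset*, so the cue is gone before the reward arrives.

**Operant conditioning** (`run_operant()`): five colors are presented every
20 s, sequentially and circularly; output-group activity is monitored over a
1-s decision window that opens one propagation step after stimulus onset
(the outputs cannot reflect the stimulus earlier, and deciding at the onset
step itself would read pure pre-stimulus noise). The earliest group to reach
30% of the maximum attainable activity wins — among simultaneous crossers
the most active one, with exact ties broken toward the lowest index — and if
none crosses, the window-end argmax wins even by a small margin. The winner
receives +10 drive and all other action groups -10 for 1 s, informing the
network of the performed action; correct answers earn r = +5 at a 0-5 s
delay, wrong answers r = -0.5. **Reversal** (`run_reversal()`) continues the
loop with a switched policy in which the previously correct action is
punished at full magnitude (-5) and a new action is rewarded;
`segment_reversal_phases()` recovers the resulting four-phase trajectory
(exploit old, weight convergence, re-exploration, exploit new).

```{r}
library(rchp)
rec <- run_classical(config = classical_config(), seed = 1)
summary(rec)
plot(rec)
```

## Parameter choices where the source leaves gaps

Several constants are not fixed by the model equations; the package's
defaults, all exposed in `network_params()` / `plasticity_params()` and in
the YAML config, were chosen once as follows.

* **Gain $\gamma$ = 0.5.** Saturates the transfer function under the +10
  stimulus drive ($\tanh 5 \approx 1$) while keeping sub-threshold responses
  in the linear range.
* **Initial weights uniform on [0, 0.2].** Weights must leave room to grow
  to saturation while keeping pre-learning responses modest, and — less
  obviously — they must be large enough for the inhibitory population to
  matter. With mean weight 0.1, a neuron's twenty inhibitory afferents
  (weight times $\kappa = -5$) roughly balance its eighty excitatory ones,
  and the inhibitory afferents of a repeatedly rewarded action group are
  themselves plastic, so reward-driven growth of a group's excitatory input
  is accompanied by growth of its inhibitory input. This negative feedback
  keeps the winner-take-all competition centered on the noise and prevents
  frequently rewarded actions from capturing the action selection of
  still-unlearned stimuli. Much smaller inits (tried during development at
  0.005-0.02) remove the inhibitory tone: the homeostatic thresholds then
  settle inside the output-noise band, rare-event conversions concentrate on
  the systematic residue of stimulus drive, and pathways to never-rewarded
  actions creep upward until they lock the argmax.
* **Modulation gain $\lambda$ = 0.25.** $\lambda$ sets how much weight
  change one reward episode buys. The conditioning runs constrain it from
  two sides: operant associations should need a few (not one) rewarded
  trials to consolidate, and classical pathways should climb to saturation
  over on the order of ten reward episodes. Both place $\lambda$ near 0.2 to
  0.45 for a one-step reward pulse; 0.25 reproduces the full set of
  behaviors — gradual classical acquisition, five colors learned within half
  an hour with incorrect pathways staying low, and a delay capacity of 10 s
  with 4-s traces. At $\lambda = 1$ single rewards one-shot pathways to
  saturation and the same conversion amplifies noise-product traces enough
  to grow never-rewarded pathways over long runs.
* **Baseline b = -0.001/s.** A small tonic negative modulation: pathways
  that keep creating traces without ever being rewarded decay slowly
  (extinction), and a cued-then-rewarded pathway shows the characteristic
  slight dip just before the reward converts its traces.
* **Action feedback duration 1 s; stimulus stays on for decision window +
  feedback (2 s).** The enunciation of an answer takes on the order of a
  second; the stimulus outlasting the decision lets the color-to-action
  correlation form during the feedback phase.
* **Reward pulse width one step (0.2 s).** A touch of the hand is modeled
  as a single-step r(t) pulse; sustained contact can be emulated by scaling
  the magnitude or repeating the pulse via the schedule.

## What the generators emulate, and what they do not

The stimulus schedules reproduce the timing statistics of the interactive
setting — Poisson arrivals, overlapping disturbers, uniform reward delays,
sequential-circular color presentations — under a fixed seed, so every run
is exactly reproducible. They do not emulate perceptual noise (flickering or
obstructed markers), variable human reaction times beyond the uniform delay
law, or reward magnitudes modulated by touch duration. Passing tests
therefore demonstrate the learning dynamics under idealized timing
uncertainty, not robustness to sensor failure.

## Numerical choices and degenerate inputs

All dynamics use explicit first-order integration at dt = 0.2 s; trace decay
per step is exactly $(1 - dt/\tau_c)$, asserted as a closed form in the
tests. Strict inequalities in the event rule mean boundary products emit
nothing. Thresholds floor at zero magnitude. Weight updates skip entirely
when m = 0, so a run with r = 0 and b = 0 leaves every weight bit-identical.
Empty groups, group demand beyond the excitatory pool, mismatched schedule
horizons and a zero monitored-synapse count raise errors. A connection
probability of zero yields an empty synapse set and a pure-noise network.
Simulation problem sizes in the test suite follow the scenario defaults
(10-run sets; 2-h classical horizons; 40-min operant horizons; 25-run delay
sweep at the 2-h horizon), with a 100-neuron reduced network for the
operation-level and property tests.

## Known limitations

* Reward expectation is not modeled: rewards act directly, so blocking does
  not occur, and extinction arises only from the tonic negative baseline.
* The homeostatic controller is slow (0.002/s): during stimulus bursts the
  instantaneous correlation rate overshoots the band by design, and the
  threshold operating point is regime-dependent.
* With frequent large rewards, noise products whose magnitude approaches the
  output-noise ceiling can still convert into small spurious weight gains;
  the modulation gain and initial-weight defaults keep this creep negligible
  over the simulated horizons, but very long exploitation phases would
  slowly inflate unrelated pathways.
* The delay capacity depends on the number of reward episodes a run
  provides; scaled-down horizons under-measure it.
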