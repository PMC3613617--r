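# rchp

Reward-modulated Hebbian learning with **r**are **c**orrelations, eligibility
traces and delayed neuromodulation, for simulating classical and operant
conditioning under realistic timing uncertainty.

## The problem and the model

When a reward arrives seconds after the cue or action that caused it — and
other, unrelated stimuli keep arriving in between — a network must decide
which of its recent activity deserves the credit (the *distal reward
problem*). rchp solves it with rarely correlating Hebbian plasticity: for
every synapse (j, i) the lagged output product is thresholded,

$$\mathrm{RCHP}_{ji}(t) = \begin{cases}
 +\alpha & v_j(t - t_{pt})\, v_i(t) > \theta_{hi} \\
 -\beta  & v_j(t - t_{pt})\, v_i(t) < \theta_{lo} \\
 0 & \text{otherwise,}
\end{cases}$$

with both thresholds adapted online so that only a rare target fraction
(~0.5 %/s) of synapses emits events. Events feed synapse-specific
eligibility traces and rewards feed a global modulation,

$$\dot c_{ji} = -c_{ji}/\tau_c + \mathrm{RCHP}_{ji}(t), \qquad
  \dot m = -m/\tau_m + \lambda r(t) + b, \qquad
  \dot w_{ji} = m\, c_{ji},$$

so a reward delayed by a few seconds ($\tau_c = 4$ s) multiplies whatever
traces survive from the causing stimulus, while traces of disturbing stimuli
rarely coincide with rewards and average out. The substrate is a
1,000-neuron rate network (tanh transfer, ±0.1 uniform output noise,
inhibitory neurons weighted −5) whose stimulus and action channels are
disjoint groups of 60 excitatory neurons; the macroscopic readout of
learning is the *pathway strength*, the mean weight from one group to
another.

The package implements, as reproducible closed-loop simulations:

* **classical conditioning** — nine Poisson stimuli, one of which (the CS)
  triggers a delayed reward; the CS pathway grows to saturation while the
  eight disturbing pathways stay low (`run_classical()`), including a
  brief-stimulus variant where the reward arrives only after the CS has
  ceased;
* **operant conditioning** — five colors, eight actions, winner-take-all
  action selection with action-to-network feedback, +5/−0.5 delayed rewards
  (`run_operant()`), and behavior reversal under punishment
  (`run_reversal()`, `segment_reversal_phases()`);
* the **synapse-population model** of credit assignment — eligible-set
  arithmetic and consecutive-reinforcement attrition (`run_toy()`,
  `expected_eligible()`, `expected_consecutive()`);
* a delay-capacity sweep for the maximum bridgeable reward delay
  (`sweep_delay()`).

The inner loop is compiled (Rcpp); a 2-h, 36,000-step conditioning run takes
a few seconds. All randomness flows through R's RNG, so every run is exactly
reproducible from a seed.

## A worked example

A full 2-h simulated classical-conditioning run:

```r
library(rchp)
rec <- run_classical(config = classical_config(), seed = 1)
summary(rec)
#> == rchp classical recording ==
#> rchp classical recording: 120.0 min simulated (36000 steps of 0.2 s), seed 1
#>   strongest pathways: S1->A0 = 0.990, S5->A0 = 0.176, S8->A0 = 0.136, S4->A0 = 0.084, S9->A0 = 0.027
#>   final m = -0.001, theta_hi = 1.04, theta_lo = -0.102
#>   mean correlation rate 2.074 %/s (last half of run)
#>   CS pathway S1->A0 dominant: TRUE
#>   conditioned responses: 206
```

S1 is the conditioned stimulus: its pathway to the output group saturates
near the weight ceiling (0.990) while the strongest disturbing pathway stays
at 0.176, and the output group responded 206 times to the CS alone — the
conditioned response. `plot(rec)` draws the pathway strengths, the
modulation signal and the output activity over time.

The population model's attrition table, analytic vs simulated (200
replications):

```r
toy_summary(toy_config(), n_episodes = 5, replications = 200, seed = 1)
#>   episode expected    mean median    sd mean_eligible sigma_always
#> 1       1 3.00e+03 3005.57   3004 54.61          3007         TRUE
#> 2       2 9.00e+01   89.87     90 10.01          2995         TRUE
#> 3       3 2.70e+00    2.83      3  1.69          3006         TRUE
#> 4       4 8.10e-02    0.07      0  0.34          3000         TRUE
#> 5       5 2.43e-03    0.00      0  0.00          3002         TRUE
```

About 3,000 synapses are eligible at any reward, ~90 survive two consecutive
rewards, at most a handful survive four, and the reward-triggering synapse
is always among the survivors.

A command-line front end wraps the same functions:

```sh
./exec/rchp classical --seed 3 --duration 7200 --out out/
./exec/rchp operant --seed 3 --out out/
./exec/rchp toy --episodes 5 --replications 200 --seed 1 --out out/
./exec/rchp sweep-delay --delays 4,6,8,10,12 --seeds 5 --seed 1 --out out/
```

Outputs are plain text: per-step scalar series (CSV), pathway strengths
(CSV), an event log (JSON-lines), and a summary (JSON); see
`inst/extdata/example-config.yaml` for the full configurable surface.

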