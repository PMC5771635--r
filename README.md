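# reservoirtask

Simulation and analysis of a reservoir-computing model of how the
orbitofrontal cortex (OFC) could acquire a task's state space during
reinforcement learning.

The scientific question: animals that learn the *structure* of a task —
e.g. that reward contingencies reverse in blocks, or that an intermediate
outcome rather than the choice itself determines reward — re-learn much
faster than a plain stimulus–response learner, and OFC lesions abolish
exactly this advantage. The model explains both observations with a
minimal circuit: a fixed, sparse random recurrent network (a reservoir, the
"state-encoding layer") receives every task event *including the reward
itself* as input. Its dynamics form conjunctive codes for task states such
as "chose A and was rewarded". A two-unit readout, trained only with a
reward-modulated Hebbian rule

&nbsp;&nbsp;&nbsp;&nbsp;Δw<sub>ik</sub> = η (r − E[r]) (y<sub>i</sub> − y<sub>th</sub>) z<sub>k</sub>,&nbsp;&nbsp;followed by column renormalization,

with softmax action selection p<sub>k</sub> ∝ exp(β v<sub>k</sub>), then
attaches actions to those state codes. Because "A rewarded" and "A
unrewarded" are different states, reversals stop erasing prior learning and
the network re-learns faster and faster; removing the reward input (the
"OFC lesion") removes the conjunctive states and with them the
acceleration.

The package implements, as tested R code:

* the reservoir dynamics (Euler-integrated leaky rate units, bounded
  transfer, per-step uniform noise) with a fast C++ core;
* the plastic softmax readout and the Hebbian update above;
* three task environments with the published parameters — deterministic
  reversal learning, a two-stage Markov decision task, and a value-based
  economic choice task with range-adapted offer inputs;
* the manipulations: reward-input lesion, decision-time inactivation of
  selected neurons, learning freeze;
* the full analysis battery: errors-to-criterion learning curves,
  selectivity classification and category grouping, population state-space
  PCA, stay-probability factorial analysis and the task-structure index,
  maximum-likelihood fitting of a hybrid model-free/model-based learner,
  lagged-state and factor logistic regressions, choice psychometrics, and
  the ten-variable value-selectivity taxonomy.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()`/`plot_*()`
functions.

## A worked example

Train a reversal-learning network for ten blocks and look at the learning
curve:

```r
library(reservoirtask)

cfg <- session_config("reversal", n_blocks = 10)
s   <- run_session(cfg, seed = 1)
glance(s)
#> # A tibble: 1 × 5
#>   task     n_trials  seed reward_rate updates
#>   <chr>       <int> <dbl>       <dbl>   <int>
#> 1 reversal     1000     1       0.838     999

errors_to_criterion(s$log)
#> # A tibble: 10 × 7
#>    block block_type n_trials criterion_met trials_to_criterion errors_to_criterion errors_total
#>    <int> <chr>         <int> <lgl>                       <dbl>               <int>        <int>
#>  1     1 A               100 TRUE                           91                  21           21
#>  2     2 B               100 TRUE                           59                  25           29
#>  3     3 A               100 TRUE                           39                  13           17
#>  4     4 B               100 TRUE                           39                  11           12
#>  5     5 A               100 TRUE                           32                   8           13
#>  6     6 B               100 TRUE                           41                  11           14
#>  7     7 A               100 TRUE                           47                  12           16
#>  8     8 B               100 TRUE                           30                   6           13
#>  9     9 A               100 TRUE                           48                  16           17
#> 10    10 B               100 TRUE                           32                   8           10
```

The initial acquisition needs 91 trials and 21 errors to reach the 93%
criterion; later reversals are re-learned with progressively fewer errors
(they flatten near their floor within tens of blocks) — the task-structure
signature. With
`session_config("reversal", ..., lesion_reward_input = TRUE)` the error
count stays flat across reversals instead.

Downstream analyses chain naturally:

```r
traces <- collect_condition_traces(s$reservoir,
                                   reversal_condition_schedules(),
                                   n_reps = 10, seed = 1, epoch = c(0, 900))
population_pca(traces, center = FALSE)
#> <population_pca> 4 condition(s); first 3 components carry 94.4% of the variance

run_session(session_config("twostage", n_trials = 3000), seed = 1,
            record_rates = FALSE) |>
  tidy() |>
  dplyr::filter(trial > 2000) |>
  stay_table() |>
  ts_index()
#> [1] 0.0850886   # > 0: the network repeats after common-rewarded and
#>              # rare-unrewarded outcomes, i.e. it uses the transition model
```

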