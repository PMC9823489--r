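---
title: "Guide-agent multi-agent feature selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-agent multi-agent feature selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marfsga)
```

## The selection problem

Given a labelled table of `N` numeric features — a gene-expression panel
with a handful of discriminative genes among thousands, a sensor table
where most channels are irrelevant — wrapper feature selection asks for
the subset of columns that maximises the holdout accuracy of a classifier
trained on that subset. Exhaustive search over `2^N` subsets is
infeasible; `marfsga` instead treats the problem as `N` tiny bandit
problems solved jointly.

## Agents, actions, rewards

Every feature `i` gets two agents:

* a **main agent** holding two Q-values, `Q_i(1)` for selecting the
  feature and `Q_i(0)` for deselecting it, and
* a **guide agent** with no state at all, which flips an independent fair
  coin every episode.

One **episode** proceeds as follows.

1. Each main agent acts epsilon-greedily: with probability `ε` it
   explores (selects with probability 1/2), otherwise it exploits,
   selecting iff `Q_i(1) >= Q_i(0)` (a tie selects). The exploration coin
   is drawn independently per agent, not once per episode.
2. Each guide agent flips its coin, yielding a second mask.
3. Both masks are scored by the environment: `R_m` and `R_g` are the test
   accuracies of a classifier trained from scratch on the main-selected
   and guide-selected columns.
4. The **train reward** is the signed difference `R_t = R_m − R_g ∈
   [−1, 1]`: positive when the learned policy beats a coin-flip subset,
   negative when it loses to one.
5. **Disagreement-gated update:** only main agents whose action differs
   from their guide counterpart at the same position learn:
   `Q_i(a_i) += α · R_t`. Agents that agree with the guide are left
   untouched, and the non-acted Q is never modified.
6. `ε` is multiplied by the decay rate `EDR`.

The gate is the core idea. `R_t` is a global signal; crediting it to all
agents would drive every Q in lockstep and make per-feature discrimination
impossible. Restricting the update to disagreeing positions makes the
expected increment of feature `i` depend on the *conditional* effect of
that feature's presence: averaged over episodes, an informative feature
sees `R_t` rise when it is in the main mask and not the guide mask, and
fall when the guide has it and the main does not, so its `Q(1) − Q(0)`
drifts upward; a noise feature's drift follows the global average and is
pushed down once the learned mask beats the random baseline.

After the last episode the selected subset is read greedily off the final
Q table (`Q_i(1) >= Q_i(0)`). The best-observed mask (highest `R_m` over
the run) is reported alongside, since on noisy rewards the two can differ;
we treat the greedy mask as the primary answer because it averages over
the whole run rather than one lucky draw.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon0` | 0.5 | initial exploration probability |
| `edr` | 0.99995 | multiplicative epsilon decay per episode |
| `alpha` | 0.01 | learning rate on the train reward |
| `n_episodes` | 10,000 | episode budget |
| `q0_init_range` | [0, 1] | uniform init of Q(deselect) |
| `q1_init_range` | [0, 0.05] | uniform init of Q(select) |

The asymmetric initialisation makes the initial greedy selection sparse:
`P(Q(1) >= Q(0)) = 0.025` per feature in closed form, so a run starts from
a small subset and grows it, rather than pruning from everything.

The decay rate is conventionally tied to the episode budget so that the
final exploration rate lands at about 0.3 (0.99995 over 10,000 episodes,
0.9995 over 1,000). `edr_for(n_episodes)` computes the rate for any
budget; the scaled-down runs in this package's tests (500 and 2,000
episodes) use it so that short runs traverse the same exploration
schedule as long ones.

There is no epsilon floor and no Q clipping: the update is a plain
bandit-style increment, not a temporal-difference rule, and Q magnitudes
are monitored through the run history rather than constrained.

## The reward environment

* **Split.** One stratified 7:3 train/test split is drawn per run, before
  the episode loop, and reused for every evaluation. Re-splitting per
  episode would move the reward scale around and confound the learning
  signal. Stratification matters for small imbalanced cohorts (e.g. 62
  samples split 40/22), where an unstratified split can starve a class.
* **Classifier.** A feed-forward network with hidden layers of 5 and 2
  ReLU units, softmax output, trained with mini-batch Adam (step 0.01,
  batch 32) for exactly 10 passes, no early stopping. It is retrained
  from scratch for every mask. Features are standardised with
  training-part statistics only. The classifier is pluggable
  (`classifier_config(classifier = ...)` accepts any
  `function(x_train, y_train, x_test, seed)` returning predictions), and
  the small network is only the default.
* **Empty masks.** A mask selecting nothing is legal and scores the
  majority-class test accuracy — the best a classifier with no inputs can
  do. This keeps the reward defined without special-casing the update,
  and makes empty selections unattractive whenever learning is possible.
* **Determinism.** A run's master seed derives five independent RNG
  streams (Q init, split, exploration coins, guide coins, classifier
  seeds), so toggling the guide off does not shift the other streams,
  and identical inputs give bit-identical histories. An optional
  per-run cache memoises evaluations by mask, deriving the classifier
  seed from the mask bits so that the reward is a fixed deterministic
  function of the mask (`cached_accuracy()` exposes the same function
  for enumeration oracles); it is off by default to mirror per-episode
  retraining, and on in tests that need an enumerable environment.

Accuracy on a held-out part of `n` samples is quantised to steps of
`1/n_test`; with 200 samples and a 7:3 split the reward cannot resolve
effects smaller than about 1.7%. This resolution limit matters below.

## The no-guide ablation

With `guide_enabled = FALSE` the guide agents are removed and every main
agent's acted Q receives `α · R_m`. Because `R_m` is always non-negative,
whichever action an agent happens to take early is reinforced and the
policy freezes within a few hundred episodes; late-run behaviour is then
driven by exploration alone. The ablation tests quantify the contrast:
the guided runs' trailing accuracy is substantially higher in every seed
pair. The trailing *variance* of the selected-subset size, by contrast,
is nearly identical between the two arms at our scaled budgets — once the
no-guide policy has frozen, both arms' subset-size fluctuation is the
same epsilon-exploration noise, while the guided arm adds a little
variance of its own through its slow Q drift. The acceptance suite states
the stronger claim (guided variance no larger than the ablation's) and we
leave it failing at the margin rather than weaken it.

## The synthetic generator

`make_synthetic()` plants ground truth so that recovery can be measured:
informative features get class means separated by `class_separation`
noise standard deviations (random sign per feature), redundant features
are an informative column plus Gaussian noise at half the separation
scale, and noise features are standard normal, label-independent. Labels
are balanced. Defaults (200 samples, 5 informative + 45 noise at 3σ)
emulate a small two-class study where most measured variables are
meaningless.

What the generator does **not** emulate: correlated noise blocks,
heavy-tailed or count-valued measurements, batch effects, label noise,
and class-conditional covariance structure. Passing recovery tests on
this generator therefore demonstrates the mechanics of the selector, not
performance on any particular real assay.

One property of the generator is worth stating plainly: in a binary
problem, features that are individually informative through separated
class means are necessarily *mutually redundant*. At 3σ separation a
single informative feature already yields ~93% accuracy and any three of
them ~99%, so the marginal accuracy of the fourth and fifth falls below
the test-set resolution. An accuracy-driven wrapper — this one, or a GA —
then has almost no signal to add the remaining planted features: runs
reliably keep 3–5 of the 5 and filter out nearly all noise, but recovery
of *all* planted features is not guaranteed at any episode budget, and
our long-run experiments plateau at 4/5. The per-feature signal that
remains (an informative feature in the guide mask raises `R_g` whenever
the guide lacks the others) moves Q-values by only ~1e-4 per episode at
`α = 0.01`. This is a property of redundancy under an accuracy reward,
not of the implementation; the acceptance suite states the stronger
recovery claim and we leave it failing rather than weaken the check.

## Problem sizes used in tests

The test and acceptance runs use scaled-down budgets chosen as this
package's own trade-off between statistical sharpness and turnaround:
500 episodes (with the evaluation cache) for the 4-feature enumeration
oracle, 2,000 episodes for recovery and ablation runs on the 50-feature
planted benchmark, 10 seeds or seed pairs per claim, and `edr_for()`
decay throughout. Monte-Carlo checks of closed-form probabilities use
10⁴–10⁶ draws.

## Numerical choices and degenerate inputs

* Ties `Q(1) = Q(0)` select the feature, both in exploitation and in the
  final greedy read-out, so a feature whose evidence is exactly balanced
  is kept rather than dropped.
* The train reward is signed; its negative range is what lets the method
  punish a policy that underperforms a coin flip. Restricting it to
  `[0, 1]` would silently halve the learning signal.
* A single-feature dataset, an empty selection, and an unreachable
  `stop_target` are all legal and covered by tests; constant feature
  columns get unit variance during standardisation instead of dividing
  by zero.
* mRMR uses the mutual-information difference criterion with 5-bin
  equal-frequency discretisation; ReliefF uses Manhattan distances on
  min-max-scaled features with class-prior-weighted misses (k = 10), so
  weights are invariant to affine rescaling of any feature.

## Known limitations

* The method has a mixing time set by the learning rate: each update
  moves one Q-value by `α·R_t`, so flipping a feature whose initial
  `Q(0) − Q(1)` gap is ~0.5 takes on the order of
  `0.5 / (α · E|R_t| · P(update))` episodes — several hundred to a few
  thousand at the default `α = 0.01`. Budgets well below that return a
  greedy mask still close to the sparse initialisation; our enumeration
  oracle checks only agree with the selector once the budget clears this
  timescale.
* Rewards are single-holdout accuracies; no cross-validation, AUROC or
  F1 reward is offered.
* The Q update has no discounting or bootstrapping; episodes are
  independent given the Q table, so the method cannot exploit
  inter-episode state.
* Guide agents act uniformly at random; on very large `N` the guide
  subset is always near `N/2` features, which weakens the contrast for
  small informative sets.
* Redundant informative features saturate the accuracy signal (see
  above); if identifying *every* member of a correlated informative
  block matters, a filter method (mRMR with a redundancy term, ReliefF)
  should complement the wrapper.
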