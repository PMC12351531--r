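---
title: "The reputation game: model, learning rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reputation game: model, learning rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgame)
```

## The model

`repgame` simulates a small group of agents (three, by default) whose only
conversation topic is each other's honesty. Each agent has a fixed
*intrinsic honesty* — its probability of telling the truth in any message —
and wants to be *seen* as honest. Reputation is credibility: the better an
agent's reputation, the more its messages move the others' beliefs, so
agents can pursue status either by being honest or by lying strategically.

Listeners face a dual-learning problem. A lie is sometimes accompanied by
an involuntary, objective cue — a *blush* — with fixed probability
(`blush_prob`, default 0.1); a truth never blushes. If the agents knew the
cue's conditional frequencies exactly, a blush would certify a lie. But
they must *learn* those frequencies from the same stream of messages whose
honesty they are trying to judge. The package exists to study when this
coupled inference succeeds and when it collapses into a *Learned
Insignificance of Credibility Signs* (LICS): a self-stabilizing state in
which an agent's estimated blush frequencies under lying and truth-telling
become so similar that the cue carries almost no evidential weight.

## Belief representation

Every scalar unknown — an agent's honesty, a blush frequency — is
represented by two nonnegative pseudo-counts $(\mu, \lambda)$ encoding the
density $\mathrm{Beta}(f \mid \mu + 1, \lambda + 1)$, with mean
$\bar f = (\mu + 1)/(\mu + \lambda + 2)$. Counts may be fractional, so
uncertain classifications can contribute partial evidence.
`belief()`, `belief_mean()`, `belief_variance()`, `belief_log_density()`,
`kl_beta()` and `fuse_beliefs()` expose this calculus.

Receiving a message under uncertainty produces a *mixture* of beta
posteriors (one per hypothesis about the speaker). Agents have no memory
for mixtures: after every update the state is compressed back to a single
beta. `compress_mixture()` returns the beta minimizing
$\mathrm{KL}(\text{mixture} \,\|\, \text{beta})$, which is equivalent to
matching the mixture's expectations of $\ln f$ and $\ln(1 - f)$. The two
digamma moment equations are solved by damped Newton iteration (tolerance
$10^{-10}$, at most 100 iterations, step halving on residual increase),
started from mean/variance moment matching. If the unconstrained optimum
would need a negative pseudo-count, the offending count is pinned at zero
and the remaining equation re-solved; if Newton fails outright the
moment-matched fallback is returned with a warning. This compression is
also the vehicle for a key property used throughout the engine: a
two-component mixture whose weight equals the prior predictive mean *is*
the prior, so uninformative evidence changes nothing.

## Conversations

One timestep is one conversation and produces exactly two messages. A
uniformly drawn initiator picks a partner and a topic according to its
strategy, composes a message, and the partner — after updating on it —
answers on the same topic. An honest message transmits the speaker's
current belief $(\mu, \lambda)$ on the topic unchanged. A lie is anchored
at the speaker's theory of mind (ToM) of the *receiver's* belief (to sound
plausible) and shifts it by `alpha` (default 2) pseudo-counts: added to
$\mu$ for a positive lie, to $\lambda$ for a negative one. Lies about
oneself and about friends are positive, about enemies negative; friendship
is bookkept per counterpart as the running mean of opinions they have
communicated about oneself, classified against the pooled grand mean
(ties, and counterparts never heard from, are neutral).

The five strategies follow the config enum `ordinary`, `deceptive`,
`manipulative`, `dominant`, `destructive`. All non-ordinary strategies have
intrinsic honesty 0. Manipulative agents seek out partners they believe
dishonest and always flatter them (topic = partner, positive). Dominant
agents seek out partners they believe honest and boast (topic = self half
of the time). Destructive agents seek honest partners, badmouth an enemy,
and never blush — trading away their own self-calibration data.

## Receiver-side learning

For each incoming message the receiver computes an honesty weight $y_h$,
its posterior probability that the message is honest:

* a *confession* — a self-directed claim strictly worse than the opinion
  the receiver already holds of the speaker — is believed outright
  ($y_h = 1$): even if it were a lie, adopting it lowers the liar's
  reputation;
* otherwise $y_h = \bar x / (\bar x + (1 - \bar x)\, R)$, where $\bar x$
  is the speaker's reputation mean and
  $R = R_{\text{blush}} \cdot e^{\gamma D}$ combines the blush likelihood
  ratio with a surprise penalty.

$R_{\text{blush}}$ evaluates the observed cue at the means of the
receiver's blush-frequency beliefs (`blush_likelihood_ratio()`). The
surprise $D$ entering the exponent is the *predictive* surprise
(`predictive_surprise()`): the Bernoulli KL divergence between the claimed
and the prior posterior means. The full beta divergence (`surprise()`)
grows without bound as both beliefs sharpen, so using it would make every
late-run disagreement unforgivable regardless of its size; the predictive
form is bounded, vanishes as opinions align, and still punishes outrageous
claims. The exponent $\gamma D$ is capped at `max_exponent` (50).

The message then updates four things:

1. **Speaker honesty.** The exact per-message posterior is the mixture
   "{$y_h$: one honest count; $1 - y_h$: one dishonest count}", and it is
   *compressed*, not added. When $y_h$ equals the prior predictive mean
   the mixture reproduces the prior, so uninformative messages move
   nothing, while decisive ones ($y_h \in \{0, 1\}$) add exactly one
   count. This choice is what gives the model its calibration property:
   in oracle mode the unique fixed point of an agent's reputation is its
   intrinsic honesty. Adding fractional counts directly would count an
   uninformative message as one full observation and pin reputations near
   their starting value.
2. **Topic belief.** Only the *novel* part of the claim relative to the
   receiver's ToM envelope of the speaker is fused (honest branch), scaled
   to at most `evidence_cap` (default 2, the lie-shift scale)
   observations; under the lie hypothesis the content is discarded.
   Confessions are exempt from the cap — they are anchored in the
   speaker's own self-observation and have no echo path. Without the
   novelty subtraction and cap, the same content returning over several
   conversational paths compounds pseudo-counts exponentially in a small,
   fully connected group (the model's acknowledged double-counting made
   catastrophic).
3. **Blush frequencies.** Under the lie hypothesis (weight $1 - y_h$) the
   message is one trial for the lie channel; under the honest hypothesis
   one trial for the truth channel; each channel's posterior mixture is
   compressed. Disabled in oracle mode.
4. **Theory of mind.** The ToM entry for (speaker, topic) ratchets up to
   the componentwise maximum of the claims the speaker has professed —
   the tracker novelty subtraction needs. After *sending*, a speaker
   nudges its ToM of the receiver toward the claim, weighted by its
   estimate of its own credibility in the receiver's eyes.

Speakers also observe themselves: one exact count per message into their
own blush-frequency channel (lie-with-blush, lie-without, or truth) and
into their belief about their own honesty (`self_weight`, default 1). The
self-knowledge count is what keeps a partly honest agent's self-image low
enough for confessions to fire; fully deceptive agents never speak
honestly about themselves and so never generate this counterweight —
which is precisely what makes them dangerous. Setting `self_weight = 0`
recovers a purely social self-image.

## LICS

The per-step predicate (`lics_flag()`) is the margin inequality
$1.1\,\bar f_{b|h} > 0.9\,\bar f_{b|\neg h}$: the flag flips exactly at a
lie/truth frequency ratio of $11/9 \approx 1.22$. Because uninformed
agents start with *equal* prior means, the inequality holds trivially at
$t = 0$; batch statistics therefore count an agent as having *developed* a
LICS only if it is inside an episode at or after a 500-step burn-in
(`developed_lics()`), the same scale as the 500-step lead-in window used
for conditional averages. The raw episodes, tracked at every timestep
regardless of the recording cadence, are always available in the run
object.

In oracle mode (`known_frequencies = TRUE`) every agent evaluates blushes
at the exact frequencies (`blush_prob` for lies, 0 for truths): a blush
certifies a lie ($y_h = 0$, even for a blushing confession), blush
learning is disabled, and no agent can satisfy the LICS predicate.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `blush_prob` | 0.1 | probability a non-suppressed lie blushes |
| `alpha` | 2 | lie shift in pseudo-counts |
| `gamma` | 1 | weight of predictive surprise in the credibility ratio |
| `evidence_cap` | 2 | max observations of novel content per message |
| `self_weight` | 1 | pseudo-count weight of one self-observation |
| `lics_margins` | (1.1, 0.9) | LICS inequality margins (boundary 11/9) |
| `max_exponent` | 50 | cap on the surprise exponent |
| `known_frequencies` | FALSE | oracle mode |
| `initiator` | random | or round_robin |

`blush_prob`, `alpha`, the margins, and the 0.97/0.80/0.14 roster are the
study conditions. `gamma`, `evidence_cap` and `self_weight` parameterize
the credibility-combination rule, which this package had to design in
full. Their defaults are the values at which the model reproduces its own
benchmark behaviors: reputations tracking intrinsic honesties in the
oracle setting, blush frequencies learned near their true values, and
deception strategies able — but not guaranteed — to entrench.
`evidence_cap` is deliberately equal to `alpha`, so a single message can
carry at most one lie's worth of content.

## Experiment drivers and problem sizes

`run_simulation()` is one run; batches derive run $k$'s seed as
`seed0 + k - 1` so strategy arms compare on matched seeds.
`run_learning_batch()` tabulates LICS incidence, final reputations, the
honest-message fraction, and reputation/informedness of ordinary agents
conditional on LICS windows (episodes plus the preceding 500 steps).
`run_honesty_sweep()` draws three uniform honesties per run, sorts them
(red lowest, cyan median, black highest), and reports exposed honesty
against the time-averaged log blush likelihood ratio.
`run_rehabilitation()` transfers an agent's full internal state
(`take_snapshot()`) into a fresh pair of ordinary agents with U(0,1)
honesties; beliefs about absent agents ride along untouched and are
restored on reinsertion. `run_continuation()` resumes a finished world,
either unchanged or with the focal agent's state replaced by a
rehabilitated snapshot.

The test suite runs 200 seeds per strategy arm at the full 4500
conversations, a 300-run honesty sweep, 20 rehabilitation runs, and 20 +
20 continuation runs of 7500 steps; these sizes keep every ensemble
statistic's Monte-Carlo error well below the contrasts being asserted.
`informedness()` — the mean log-density of an agent's honesty beliefs at
the true honesties, clamped to $[10^{-6}, 1 - 10^{-6}]$ — is recorded at
the trajectory cadence (every 10 steps in batches).

## What the generator does and does not emulate

All inputs are synthetic: the simulation itself is the data-generating
process, and its defaults are the study conditions above. It emulates
small, fully connected groups with a single conversation topic per
exchange, one special strategist at most, stationary intrinsic honesties,
and an objective binary cue with fixed conditional frequencies. It does
not emulate larger networks, topic diversity, mixed or adaptive
strategies, forgetting, or any natural-language content — so passing
tests show that the *mechanisms* behave as described under these idealized
conditions, not that real social systems do.

## Numerical choices and degenerate inputs

All log/digamma evaluations act on parameters shifted by $+1$, so the
uninformed state $(0,0)$ is regular everywhere. Belief construction
rejects negative or non-finite counts; densities are evaluated only on the
open interval. Compression short-circuits single-component and
near-degenerate-weight mixtures (weight $\ge 1 - 10^{-12}$) to the heavy
component exactly, which also guarantees that decisive updates
($y_h \in \{0,1\}$) are exact count increments. Friendship ties and
empty ledgers are neutral; a destructive agent with no enemies picks a
topic uniformly among the others. Two-agent worlds are legal (partner
selection is forced). Runs are bit-reproducible from `(config, seed)`;
all randomness flows through R's RNG, so `set.seed()` governs the
compiled core as well.

## Known limitations

The credibility-combination rule is a reconstruction; its published form
was not available. One consequence is that in this reconstruction the
dominant and deceptive strategies entrench
almost deterministically while the manipulative strategy's
flattery-cascade is partially damped by the self-knowledge anchor, so the
relative LICS-incidence ranking of the manipulative arm falls below the
dominant and deceptive arms. The within-arm victim patterns (manipulative
harms the most honest agent most; dominant harms the middle agent most;
destructive harms mainly itself) and all other ensemble patterns are
reproduced. Pseudo-count growth is kept linear by construction; there is
no forgetting mechanism.
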