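# repgame

Agent-based simulations of reputation, deception, and the learned
devaluation of an objective lie cue.

## The problem

Small groups of agents talk about one thing only: how honest each of them
is. Every agent has a fixed intrinsic honesty — its probability of telling
the truth in any message — and wants to be seen as honest, either by being
honest or by lying strategically. Lies are sometimes betrayed by an
involuntary, objective cue (a "blush"): a lie blushes with probability
`blush_prob = 0.1`, a truth never does. Listeners face a dual-learning
problem: they must infer everyone's honesty from messages whose honesty is
itself uncertain, while simultaneously learning how informative the blush
cue is.

`repgame` implements this model end to end for researchers in
computational cognitive science and opinion dynamics: the
beta-pseudo-count belief calculus with information-optimal mixture
compression, the message protocol (honest transmission, theory-of-mind
anchored lies, blushes, confessions, surprise), five communication
strategies (`ordinary`, `deceptive`, `manipulative`, `dominant`,
`destructive`), a fast compiled simulation engine, and batch drivers for
learning runs, uniform-honesty sweeps, rehabilitation runs and
continuation runs. It detects the emergent **Learned Insignificance of
Credibility Signs (LICS)**: the state in which an agent's estimated blush
frequencies satisfy `1.1 * f_b|truth > 0.9 * f_b|lie` (boundary ratio
11/9), so the cue has lost its evidential value.

Beliefs are pseudo-count pairs `(mu, la)` encoding
`Beta(f | mu + 1, la + 1)` with mean `(mu + 1) / (mu + la + 2)`. A
receiver weighs each message by the speaker's reputation, the blush
likelihood ratio, a surprise penalty, and the confession rule, then
compresses the resulting belief mixtures back into single betas by
minimizing `KL(mixture || beta)`. The methods vignette
(`vignettes/reputation-game.Rmd`) derives the update rules and documents
every design choice and default.

## A worked example

```r
library(repgame)

cfg <- sim_config(agent_roster(c("black", "cyan", "red"),
                               c(0.97, 0.80, 0.14)),
                  n_timesteps = 4500, seed = 7)
sim <- run_simulation(cfg)
print(sim)
#> <rg_sim: 4500 steps, honest fraction 0.641>
#> final reputations:
#> black  cyan   red
#> 0.933 0.829 0.198
#> LICS episodes: 5 (agents: black, red, cyan)

bb <- blush_beliefs_of(sim$world, "black")
sprintf("black estimates: f_b|lie = %.3f, f_b|truth = %.4f",
        belief_mean(bb$lie_freq), belief_mean(bb$truth_freq))
#> "black estimates: f_b|lie = 0.105, f_b|truth = 0.0055"
```

About 64% of messages are honest (the mean of the three intrinsic
honesties), the final reputations track the intrinsic honesties
0.97/0.80/0.14, and agent black has learned that roughly one lie in ten
blushes while truths essentially never do — the dual-learning problem
solved. The `LICS episodes` line lists intervals in which an agent's two
blush-frequency estimates were too similar; here they are brief
early-learning transients (see `developed_lics()` for the burn-in-aware
statistic used in batch summaries).

Ensemble experiments follow the same pattern:

```r
batch <- run_learning_batch("dominant", n_runs = 200, seed0 = 1)
batch$summary$lics_fraction        # who develops a LICS, how often
sweep <- run_honesty_sweep(n_runs = 300, seed0 = 1)
snap  <- take_snapshot(sim$world, "cyan")
rehab <- run_rehabilitation(snap, n_runs = 20, seed0 = 1)
```

A thin command-line front end over these functions is installed at
`inst/cli/repgame.R` (`simulate`, `batch`, `sweep`, `rehab`, `continue`
subcommands; YAML configs via `read_config()`).

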