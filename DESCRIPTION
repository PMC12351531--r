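Package: repgame
Title: Reputation Game Simulations with Learnable Credibility Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of small groups of agents that talk about
    each other's honesty while simultaneously learning how informative an
    objective deception cue (a "blush") is. Beliefs are represented as beta
    distributions over frequencies; receivers weigh incoming claims by the
    speaker's reputation, the surprise of the claim, confessions, and the
    blush likelihood ratio, and compress the resulting belief mixtures back
    into single beta distributions. The package provides the belief calculus,
    the message protocol, the five communication strategies (ordinary,
    deceptive, manipulative, dominant, destructive), a fast simulation engine,
    and batch experiment drivers for learning runs, honesty sweeps,
    rehabilitation runs, and continuation runs, including detection of the
    emergent Learned Insignificance of Credibility Signs (LICS) bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
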