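Package: bistable
Title: Hidden Markov and Hierarchical Brownian Models for Bistable Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models for sequences of perceptual dominance times recorded during
    continuous and intermittent viewing of ambiguous stimuli. Provides a
    one-state inverse-Gaussian model and a two-state hidden Markov model with
    inverse-Gaussian emissions (Baum-Welch estimation, Viterbi decoding), and a
    hierarchical Brownian model in which percept switches and switches between
    stable and unstable regimes both arise from first passages of drifting
    Brownian motions. Includes duration-dependent state transitions governed by
    normal-inverse-Gaussian laws, constrained maximum-likelihood fitting,
    exact and path-level simulators, derived pattern statistics (stable-time
    fraction, alternation rate, pre-transition dominance times), a likelihood
    ratio test for equality of two inverse-Gaussian samples, parametric
    bootstrap precision studies, cumulative-history permutation analysis, and
    a synthetic cohort generator for two-group designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
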