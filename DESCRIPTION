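Package: mindsetmdp
Title: Simulating and Classifying Cultural-Mindset Decision Making
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generative belief-augmented Markov decision process models of
    "fixed" and "malleable" cultural mindsets playing a dialog-based
    cross-cultural task (asking villagers for the location of a water
    source under an unfamiliar formality norm). Provides softmax-consistent
    Q-value iteration over the discrete belief-augmented state space,
    seeded cohort simulation with lognormally distributed decision-noise
    parameters, behavioral validity metrics (cultural learning,
    conversation structure, quitting, responsiveness to feedback), group
    comparisons (Welch t, chi-squared, Cohen's d), and maximum-likelihood
    classification of play records by generating mindset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
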