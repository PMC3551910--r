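Package: pomdpdots
Title: Reward-Optimal Decision Making in the Random-Dots Motion Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the random-dots motion discrimination task as a partially
    observable Markov decision process. Spike counts from direction-selective
    MT populations are binomial observations whose success probability jointly
    encodes motion direction and coherence; conjugate beta belief updating
    reduces the task to a Markov decision process on an integer evidence
    lattice, which is solved by backward induction to yield a reward-maximizing
    policy with a collapsing decision boundary. Exact first-passage analysis of
    the solved policy gives psychometric and chronometric predictions, a seeded
    Monte Carlo simulator generates synthetic trials, and an LIP firing-rate
    read-out reproduces urgency and buildup-rate signatures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
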