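Package: dqnxdrop
Title: Seed-and-Extend Local DNA Alignment with a Deep Q-Network X-Drop Extender
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Local alignment of DNA sequences by seed-and-extend, where the
    gapped-extension stage is driven by a dueling double deep Q-network that
    observes sliding windows of both sequences and chooses forward, insertion
    or deletion moves, terminated by the x-drop rule. Includes the mutation
    simulator (substitutions plus Zipfian-length indels) that defines the
    training environments, a meta-learning training loop over a distribution
    of mutation models, a classical greedy x-drop dynamic-programming baseline,
    and numerical evaluators for the step-error and complexity analysis of the
    method (Gumbel-statistics step-error bound, Zipf length bound, window-size
    relation, step-count scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    pracma,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
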