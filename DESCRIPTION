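Package: profnj
Title: Gene Tree Correction by Duplication-Loss Aware Polytomy Resolution
Version: 0.1.0
Authors@R:
    person("P2R", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects weakly supported gene trees against a rooted binary
    species tree. Branches below a support threshold are contracted, each
    resulting polytomy is resolved by a dynamic program that minimises a
    weighted duplication-loss reconciliation cost, and ties among the
    cost-optimal resolutions are broken with the Neighbor-Joining criterion
    applied to a sequence distance matrix. Also provides LCA reconciliation
    with per-branch duplication and loss tallies, ancestral gene content
    inference, rooting by minimum reconciliation cost, a birth-death gene
    family simulator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
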