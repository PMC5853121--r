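Package: octal
Title: Optimal Completion of Incomplete Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adds missing taxa to incomplete unrooted binary gene trees so as
    to provably minimize the Robinson-Foulds (RF) distance to a reference tree
    on the full taxon set. Implements the greedy leaf-insertion algorithm that
    solves the RF optimal tree completion problem exactly, together with the
    superleaf decomposition that certifies optimality (achieved RF equals
    r + 2m, where r is the RF distance between the restricted reference tree
    and the gene tree and m counts Type II superleaves), a brute-force
    enumeration oracle for small instances, quartet and matching tree
    distances for evaluating completions, and a synthetic-data generator that
    emulates gene-tree discordance and taxon-deletion protocols used in
    coalescent-based phylogenomic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
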