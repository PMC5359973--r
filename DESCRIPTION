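Package: dupcoev
Title: Duplication-Loss Reconciliation and Gene-Family Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene duplication and loss events by weighted-parsimony
    reconciliation of gene trees with (possibly non-binary) species trees,
    including support-threshold rearrangement of weakly supported branches,
    branch-balance rooting, per-branch event tables, and rank-sum/exact tests
    for correlated evolution of two gene families. Includes a birth-death
    simulator of gene-family histories with optionally shared rate episodes,
    and sequence-side helpers (maximum-likelihood pairwise distances under the
    LG model, distance-based subset selection, alignment column and homology
    hit filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
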