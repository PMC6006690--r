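Package: gapfillr
Title: Minimum-Cost MILP Gap Filling and Auditing of Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flux-balance analysis and parsimony-based gap filling of
    genome-scale metabolic networks. Given an incomplete metabolic model and a
    database of candidate reactions, a mixed-integer linear program selects a
    minimum-cost set of reactions to add (and existing irreversible reactions
    to reverse) so that the model can produce all of its biomass metabolites
    from the supplied nutrients. Costs encode taxonomic-range compatibility and
    the preference for reversing existing reactions over inserting new ones.
    The package also provides post-hoc quality control for gap-filler output:
    an indicator-constraint audit that detects solver-imprecision violations,
    minimality verification by iterative reaction removal, a brute-force
    optimal oracle for small instances, precision/recall scoring of predicted
    against reference reaction sets, a synthetic-benchmark generator with known
    deleted reaction sets and decoys, and packaged reference data from a
    published Bifidobacterium longum gap-filling comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
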