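Package: icrdm
Title: Cross-Ratio Intuitionistic Fuzzy Multicriteria Decision Analysis
Version: 0.1.0
Authors@R:
    person("icrdm", "maintainers", email = "icrdm@example.org", role = c("aut", "cre"))
Description: Algebra, ranking and aggregation of cross-ratio intuitionistic
    fuzzy values, and a two-level hierarchical multicriteria decision
    procedure built on them. Pairwise comparisons of alternatives are given
    per criterion as intuitionistic preference relations on a bounded bipolar
    0.1-0.9 rating scale; row-wise weighted geometric aggregation in odds
    space yields local and overall priorities, which are ranked by score and
    accuracy functions. Includes readers and writers for preference-relation
    matrices (CSV) and decision problems (JSON/YAML), a seeded generator of
    random valid preference relations, a command-line interface, and an
    embedded medical-waste disposal case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
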