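Package: argdx
Title: Argumentation-Based Differential Diagnosis over Scenario-Table
    Knowledge Bases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based differential-diagnosis engine in which medical
    knowledge is encoded as hierarchical diagnostic tables: each table is
    rooted at a presenting complaint and its rows describe increasingly
    specific clinical scenarios, marking which diseases remain supported.
    Matched rows give rise to arguments for diseases; deeper (more specific)
    rows yield stronger arguments, and a dialectic comparison of arguments
    and counterarguments selects the plausible diagnosis set.  The package
    provides a YAML knowledge-base format with parser, serializer, validator
    and local (single-table) revision; per-disease explanations and ranked
    next-question guidance; a closeness-accuracy evaluation protocol over
    three phases of a patient visit; and seeded generators for synthetic
    knowledge bases and patient cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
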