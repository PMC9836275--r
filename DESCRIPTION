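Package: claimdef
Title: Cohort Definition Building from Claims Diagnosis-Code Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds preliminary cohort definitions for administrative claims
    research. Given encounter-level claims, the package selects a sample of
    claims with a service of interest and a 1:1 matched random sample without
    it, fits an entropy-based classification tree on binary diagnosis-code
    indicators to rank codes by relative importance, screens the ranked codes
    with beta-distribution proportion intervals so that only codes credibly
    more frequent in service claims are retained, groups service claims by
    descending code importance, suppresses small cells to count ranges before
    the summary leaves a secure data environment, and propagates the masked
    counts as intervals through an include/exclude definition count engine.
    A synthetic Medicare-like claims generator with known ground truth makes
    every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
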