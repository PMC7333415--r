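Package: orsim
Title: Simulation-Based Design and Assessment of Operating-Room Setups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and comparing operating-room (OR) table
    setups for joint-replacement surgery. Encodes OR floor plans,
    instrument-table layouts and staff positions for total hip (THA) and
    total knee (TKA) arthroplasty; scores setups with a Total Rotational
    Movement (TRM) ergonomics model; simulates scrub-nurse-to-surgeon
    instrument handover times and circulator travel distances with an
    obstacle-aware grid path planner; compares setups with two-sample
    t-tests; and generates synthetic surgery logs that reproduce recorded
    per-surgery handover counts, circulator trip counts and
    incision-to-begin-of-closure times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
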